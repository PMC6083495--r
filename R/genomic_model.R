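#' Construct a set of gene loci
#'
#' Builds a [GenomicRanges::GRanges] of flat gene loci from BED-style
#' coordinates (0-based, half-open).  A gene locus is the most inclusive
#' genomic extent of one gene: the unit downstream of which readthrough
#' (DoG) regions are sought.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @param strand `"+"` or `"-"` per locus.
#' @param gene_id non-empty gene identifiers.
#' @param source_count number of annotation sources contributing to each
#'   locus (default 1).
#' @param seqlengths optional named integer vector of chromosome lengths.
#'
#' @return A `GRanges` (1-based internally, as is standard for Bioconductor
#'   containers) with metadata columns `gene_id` and `source_count`.
#' @export
gene_loci <- function(chrom, start, end, strand, gene_id,
                      source_count = 1L, seqlengths = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0) || any(start >= end))
    stop("gene loci require 0 <= start < end (0-based half-open)")
  if (!all(strand %in% c("+", "-")))
    stop("gene locus strand must be '+' or '-'")
  if (any(!nzchar(gene_id)))
    stop("gene_id must be non-empty")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand,
    gene_id = as.character(gene_id),
    source_count = rep_len(as.integer(source_count), length(chrom))
  )
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <-
      seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' 3' end of gene loci
#'
#' Returns the 3' boundary of each locus as an inter-base (0-based boundary)
#' coordinate, i.e. the same number a BED file would print: the BED `end`
#' for `+` loci, the BED `start` for `-` loci.
#'
#' @param loci a `GRanges` of gene loci (see [gene_loci()]).
#' @return numeric vector of 3' boundary positions.
#' @export
three_prime_end <- function(loci) {
  s <- as.character(BiocGenerics::strand(loci))
  if (any(s == "*"))
    stop("loci must be stranded to define a 3' end")
  ifelse(s == "+",
         BiocGenerics::end(loci),
         BiocGenerics::start(loci) - 1)
}

#' Interval downstream of gene 3' ends
#'
#' The strand-oriented region of width `length` immediately downstream of
#' each locus 3' end, silently clipped at chromosome boundaries.  The
#' returned interval never overlaps its own locus; at a boundary it may be
#' shorter than requested (possibly zero-width, returned as an empty range).
#'
#' @param loci a `GRanges` of gene loci.
#' @param length requested downstream width in bp (> 0).
#' @param chrom_len chromosome length(s): a single value, a vector parallel
#'   to `loci`, or `NULL` to use `seqlengths(loci)`.
#' @return a `GRanges` parallel to `loci` carrying the loci's metadata.
#' @export
downstream_interval <- function(loci, length, chrom_len = NULL) {
  stopifnot(length > 0)
  if (is.null(chrom_len)) {
    chrom_len <- GenomeInfoDb::seqlengths(loci)[
      as.character(GenomeInfoDb::seqnames(loci))]
    if (anyNA(chrom_len))
      stop("chromosome lengths unknown; supply chrom_len")
  }
  chrom_len <- rep_len(as.numeric(chrom_len), length(loci))
  if (any(BiocGenerics::end(loci) > chrom_len))
    stop("locus extends beyond the stated chromosome length")
  a <- three_prime_end(loci)               # 0-based boundary
  plus <- as.character(BiocGenerics::strand(loci)) == "+"
  dstart <- ifelse(plus, a, pmax(a - length, 0))          # 0-based
  dend <- ifelse(plus, pmin(a + length, chrom_len), a)
  dstart <- pmin(dstart, dend)
  out <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(loci),
    ranges = IRanges::IRanges(start = dstart + 1, end = dend),
    strand = BiocGenerics::strand(loci)
  )
  S4Vectors::mcols(out) <- S4Vectors::mcols(loci)
  out
}

#' DoG discovery parameters
#'
#' @param min_dog_len minimal initial downstream length (bp) that must meet
#'   the coverage criterion for a candidate DoG.  Default 4000.
#' @param min_dog_cov minimal coverage breadth (fraction of bases covered by
#'   at least one read) required over the initial interval and over every
#'   elongation window.  Default 0.60.  Stricter settings (e.g. 4500 bp /
#'   0.80) are advisable for non-polyA-selected, nuclear-enriched libraries.
#' @param window_len,window_step elongation window geometry (bp).  Windows
#'   of `window_len` slide downstream by `window_step`; defaults 200/100
#'   (50% overlap) resolve DoG endpoints to ~`window_step`.
#' @return an object of class `dog_params`.
#' @export
dog_params <- function(min_dog_len = 4000, min_dog_cov = 0.6,
                       window_len = 200, window_step = 100) {
  if (min_dog_len <= 0) stop("min_dog_len must be > 0")
  if (min_dog_cov <= 0 || min_dog_cov > 1)
    stop("min_dog_cov must be in (0, 1]")
  if (window_step <= 0 || window_step > window_len ||
      window_len > min_dog_len)
    stop("need 0 < window_step <= window_len <= min_dog_len")
  structure(
    list(min_dog_len = as.integer(min_dog_len),
         min_dog_cov = min_dog_cov,
         window_len = as.integer(window_len),
         window_step = as.integer(window_step)),
    class = "dog_params")
}

#' @export
print.dog_params <- function(x, ...) {
  cat(sprintf(
    "DoG parameters: min_dog_len=%d bp, min_dog_cov=%.2f, window=%d/%d bp\n",
    x$min_dog_len, x$min_dog_cov, x$window_len, x$window_step))
  invisible(x)
}

#' Construct DoG records
#'
#' A DoG record is a called readthrough region anchored at its parent
#' gene's 3' end; its BED `start` (for `+` genes: the gene end) or BED
#' `end` (for `-` genes: the gene start) coincides with that anchor.
#'
#' @inheritParams gene_loci
#' @return a `GRanges` with metadata columns `gene_id` and `dog_length`.
#' @export
dog_records <- function(chrom, start, end, strand, gene_id,
                        seqlengths = NULL) {
  gr <- gene_loci(chrom, start, end, strand, gene_id,
                  seqlengths = seqlengths)
  S4Vectors::mcols(gr)$source_count <- NULL
  S4Vectors::mcols(gr)$dog_length <- BiocGenerics::width(gr)
  gr
}
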