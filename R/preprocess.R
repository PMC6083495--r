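#' Infer RNA-seq library layout and strandedness
#'
#' Uses reads overlapping "unambiguous" loci — loci with no
#' opposite-strand overlapping locus — to estimate the concordance `f`
#' between read strand and gene strand under the forward-protocol model
#' (single/mate-1 read matches the transcript strand, mate-2 is opposite).
#' Returns `forward` if `f >= threshold`, `reverse` if
#' `1 - f >= threshold`, otherwise `unstranded`.  Layout is read from the
#' pairing flags.
#'
#' @param reads a read set with raw mapped strands.
#' @param loci a `GRanges` of gene loci.
#' @param sample_size number of informative alignments to inspect
#'   (default 200000).
#' @param threshold concordance needed to call a stranded protocol
#'   (default 0.8).
#' @return an object of class `library_spec`: list with `layout`
#'   (`"single"`/`"paired"`), `strandedness` (`"forward"`, `"reverse"`,
#'   `"unstranded"`), `concordance_fraction`, and `n_used`.
#' @export
infer_library_type <- function(reads, loci, sample_size = 200000,
                               threshold = 0.8) {
  if (length(loci) == 0) stop("loci annotation is empty")
  stopifnot(sample_size >= 1)
  opp <- GenomicRanges::findOverlaps(loci, BiocGenerics::invertStrand(loci),
                                     ignore.strand = FALSE)
  opp <- opp[S4Vectors::queryHits(opp) != S4Vectors::subjectHits(opp)]
  unamb <- loci[!seq_along(loci) %in% unique(S4Vectors::queryHits(opp))]
  hits <- GenomicRanges::findOverlaps(reads, unamb, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  # keep reads hitting loci of a single strand only
  gstr <- as.character(BiocGenerics::strand(unamb))[S4Vectors::subjectHits(hits)]
  nstr <- tapply(gstr, qh, function(s) length(unique(s)))
  rid <- as.integer(names(nstr)[nstr == 1])
  gene_strand <- vapply(split(gstr, qh)[as.character(rid)], `[[`,
                        character(1), 1)
  if (length(rid) == 0) stop("no usable alignments overlap the loci")
  if (length(rid) > sample_size) {
    gene_strand <- gene_strand[seq_len(sample_size)]
    rid <- rid[seq_len(sample_size)]
  }
  if (length(rid) < min(sample_size, 1000))
    warning("only ", length(rid),
            " usable alignments for strand inference; proceeding")
  mc <- S4Vectors::mcols(reads)
  rstrand <- mc$rstrand[rid]
  is_mate2 <- !is.na(mc$mate[rid]) & mc$mate[rid] == 2L
  concord <- ifelse(is_mate2, rstrand != gene_strand,
                    rstrand == gene_strand)
  f <- mean(concord)
  strandedness <- if (f >= threshold) "forward"
                  else if ((1 - f) >= threshold) "reverse"
                  else "unstranded"
  structure(list(
    layout = if (any(mc$paired)) "paired" else "single",
    strandedness = strandedness,
    concordance_fraction = if (strandedness == "reverse") 1 - f else
      if (strandedness == "forward") f else f,
    n_used = length(rid)), class = "library_spec")
}

#' Construct a library spec directly
#'
#' @param layout `"single"` or `"paired"`.
#' @param strandedness `"forward"`, `"reverse"` or `"unstranded"`.
#' @param concordance_fraction observed concordance (optional).
#' @return a `library_spec` object.
#' @export
library_spec <- function(layout = c("single", "paired"),
                         strandedness = c("forward", "reverse",
                                          "unstranded"),
                         concordance_fraction = NA_real_) {
  structure(list(layout = match.arg(layout),
                 strandedness = match.arg(strandedness),
                 concordance_fraction = concordance_fraction,
                 n_used = NA_integer_),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("library: %s-end, %s (concordance %.3f, n=%s)\n",
              x$layout, x$strandedness, x$concordance_fraction,
              format(x$n_used)))
  invisible(x)
}

#' Normalize read strands to the transcript strand
#'
#' Applies the protocol model so that each read's `strand` column becomes
#' the effective transcription strand: forward protocol keeps the mapped
#' strand for single/mate-1 reads and flips mate-2; reverse protocol does
#' the opposite; unstranded keeps mapped strands but marks them
#' non-informative (strand-specific logic then treats every read as
#' matching).
#'
#' @param reads a read set with raw mapped strands.
#' @param spec a `library_spec`.
#' @return the read set with effective strands and `informative` set.
#' @export
normalize_strand <- function(reads, spec) {
  stopifnot(inherits(spec, "library_spec"))
  mc <- S4Vectors::mcols(reads)
  eff <- mc$rstrand
  flip <- function(s) ifelse(s == "+", "-", "+")
  if (spec$strandedness == "forward") {
    m2 <- !is.na(mc$mate) & mc$mate == 2L
    eff[m2] <- flip(eff[m2])
    informative <- TRUE
  } else if (spec$strandedness == "reverse") {
    m2 <- !is.na(mc$mate) & mc$mate == 2L
    eff[!m2] <- flip(eff[!m2])
    informative <- TRUE
  } else {
    informative <- FALSE
  }
  mc$rstrand <- eff
  mc$informative <- rep(informative, length(reads))
  S4Vectors::mcols(reads) <- mc
  .sync_block_strand(reads)
}

#' Downsample a read set to a target depth
#'
#' Seeded sampling without replacement to exactly `target` mapped reads
#' (mates count individually).  For paired layouts, sampling is
#' pair-atomic: whole templates are kept or dropped, so the output never
#' contains exactly one mate of a pair; `target` must then be attainable
#' as a whole number of templates.
#'
#' @param reads a read set.
#' @param target number of reads to retain; must not exceed the read
#'   count.  `target == n_reads(reads)` passes the set through unchanged.
#' @param seed integer RNG seed (mandatory: discovery is depth-dependent,
#'   so unseeded sampling would break reproducibility).
#' @return the downsampled read set.
#' @export
downsample_reads <- function(reads, target, seed = 1L) {
  n <- length(reads)
  if (target > n)
    stop("target ", target, " exceeds available reads (", n, ")")
  if (target == n) return(reads)
  mc <- S4Vectors::mcols(reads)
  if (any(mc$paired)) {
    qn <- unique(mc$qname)
    per <- length(reads) / length(qn)          # ~2 for fully paired
    n_templates <- round(target / per)
    if (abs(n_templates * per - target) > 0.5)
      warning("pair-atomic sampling: retaining ", n_templates * per,
              " reads (nearest attainable to target ", target, ")")
    pick <- .seeded_sample(qn, n_templates, seed)
    reads[mc$qname %in% pick]
  } else {
    reads[sort(.seeded_sample(seq_len(n), target, seed))]
  }
}

# sample() under a local seed, leaving the global RNG untouched
.seeded_sample <- function(x, size, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  x[sample.int(length(x), size)]
}

#' Preprocess a set of samples to a common depth
#'
#' The per-dataset preparation step: infers each sample's library type,
#' normalizes strands, and downsamples every sample to a common target so
#' DoG discovery — which depends on depth through its continuous-coverage
#' criterion — is comparable across samples.  Both the strand-normalized
#' and the downsampled read sets are kept, so discovery can be re-run with
#' different parameters without repeating this step.
#'
#' @param samples named list of read sets (or SAM/BAM paths).
#' @param loci gene loci for strand inference.
#' @param target common depth: a read count, or `"auto"` (the minimum
#'   mapped-read count across the samples).
#' @param seed base RNG seed; sample `i` uses `seed + i - 1` so samples
#'   are sampled independently but reproducibly.
#' @param sample_size,threshold passed to [infer_library_type()].
#' @return a `sample_manifest`: per sample, a list with `name`, `spec`,
#'   `total_mapped`, `prep` (normalized reads), `ds` (downsampled reads),
#'   `target`, `seed`.
#' @export
preprocess_samples <- function(samples, loci, target = "auto", seed = 1L,
                               sample_size = 200000, threshold = 0.8) {
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("sample", seq_along(samples))
  samples <- lapply(samples, function(s)
    if (is.character(s)) read_alignments(s) else s)
  totals <- vapply(samples, length, integer(1))
  if (identical(target, "auto")) target <- min(totals)
  target <- as.integer(target)
  if (any(target > totals))
    stop("target ", target, " exceeds mapped reads of sample(s): ",
         paste(names(samples)[target > totals], collapse = ", "))
  out <- lapply(seq_along(samples), function(i) {
    spec <- infer_library_type(samples[[i]], loci,
                               sample_size = sample_size,
                               threshold = threshold)
    prep <- normalize_strand(samples[[i]], spec)
    ds <- downsample_reads(prep, target, seed = seed + i - 1L)
    list(name = names(samples)[i], spec = spec,
         total_mapped = totals[[i]], prep = prep, ds = ds,
         target = target, seed = seed + i - 1L)
  })
  names(out) <- names(samples)
  structure(out, class = "sample_manifest")
}
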