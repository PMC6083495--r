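#' Build a most-inclusive gene-loci annotation from GTF sources
#'
#' For each annotation source, every gene's locus is the most inclusive
#' extent (minimum start to maximum end) over all its features on one
#' chromosome and strand.  Across sources, loci on the same chromosome and
#' strand that overlap by at least 1 bp are merged into a single locus
#' spanning their union — whether they carry the same identifier in both
#' sources or are distinct overlapping genes (read density inside another
#' gene cannot be attributed to readthrough unambiguously, so such regions
#' are treated as genic as a whole).  The merged locus takes the
#' identifier of its longest contributor; other identifiers are recorded
#' as aliases.
#'
#' @param sources character vector of GTF paths, or a list of `GRanges`
#'   as returned by [read_gtf()].
#' @return a sorted `GRanges` with metadata columns `gene_id`, `aliases`
#'   (comma-separated, `""` if none) and `source_count` (number of sources
#'   contributing).
#' @export
build_loci <- function(sources) {
  if (length(sources) == 0) stop("at least one annotation source required")
  if (is.character(sources)) sources <- lapply(sources, read_gtf)
  per_source <- lapply(seq_along(sources), function(i) {
    gr <- sources[[i]]
    if (length(gr) == 0) return(NULL)
    key <- paste(S4Vectors::mcols(gr)$gene_id,
                 as.character(GenomeInfoDb::seqnames(gr)),
                 as.character(BiocGenerics::strand(gr)), sep = "\r")
    sp <- split(seq_along(gr), key)
    loci <- GenomicRanges::GRanges(
      seqnames = vapply(sp, function(j)
        as.character(GenomeInfoDb::seqnames(gr))[j[1]], character(1)),
      ranges = IRanges::IRanges(
        start = vapply(sp, function(j)
          min(BiocGenerics::start(gr)[j]), numeric(1)),
        end = vapply(sp, function(j)
          max(BiocGenerics::end(gr)[j]), numeric(1))),
      strand = vapply(sp, function(j)
        as.character(BiocGenerics::strand(gr))[j[1]], character(1)),
      gene_id = vapply(sp, function(j)
        S4Vectors::mcols(gr)$gene_id[j[1]], character(1)),
      source = i)
    names(loci) <- NULL
    loci
  })
  all_loci <- suppressWarnings(
    do.call(c, per_source[!vapply(per_source, is.null, logical(1))]))
  if (is.null(all_loci) || length(all_loci) == 0)
    stop("no usable annotation records in any source")
  merged <- GenomicRanges::reduce(all_loci, min.gapwidth = 0L,
                                  with.revmap = TRUE,
                                  ignore.strand = FALSE)
  revmap <- S4Vectors::mcols(merged)$revmap
  mc <- lapply(revmap, function(j) {
    w <- BiocGenerics::width(all_loci)[j]
    ids <- S4Vectors::mcols(all_loci)$gene_id[j]
    main <- ids[which.max(w)]
    list(gene_id = main,
         aliases = paste(sort(unique(setdiff(ids, main))), collapse = ","),
         source_count = length(unique(S4Vectors::mcols(all_loci)$source[j])))
  })
  S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
    gene_id = vapply(mc, `[[`, character(1), "gene_id"),
    aliases = vapply(mc, `[[`, character(1), "aliases"),
    source_count = vapply(mc, `[[`, integer(1), "source_count"))
  BiocGenerics::sort(merged, ignore.strand = TRUE)
}

#' Boundary of the nearest 3' neighboring locus
#'
#' For each query locus, the boundary coordinate (inter-base, BED-style) of
#' the nearest other locus lying 3' of the query's 3' end: the neighbor's
#' start for a `+` query, its end for a `-` query.  Loci that overlap the
#' query and extend past its 3' end count as neighbors (the available room
#' downstream is then clamped to zero by [eligible_genes()]).  With
#' `stranded = TRUE` only same-strand loci constrain; with `FALSE` all loci
#' do, as appropriate for unstranded libraries.
#'
#' @param loci a `GRanges` of gene loci (typically from [build_loci()]).
#' @param query integer indices into `loci` (default: all).
#' @param stranded restrict to same-strand neighbors?
#' @return numeric vector of boundary positions, `NA` where no 3' neighbor
#'   exists on the chromosome.
#' @export
nearest_downstream_neighbor <- function(loci, query = seq_along(loci),
                                        stranded = TRUE) {
  chrom <- as.character(GenomeInfoDb::seqnames(loci))
  str <- as.character(BiocGenerics::strand(loci))
  start_bed <- BiocGenerics::start(loci) - 1
  end_bed <- BiocGenerics::end(loci)
  a <- three_prime_end(loci)
  out <- rep(NA_real_, length(query))
  grp_all <- if (stranded) paste(chrom, str) else chrom
  for (g in unique(grp_all[query])) {
    cand <- which(grp_all == g)
    qs <- which(grp_all[query] == g)
    # '+' queries: nearest start among loci extending past the 3' end
    ord_e <- cand[order(end_bed[cand])]
    sufmin <- rev(cummin(rev(start_bed[ord_e])))
    # '-' queries: furthest end among loci beginning before the 3' end
    ord_s <- cand[order(start_bed[cand])]
    prefmax <- cummax(end_bed[ord_s])
    for (k in qs) {
      q <- query[k]
      if (str[q] == "+") {
        idx <- findInterval(a[q], end_bed[ord_e]) + 1L
        if (idx <= length(ord_e)) out[k] <- sufmin[idx]
      } else {
        idx <- findInterval(a[q] - 0.5, start_bed[ord_s])
        if (idx >= 1L) out[k] <- prefmax[idx]
      }
    }
  }
  out
}

#' Genes with room for a DoG
#'
#' Applies the discard rule: a gene is eligible for DoG discovery only if
#' the strand-oriented distance from its 3' end to the nearest 3' neighbor
#' boundary (or, absent a neighbor, to the chromosome boundary) is at least
#' `min_dog_len`.  A neighbor overlapping the query clamps the room to 0.
#'
#' @param loci a `GRanges` of gene loci.
#' @param params a [dog_params()] object.
#' @param stranded use same-strand neighbors only?
#' @param chrom_len named vector of chromosome lengths (required for `+`
#'   genes with no downstream neighbor; defaults to `seqlengths(loci)`).
#' @return the eligible subset of `loci` with extra metadata columns
#'   `limit` (boundary position capping the DoG) and `room` (bp available).
#' @export
eligible_genes <- function(loci, params, stranded = TRUE,
                           chrom_len = NULL) {
  if (length(loci) == 0) return(loci)
  if (is.null(chrom_len)) chrom_len <- GenomeInfoDb::seqlengths(loci)
  chrom <- as.character(GenomeInfoDb::seqnames(loci))
  str <- as.character(BiocGenerics::strand(loci))
  a <- three_prime_end(loci)
  nb <- nearest_downstream_neighbor(loci, stranded = stranded)
  cl <- as.numeric(chrom_len[chrom])
  if (anyNA(cl) && any(is.na(nb) & str == "+" & is.na(cl)))
    stop("chromosome lengths needed for genes with no 3' neighbor")
  limit <- ifelse(is.na(nb), ifelse(str == "+", cl, 0), nb)
  room <- pmax(0, ifelse(str == "+", limit - a, a - limit))
  keep <- room >= params$min_dog_len
  out <- loci[keep]
  S4Vectors::mcols(out)$limit <- limit[keep]
  S4Vectors::mcols(out)$room <- room[keep]
  out
}
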