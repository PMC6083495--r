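#' Count reads overlapping a DoG annotation
#'
#' Number of alignment records with at least 1 bp of block overlap with
#' each DoG interval; each mate counts once.  For stranded libraries only
#' reads whose effective strand matches the DoG strand count; for
#' unstranded libraries any strand counts.
#'
#' @param reads a strand-normalized read set.
#' @param dogs a `GRanges` of DoG records.
#' @param spec a `library_spec` (or `NULL` with `stranded` set directly).
#' @param stranded logical override used when `spec` is `NULL`.
#' @return integer vector of counts parallel to `dogs`.
#' @export
count_dog_reads <- function(reads, dogs, spec = NULL, stranded = NULL) {
  if (is.null(stranded)) {
    stranded <- if (is.null(spec)) TRUE
                else spec$strandedness != "unstranded"
  }
  GenomicRanges::countOverlaps(dogs, reads, ignore.strand = !stranded)
}

#' DoG expression as RPKM
#'
#' Reads per kilobase of DoG per million mapped reads:
#' `rpkm = count / ((length/1000) * (total_mapped/1e6))`.  The denominator
#' is the mapped-read count of the supplied (pre-processed, downsampled)
#' read set, so cross-sample RPKMs share the normalization the
#' depth-equalization step established.  Genic-read filtering is *not*
#' applied here by default — it belongs to discovery, not quantification —
#' but can be requested.
#'
#' @param reads the sample's read set.
#' @param dogs a `GRanges` of DoG records (any annotation: per-sample,
#'   common, or union).
#' @param spec,stranded as in [count_dog_reads()].
#' @param total_mapped denominator; defaults to `n_reads(reads)`.
#' @param exclude_genic drop reads overlapping `loci` before counting.
#' @param loci gene loci, required when `exclude_genic = TRUE`.
#' @return `dogs` with metadata columns `read_count`, `total_mapped` and
#'   `rpkm`, in the input annotation order.
#' @export
compute_rpkm <- function(reads, dogs, spec = NULL, stranded = NULL,
                         total_mapped = NULL, exclude_genic = FALSE,
                         loci = NULL) {
  if (is.null(total_mapped)) total_mapped <- n_reads(reads)
  if (total_mapped == 0) stop("total_mapped is zero")
  if (exclude_genic) {
    if (is.null(loci)) stop("exclude_genic = TRUE requires loci")
    st <- if (is.null(stranded)) {
      if (is.null(spec)) TRUE else spec$strandedness != "unstranded"
    } else stranded
    reads <- filter_genic_reads(reads, loci, stranded = st)
  }
  counts <- count_dog_reads(reads, dogs, spec = spec, stranded = stranded)
  len <- BiocGenerics::width(dogs)
  S4Vectors::mcols(dogs)$dog_length <- len
  S4Vectors::mcols(dogs)$read_count <- counts
  S4Vectors::mcols(dogs)$total_mapped <- total_mapped
  S4Vectors::mcols(dogs)$rpkm <-
    counts / ((len / 1000) * (total_mapped / 1e6))
  dogs
}
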