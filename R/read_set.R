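#' In-memory set of mapped reads
#'
#' A read set holds one entry per mapped alignment record (one mate of a
#' pair, or one single-end read), reduced to its splice-aware aligned
#' blocks plus strand and pairing flags.  It is implemented as a
#' [GenomicAlignments::GRangesList] (one element per read, one range per
#' aligned block) with per-read metadata columns:
#'
#' * `qname` — read/template name (shared by the two mates of a pair)
#' * `mate` — `1L`, `2L`, or `NA` for single-end
#' * `paired` — logical
#' * `strand` — the read's current strand as a character: the raw mapped
#'   strand until [normalize_strand()] is applied, the effective
#'   transcription strand afterwards
#' * `informative` — `NA` before normalization; afterwards `TRUE` for
#'   stranded protocols, `FALSE` when the library is unstranded (strand
#'   kept but not used for strand-specific logic)
#'
#' The inner ranges' strand is kept in sync with the `strand` column.
#'
#' @param blocks a `GRangesList` of aligned blocks, one element per read.
#' @param qname,mate,paired,strand,informative per-read metadata (recycled
#'   where length 1).
#' @param seqlengths optional named chromosome lengths.
#' @return the annotated `GRangesList` (class unchanged).
#' @export
read_set <- function(blocks, qname, strand, mate = NA_integer_,
                     paired = FALSE, informative = NA,
                     seqlengths = NULL) {
  n <- length(blocks)
  stopifnot(all(strand %in% c("+", "-")))
  df <- S4Vectors::DataFrame(
    qname = rep_len(as.character(qname), n),
    mate = rep_len(as.integer(mate), n),
    paired = rep_len(as.logical(paired), n),
    rstrand = rep_len(as.character(strand), n),
    informative = rep_len(as.logical(informative), n))
  S4Vectors::mcols(blocks) <- df
  blocks <- .sync_block_strand(blocks)
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(blocks) <- names(seqlengths)
    GenomeInfoDb::seqlengths(blocks) <- seqlengths
  }
  blocks
}

# push the per-read strand column down onto the aligned blocks
.sync_block_strand <- function(reads) {
  if (length(reads) == 0) return(reads)
  widths <- S4Vectors::elementNROWS(reads)
  flat <- BiocGenerics::unlist(reads, use.names = FALSE)
  BiocGenerics::strand(flat) <- rep(S4Vectors::mcols(reads)$rstrand, widths)
  out <- BiocGenerics::relist(flat, reads)
  S4Vectors::mcols(out) <- S4Vectors::mcols(reads)
  out
}

#' Number of mapped reads in a read set
#' @param reads a read set (see [read_set()]).
#' @return integer count of alignment records (mates count separately).
#' @export
n_reads <- function(reads) length(reads)

#' Flattened aligned blocks of a read set
#'
#' @param reads a read set.
#' @return a `GRanges` of all aligned blocks, strand set to each read's
#'   current strand.
#' @export
read_blocks <- function(reads) BiocGenerics::unlist(reads, use.names = FALSE)

#' Per-read strand of a read set
#' @param reads a read set.
#' @return character vector of `"+"`/`"-"`.
#' @export
read_strand <- function(reads) S4Vectors::mcols(reads)$rstrand
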