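# Shared machinery for union/intersection of DoG annotation sets.
# Membership is keyed by gene_id: every DoG is anchored to one gene by
# construction, so replicate/treatment comparisons are gene-level.
.combine_dogs <- function(sets, keep_ids, combine = c("max", "min")) {
  combine <- match.arg(combine)
  all_rec <- do.call(rbind, lapply(sets, function(s) data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(s)),
    start = BiocGenerics::start(s) - 1,
    end = BiocGenerics::end(s),
    strand = as.character(BiocGenerics::strand(s)),
    gene_id = S4Vectors::mcols(s)$gene_id)))
  all_rec <- all_rec[all_rec$gene_id %in% keep_ids, , drop = FALSE]
  if (nrow(all_rec) == 0)
    return(dog_records(character(), numeric(), numeric(), character(),
                       character()))
  sp <- split(all_rec, all_rec$gene_id)
  rows <- lapply(sp, function(g) {
    if (length(unique(g$strand)) != 1)
      stop("gene ", g$gene_id[1],
           " has conflicting strands across DoG files")
    if (length(unique(g$chrom)) != 1)
      stop("gene ", g$gene_id[1],
           " appears on different chromosomes across DoG files")
    plus <- g$strand[1] == "+"
    # most-downstream rule: extremal far end, anchor side preserved
    if (combine == "max") {
      if (plus) g$end[1] <- max(g$end) else g$start[1] <- min(g$start)
    } else {
      if (plus) g$end[1] <- min(g$end) else g$start[1] <- max(g$start)
    }
    g[1, , drop = FALSE]
  })
  df <- do.call(rbind, rows)
  dogs <- dog_records(df$chrom, df$start, df$end, df$strand, df$gene_id)
  BiocGenerics::sort(dogs, ignore.strand = TRUE)
}

#' Union of DoG annotation sets
#'
#' Merges DoG annotations from several samples (replicates, treatments)
#' into one: a gene appearing in any input contributes one record whose
#' far end is the most downstream coordinate observed for it — maximum end
#' on `+`, minimum start on `-` — with the gene-3'-end anchor preserved.
#'
#' @param sets a list of DoG `GRanges` (each with unique `gene_id`s, as
#'   produced by [discover_dogs()] or [read_bed()]).
#' @return a sorted `GRanges` of combined DoG records.
#' @export
union_dogs <- function(sets) {
  stopifnot(length(sets) >= 1)
  ids <- unique(unlist(lapply(sets, function(s)
    S4Vectors::mcols(s)$gene_id)))
  .combine_dogs(sets, ids, combine = "max")
}

#' Intersection of DoG annotation sets
#'
#' Keeps only genes whose DoG appears in every input set (e.g. DoGs common
#' to all biological replicates); ends are combined by the same
#' most-downstream rule as [union_dogs()] unless `combine = "min"` is
#' requested (minimal common extent).
#'
#' @param sets a list of two or more DoG `GRanges`.
#' @param combine `"max"` (most-downstream end, default) or `"min"`.
#' @return a sorted `GRanges` of the common DoG records.
#' @export
common_dogs <- function(sets, combine = c("max", "min")) {
  if (length(sets) < 2)
    stop("intersection needs at least two DoG sets")
  id_lists <- lapply(sets, function(s) S4Vectors::mcols(s)$gene_id)
  ids <- Reduce(intersect, id_lists)
  .combine_dogs(sets, ids, combine = match.arg(combine))
}
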