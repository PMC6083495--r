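#' Read a GTF annotation
#'
#' Parses a GTF file through [rtracklayer::import()] and returns the
#' transcript-level features usable for locus building.  Coordinates come
#' back in the standard Bioconductor 1-based representation (the GTF's
#' 1-based closed intervals are preserved; BED-style numbers appear only in
#' BED output).  Features without a parseable gene identifier (`gene_id`,
#' falling back to `gene_name`) and strandless features are skipped with a
#' warning.
#'
#' @param path GTF file path.
#' @param feature_types feature types to keep; features of other types are
#'   ignored.  Default keeps transcript- and exon-level rows (plus `gene`
#'   rows, harmless because locus building takes per-gene extents).
#' @return a `GRanges` with metadata columns `type`, `gene_id`,
#'   `transcript_id`.
#' @export
read_gtf <- function(path,
                     feature_types = c("gene", "transcript", "exon")) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
    type = character(0), gene_id = character(0),
    transcript_id = character(0))
  if (!any(nzchar(grep("^[^#]", readLines(path), value = TRUE))))
    return(empty)
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) return(empty)
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(S4Vectors::mcols(gr)$type) %in% feature_types]
  mc <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
         else rep(NA_character_, length(gr))
  if ("gene_name" %in% names(mc)) {
    fallback <- as.character(mc$gene_name)
    gid[is.na(gid) | !nzchar(gid)] <- fallback[is.na(gid) | !nzchar(gid)]
  }
  bad_id <- is.na(gid) | !nzchar(gid)
  if (any(bad_id))
    warning(sum(bad_id), " GTF record(s) without a gene identifier skipped")
  bad_strand <- as.character(BiocGenerics::strand(gr)) == "*"
  if (any(bad_strand & !bad_id))
    warning(sum(bad_strand & !bad_id),
            " strandless GTF record(s) skipped")
  keep <- !bad_id & !bad_strand
  gr <- gr[keep]
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    type = as.character(S4Vectors::mcols(gr)$type),
    gene_id = gid[keep],
    transcript_id = if ("transcript_id" %in% names(mc))
      as.character(S4Vectors::mcols(gr)$transcript_id)
    else rep(NA_character_, length(gr)))
  out
}

#' Read a BED6 annotation of loci or DoGs
#'
#' Requires at least six columns; the `name` column is interpreted as the
#' gene identifier and `score` is ignored.  `track`/`browser` header lines
#' are tolerated.
#'
#' @param path BED file path.
#' @return a `GRanges` with metadata columns `gene_id` and `dog_length`
#'   (the interval width; meaningful for DoG files, harmless for loci).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(body) == 0) {
    return(dog_records(character(), numeric(), numeric(),
                       character(), character())[0])
  }
  nfield <- length(strsplit(body[[1]], "\t", fixed = TRUE)[[1]])
  if (nfield < 6)
    stop("BED file has ", nfield,
         " columns; need >= 6 (column 6 = strand is required)")
  gr <- rtracklayer::import(path, format = "bed")
  if (any(as.character(BiocGenerics::strand(gr)) == "*"))
    stop("BED records without strand are not usable here")
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = as.character(S4Vectors::mcols(gr)$name),
    dog_length = BiocGenerics::width(out))
  out
}

#' Write loci or DoG records as BED6
#'
#' Records are sorted by (chromosome, start) and written 0-based half-open;
#' `name` carries the gene identifier, `score` is 0.  The output
#' round-trips losslessly through [read_bed()].
#'
#' @param records a `GRanges` with a `gene_id` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  if (length(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ord <- order(as.character(GenomeInfoDb::seqnames(records)),
               BiocGenerics::start(records), BiocGenerics::end(records))
  records <- records[ord]
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(records)),
    start = format(BiocGenerics::start(records) - 1, scientific = FALSE,
                   trim = TRUE),
    end = format(BiocGenerics::end(records), scientific = FALSE,
                 trim = TRUE),
    name = S4Vectors::mcols(records)$gene_id,
    score = 0L,
    strand = as.character(BiocGenerics::strand(records)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read mapped alignments from SAM or BAM
#'
#' Loads genome-mapped alignments into a read set (see [read_set()]),
#' excluding unmapped, secondary and supplementary records, and decomposing
#' spliced alignments (CIGAR `N`) into aligned blocks.  SAM input and
#' unsorted/unindexed BAM are converted, sorted and indexed into temporary
#' files transparently.  The strand stored is the raw mapped strand;
#' protocol normalization is a separate step ([normalize_strand()]).
#'
#' @param path SAM or BAM file.
#' @param drop_duplicates drop records flagged as PCR/optical duplicates
#'   (default `FALSE`: duplicates are retained).
#' @return a read set; its `metadata()$total_mapped` is the number of
#'   mapped records kept.
#' @export
read_alignments <- function(path, drop_duplicates = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  sorted <- Rsamtools::sortBam(bam, tempfile())
  Rsamtools::indexBam(sorted)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (drop_duplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("qname", "flag"))
  gal <- GenomicAlignments::readGAlignments(sorted, param = param)
  flagv <- S4Vectors::mcols(gal)$flag
  paired <- bitwAnd(flagv, 1L) > 0L
  mate <- ifelse(bitwAnd(flagv, 64L) > 0L, 1L,
                 ifelse(bitwAnd(flagv, 128L) > 0L, 2L, NA_integer_))
  mate[!paired] <- NA_integer_
  blocks <- GenomicAlignments::grglist(gal)
  reads <- read_set(blocks,
                    qname = S4Vectors::mcols(gal)$qname,
                    strand = as.character(BiocGenerics::strand(gal)),
                    mate = mate, paired = paired)
  S4Vectors::metadata(reads)$total_mapped <- length(gal)
  reads
}

# CIGAR string for a read's aligned blocks: M runs separated by N skips
.blocks_to_cigar <- function(starts, ends) {
  n <- length(starts)
  cig <- sprintf("%dM", ends[1] - starts[1] + 1)
  if (n > 1) {
    for (i in 2:n) {
      cig <- paste0(cig, sprintf("%dN%dM",
                                 starts[i] - ends[i - 1] - 1,
                                 ends[i] - starts[i] + 1))
    }
  }
  cig
}

#' Write a read set as a SAM file
#'
#' Emits a coordinate-sorted SAM with `@SQ` lines from the read set's
#' `seqlengths`.  Flags encode pairing, mate index, and the *raw* mapped
#' strand, so the output feeds back through [read_alignments()].  Sequences
#' and qualities are written as `*` (the pipeline never uses them).
#'
#' @param reads a read set carrying raw mapped strands.
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path) {
  sl <- GenomeInfoDb::seqlengths(reads)
  if (anyNA(sl) || length(sl) == 0)
    stop("write_sam requires seqlengths on the read set")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
  if (length(reads) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  mc <- S4Vectors::mcols(reads)
  flat <- BiocGenerics::unlist(reads, use.names = FALSE)
  first <- cumsum(c(1L, utils::head(S4Vectors::elementNROWS(reads), -1L)))
  chrom <- as.character(GenomeInfoDb::seqnames(flat))[first]
  pos <- BiocGenerics::start(flat)[first]      # leftmost aligned base
  ord <- order(match(chrom, names(sl)), pos)
  flag <- integer(length(reads))
  paired <- mc$paired
  flag[paired] <- flag[paired] + 1L + 2L
  flag[mc$rstrand == "-"] <- flag[mc$rstrand == "-"] + 16L
  flag[paired & mc$mate == 1L] <- flag[paired & mc$mate == 1L] + 64L
  flag[paired & mc$mate == 2L] <- flag[paired & mc$mate == 2L] + 128L
  # mate strand / position by qname lookup (pairs share qname)
  rnext <- rep("*", length(reads))
  pnext <- integer(length(reads))
  if (any(paired)) {
    key <- paste0(mc$qname, "/", 3L - mc$mate)
    own <- paste0(mc$qname, "/", mc$mate)
    idx <- match(key, own)
    has_mate <- paired & !is.na(idx)
    mate_rev <- which(has_mate)[mc$rstrand[idx[has_mate]] == "-"]
    flag[mate_rev] <- flag[mate_rev] + 32L
    rnext[has_mate] <- "="
    pnext[has_mate] <- pos[idx[has_mate]]
  }
  cig <- vapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    .blocks_to_cigar(BiocGenerics::start(r), BiocGenerics::end(r))
  }, character(1))
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t0\t*\t*",
                   mc$qname, flag, chrom, pos, cig, rnext, pnext)
  writeLines(c(hdr, lines[ord]), path)
  invisible(path)
}

#' Write a DoG expression table
#'
#' Tab-delimited text with a header row; columns `chrom`, `start`, `end`
#' (BED convention), `gene_id`, `strand`, `dog_length`, `rpkm` (printed
#' with 4 decimals).
#'
#' @param expr a `GRanges` of DoG records with metadata columns `gene_id`,
#'   `dog_length` and `rpkm` (as produced by [compute_rpkm()]).
#' @param path output path (`.tsv` by convention; `.csv` accepted).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(expr)),
    start = BiocGenerics::start(expr) - 1,
    end = BiocGenerics::end(expr),
    gene_id = S4Vectors::mcols(expr)$gene_id,
    strand = as.character(BiocGenerics::strand(expr)),
    dog_length = S4Vectors::mcols(expr)$dog_length,
    rpkm = sprintf("%.4f", S4Vectors::mcols(expr)$rpkm))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
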