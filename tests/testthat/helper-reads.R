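# Build a read set from plain BED-style vectors (one block per read).
mk_reads <- function(chrom, start0, end0, strand, seqlen,
                     qname = NULL, mate = NA_integer_, paired = FALSE,
                     informative = TRUE) {
  n <- length(start0)
  if (is.null(qname)) qname <- sprintf("q%05d", seq_len(n))
  gr <- GenomicRanges::GRanges(
    rep_len(chrom, n),
    IRanges::IRanges(start = start0 + 1, end = end0),
    strand = rep_len(strand, n))
  grl <- S4Vectors::split(gr, factor(seq_len(n), levels = seq_len(n)))
  names(grl) <- NULL
  r <- read_set(grl, qname = qname, strand = rep_len(strand, n),
                mate = mate, paired = paired, informative = informative,
                seqlengths = seqlen)
  S4Vectors::metadata(r)$total_mapped <- n
  r
}

# One multi-block (spliced) read.
mk_spliced_read <- function(chrom, starts0, ends0, strand, seqlen,
                            qname = "spliced1") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts0 + 1, end = ends0),
    strand = strand)
  grl <- GenomicRanges::GRangesList(gr)
  names(grl) <- NULL
  read_set(grl, qname = qname, strand = strand, informative = TRUE,
           seqlengths = seqlen)
}

# Dense single-end coverage of [start0, end0) with reads of read_len,
# stepped so every base is covered.
mk_tiling_reads <- function(chrom, start0, end0, strand, seqlen,
                            read_len = 100, by = 50) {
  s <- seq(start0, end0 - read_len, by = by)
  s <- unique(c(s, end0 - read_len))
  mk_reads(chrom, s, s + read_len, strand, seqlen)
}

bed_start <- function(gr) BiocGenerics::start(gr) - 1
bed_end <- function(gr) BiocGenerics::end(gr)
gr_strand <- function(gr) as.character(BiocGenerics::strand(gr))
gr_chrom <- function(gr) as.character(GenomeInfoDb::seqnames(gr))
gid <- function(gr) S4Vectors::mcols(gr)$gene_id
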