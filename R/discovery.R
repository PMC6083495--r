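#' Remove genic reads
#'
#' A read is genic — and removed — if any of its aligned blocks overlaps
#' any gene locus by at least 1 bp: same-effective-strand loci only for
#' stranded libraries, loci of either strand for unstranded ones.  DoG
#' discovery runs on the surviving non-genic reads only, so the signal is
#' not confounded by alternative isoforms or other annotated RNAs.
#'
#' @param reads a strand-normalized read set.
#' @param loci gene loci.
#' @param stranded match strands when testing overlap?
#' @return the non-genic subset of `reads`.
#' @export
filter_genic_reads <- function(reads, loci, stranded = TRUE) {
  if (length(reads) == 0 || length(loci) == 0) return(reads)
  hits <- GenomicRanges::findOverlaps(reads, loci,
                                      ignore.strand = !stranded)
  genic <- unique(S4Vectors::queryHits(hits))
  if (length(genic) == 0) reads else reads[-genic]
}

# Binary (0/1) coverage Rle per chromosome for one strand class.
# Returns list: key "+"/"-"/"any" -> named list of integer Rle per chrom.
.coverage_index <- function(reads, chrom_len, stranded) {
  blocks <- read_blocks(reads)
  keys <- if (stranded) c("+", "-") else "any"
  idx <- list()
  for (key in keys) {
    b <- if (key == "any") blocks
         else blocks[as.character(BiocGenerics::strand(blocks)) == key]
    per_chrom <- list()
    for (ch in names(chrom_len)) {
      bc <- b[as.character(GenomeInfoDb::seqnames(b)) == ch]
      ir <- IRanges::reduce(IRanges::ranges(bc))
      cov <- IRanges::coverage(ir, width = chrom_len[[ch]])
      per_chrom[[ch]] <- S4Vectors::Rle(as.integer(cov > 0))
    }
    idx[[key]] <- per_chrom
  }
  idx
}

# Covered bases within 1-based closed windows [starts1, ends1] on one
# chromosome/strand-class; zero-length windows yield 0.
.covered_bases <- function(idx, key, chrom, starts1, ends1) {
  bin <- idx[[key]][[chrom]]
  if (is.null(bin)) return(numeric(length(starts1)))
  ok <- ends1 >= starts1
  out <- numeric(length(starts1))
  if (any(ok))
    out[ok] <- IRanges::viewSums(
      IRanges::Views(bin, start = starts1[ok], end = ends1[ok]))
  out
}

#' Coverage breadth of an interval
#'
#' Fraction of base positions in `interval` covered by at least one
#' aligned block of a strand-matching read (depth beyond 1 does not count
#' extra; splice gaps contribute nothing).
#'
#' @param reads a read set.
#' @param interval a length-1 `GRanges`.
#' @param strand `"+"`, `"-"` (match effective read strand) or `"any"`.
#' @return covered fraction in \[0, 1\].
#' @export
coverage_fraction <- function(reads, interval, strand = "any") {
  stopifnot(length(interval) == 1, BiocGenerics::width(interval) > 0)
  blocks <- read_blocks(reads)
  if (strand != "any")
    blocks <- blocks[as.character(BiocGenerics::strand(blocks)) == strand]
  blocks <- blocks[as.character(GenomeInfoDb::seqnames(blocks)) ==
                     as.character(GenomeInfoDb::seqnames(interval))]
  ir <- IRanges::reduce(IRanges::ranges(blocks))
  hit <- IRanges::restrict(ir, start = BiocGenerics::start(interval),
                           end = BiocGenerics::end(interval))
  sum(BiocGenerics::width(hit)) / BiocGenerics::width(interval)
}

# Endpoint offset (bp downstream of the 3' end) for one eligible gene, or
# NA when no candidate.  All coordinates 0-based boundaries.
.call_gene <- function(idx, key, chrom, a, dir, room, params) {
  minLen <- params$min_dog_len
  win <- params$window_len
  step <- params$window_step
  w1 <- function(lo, hi) .covered_bases(idx, key, chrom, lo + 1, hi)
  init <- if (dir > 0) w1(a, a + minLen) else w1(a - minLen, a)
  if (init / minLen < params$min_dog_cov) return(NA_real_)
  if (room <= minLen) return(minLen)
  offs <- seq(minLen, room - 1, by = step)         # window start offsets
  w_eff <- pmin(win, room - offs)
  lo <- if (dir > 0) a + offs else a - offs - w_eff
  hi <- if (dir > 0) a + offs + w_eff else a - offs
  covered <- .covered_bases(idx, key, chrom, lo + 1, hi)
  pass <- covered / w_eff >= params$min_dog_cov
  fail <- which(!pass)
  j <- if (length(fail) == 0) length(offs) else fail[1] - 1L
  if (j == 0) minLen else offs[j] + w_eff[j]
}

#' Discover DoGs in one sample
#'
#' For every eligible gene (3' neighbor room of at least `min_dog_len`;
#' closer neighbors disqualify the gene), tests whether the initial
#' `min_dog_len` bases downstream of the gene's 3' end reach coverage
#' breadth `min_dog_cov` over the non-genic reads, then elongates the
#' candidate in overlapping running windows (`window_len` wide, advancing
#' by `window_step`) until coverage drops below `min_dog_cov` or the
#' neighbor/chromosome limit is reached.  One DoG at most per gene.
#'
#' For stranded libraries, coverage and neighbor limits use reads and loci
#' of the matching strand; for unstranded libraries coverage is
#' strand-blind and neighbors constrain regardless of strand.
#'
#' @param reads a strand-normalized (and typically downsampled) read set.
#' @param loci gene loci from [build_loci()].
#' @param params a [dog_params()] object.
#' @param spec a `library_spec`, or `NULL` to pass `stranded` directly.
#' @param stranded logical override used when `spec` is `NULL`.
#' @param chrom_len named chromosome lengths; defaults to the read set's
#'   `seqlengths`.
#' @return a sorted `GRanges` of DoG records with metadata columns
#'   `gene_id` and `dog_length`.
#' @export
discover_dogs <- function(reads, loci, params = dog_params(),
                          spec = NULL, stranded = NULL,
                          chrom_len = NULL) {
  if (is.null(stranded)) {
    stranded <- if (is.null(spec)) TRUE
                else spec$strandedness != "unstranded"
  }
  if (is.null(chrom_len)) {
    chrom_len <- GenomeInfoDb::seqlengths(reads)
    if (length(chrom_len) == 0 || anyNA(chrom_len))
      stop("chromosome lengths unknown; supply chrom_len")
  }
  empty <- dog_records(character(), numeric(), numeric(), character(),
                       character())
  if (length(loci) == 0) return(empty)
  if (length(reads) > 0) {
    rchrom <- unique(as.character(GenomeInfoDb::seqnames(read_blocks(reads))))
    lchrom <- unique(as.character(GenomeInfoDb::seqnames(loci)))
    if (length(intersect(rchrom, lchrom)) == 0)
      stop("chromosome names of alignments (", rchrom[1],
           ", ...) and loci (", lchrom[1], ", ...) do not match; ",
           "rename one set (e.g. '1' vs 'chr1') so they agree")
  }
  elig <- eligible_genes(loci, params, stranded = stranded,
                         chrom_len = chrom_len)
  if (length(elig) == 0 || length(reads) == 0) return(empty)
  nongenic <- filter_genic_reads(reads, loci, stranded = stranded)
  idx <- .coverage_index(nongenic, chrom_len, stranded)
  chrom <- as.character(GenomeInfoDb::seqnames(elig))
  str <- as.character(BiocGenerics::strand(elig))
  a <- three_prime_end(elig)
  room <- S4Vectors::mcols(elig)$room
  ends <- vapply(seq_along(elig), function(i) {
    key <- if (stranded) str[i] else "any"
    .call_gene(idx, key, chrom[i], a[i],
               if (str[i] == "+") 1 else -1, room[i], params)
  }, numeric(1))
  hit <- !is.na(ends)
  if (!any(hit)) return(empty)
  plus <- str[hit] == "+"
  dogs <- dog_records(
    chrom = chrom[hit],
    start = ifelse(plus, a[hit], a[hit] - ends[hit]),
    end = ifelse(plus, a[hit] + ends[hit], a[hit]),
    strand = str[hit],
    gene_id = S4Vectors::mcols(elig)$gene_id[hit],
    seqlengths = chrom_len)
  BiocGenerics::sort(dogs, ignore.strand = TRUE)
}
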