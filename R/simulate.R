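# evaluate expr under a local RNG seed, restoring the global RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for a synthetic readthrough fixture
#'
#' Describes a multi-gene genome with configurable intergenic gaps,
#' per-gene expression depth, planted readthrough of known length and
#' coverage breadth on a chosen subset of genes, library layout and strand
#' protocol, and background noise — every regime the pipeline must handle,
#' with the ground truth known exactly.
#'
#' @param n_genes number of genes.
#' @param gene_len gene length (bp).
#' @param intergenic_gap gap between consecutive genes (bp); also the
#'   margin at both chromosome ends.
#' @param n_chroms number of chromosomes; genes are distributed evenly.
#' @param strands `"alternate"` (+,-,+,...), `"plus"`, `"minus"`,
#'   `"random"`, or an explicit character vector of one strand per gene.
#' @param expression_depth mean per-base read depth over gene bodies
#'   (scalar or per-gene).
#' @param readthrough_depth per-base read depth over the unmasked part of
#'   planted readthrough intervals (scalar or per-gene); defaults to
#'   `expression_depth`.  Real libraries are dominated by genic reads, so
#'   readthrough depth is typically set below body depth.
#' @param readthrough_len planted readthrough length downstream of each
#'   gene's 3' end (scalar or per-gene; 0 = none).
#' @param readthrough_breadth coverage breadth planted over the
#'   readthrough interval (scalar or per-gene).  Breadth is enforced
#'   periodically: within every `window_len`-sized segment of the
#'   readthrough the leading `breadth` fraction is covered and the rest
#'   masked, so any discovery window of that size sees exactly the
#'   configured breadth (see the methods vignette).
#' @param window_len the segment period used for breadth masking; keep
#'   equal to the `window_len` of the [dog_params()] the fixture is meant
#'   to exercise (default 200).
#' @param read_len read length (bp).
#' @param layout `"single"` or `"paired"`.
#' @param protocol `"forward"`, `"reverse"` or `"unstranded"`.
#' @param noise_rate background intergenic reads per kb of intergenic
#'   sequence.
#' @param insert_size paired-end outer distance (default `2 * read_len`).
#' @param seed mandatory RNG seed.
#' @param allow_collisions permit gaps too small to keep planted truths
#'   separable (used to exercise the neighbor discard rule).
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(n_genes = 4, gene_len = 2000,
                           intergenic_gap = 50000, n_chroms = 1,
                           strands = "alternate",
                           expression_depth = 10,
                           readthrough_depth = NULL,
                           readthrough_len = 0,
                           readthrough_breadth = 1.0,
                           window_len = 200,
                           read_len = 100,
                           layout = c("single", "paired"),
                           protocol = c("forward", "reverse",
                                        "unstranded"),
                           noise_rate = 0, insert_size = NULL,
                           seed, allow_collisions = FALSE) {
  if (missing(seed)) stop("a seed is mandatory for fixture generation")
  layout <- match.arg(layout)
  protocol <- match.arg(protocol)
  cfg <- list(
    n_genes = n_genes, gene_len = gene_len,
    intergenic_gap = intergenic_gap, n_chroms = n_chroms,
    strands = strands,
    expression_depth = rep_len(expression_depth, n_genes),
    readthrough_depth = rep_len(
      if (is.null(readthrough_depth)) expression_depth
      else readthrough_depth, n_genes),
    readthrough_len = rep_len(readthrough_len, n_genes),
    readthrough_breadth = rep_len(readthrough_breadth, n_genes),
    window_len = window_len,
    read_len = read_len, layout = layout, protocol = protocol,
    noise_rate = noise_rate,
    insert_size = if (is.null(insert_size)) 2L * read_len
                  else insert_size,
    seed = as.integer(seed))
  if (!allow_collisions &&
      intergenic_gap <= max(cfg$readthrough_len))
    stop("intergenic_gap must exceed the longest planted readthrough ",
         "(or set allow_collisions = TRUE)")
  if (gene_len < cfg$insert_size && layout == "paired")
    stop("gene_len shorter than the paired-end insert")
  structure(cfg, class = "fixture_config")
}

# uniform single-end reads across [lo, hi) (0-based); returns 0-based starts
.uniform_starts <- function(n, lo, hi, read_len) {
  if (n <= 0 || hi - lo < read_len) return(integer(0))
  lo + sample.int(hi - lo - read_len + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic fixture with planted readthrough
#'
#' Places genes deterministically from the configuration and samples reads
#' under the stated seed: uniform starts across each gene body; for
#' readthrough genes, reads tiled over the unmasked fraction of the
#' downstream interval; noise reads uniform over intergenic space.  The
#' same configuration and seed always produce the identical fixture.
#'
#' @param config a [fixture_config()].
#' @param params a [dog_params()] used only to annotate expected
#'   callability in the truth table.
#' @return a `dog_fixture` list: `loci` (gene annotation `GRanges`),
#'   `reads` (read set, raw strands), `truth` (data frame with the planted
#'   readthrough interval and expected callability per gene), `chrom_len`,
#'   `config`.
#' @export
generate_fixture <- function(config, params = dog_params()) {
  stopifnot(inherits(config, "fixture_config"))
  cfg <- config
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  chrom_len <- cfg$intergenic_gap +
    per_chrom * (cfg$gene_len + cfg$intergenic_gap)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  seqlen <- stats::setNames(rep(chrom_len, cfg$n_chroms), chroms)
  gi <- seq_len(cfg$n_genes) - 1L
  chrom <- chroms[gi %/% per_chrom + 1L]
  slot <- gi %% per_chrom
  gstart <- cfg$intergenic_gap +
    slot * (cfg$gene_len + cfg$intergenic_gap)      # 0-based
  gend <- gstart + cfg$gene_len
  strand <- if (length(cfg$strands) == cfg$n_genes &&
                all(cfg$strands %in% c("+", "-"))) {
    cfg$strands
  } else .with_seed(cfg$seed, switch(
    cfg$strands,
    alternate = rep(c("+", "-"), length.out = cfg$n_genes),
    plus = rep("+", cfg$n_genes),
    minus = rep("-", cfg$n_genes),
    random = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stop("unknown strand rule: ", cfg$strands)))
  gene_id <- sprintf("G%03d", seq_len(cfg$n_genes))
  loci <- gene_loci(chrom, gstart, gend, strand, gene_id,
                    seqlengths = seqlen)
  a <- three_prime_end(loci)

  rl <- cfg$read_len
  sim <- .with_seed(cfg$seed + 1L, {
    starts <- integer(0); lens <- integer(0); isrt <- logical(0)
    chs <- character(0); tstr <- character(0)
    for (i in seq_len(cfg$n_genes)) {
      n_body <- round(cfg$expression_depth[i] * cfg$gene_len / rl)
      s <- .uniform_starts(n_body, gstart[i], gend[i], rl)
      l <- rep(rl, length(s))
      # planted readthrough: periodic breadth masking.  The downstream
      # interval is split into window_len segments; within each, the
      # leading `breadth` fraction is paved with reads and the trailing
      # remainder left bare, so any window_len-sized discovery window
      # sees exactly the configured breadth.
      rt <- cfg$readthrough_len[i]
      if (rt > 0) {
        seg <- cfg$window_len
        seg_off <- seq(0, rt - 1, by = seg)
        seg_len <- pmin(seg, rt - seg_off)
        kept_len <- round(cfg$readthrough_breadth[i] * seg_len)
        n_per <- max(1L, round(cfg$readthrough_depth[i]))
        roff <- integer(0); rlen <- integer(0)
        for (k in seq_along(seg_off)) {
          pos <- 0L
          while (pos < kept_len[k]) {
            w <- min(rl, kept_len[k] - pos)
            roff <- c(roff, seg_off[k] + pos)
            rlen <- c(rlen, w)
            pos <- pos + w
          }
        }
        st0 <- if (strand[i] == "+") a[i] + roff
               else a[i] - roff - rlen
        s <- c(s, rep(st0, each = n_per))
        l <- c(l, rep(rlen, each = n_per))
      }
      starts <- c(starts, s)
      lens <- c(lens, l)
      isrt <- c(isrt, c(rep(FALSE, n_body), rep(TRUE, length(s) - n_body)))
      chs <- c(chs, rep(chrom[i], length(s)))
      tstr <- c(tstr, rep(strand[i], length(s)))
    }
    # intergenic noise, uniform over each chromosome's non-genic space
    if (cfg$noise_rate > 0) {
      for (ch in chroms) {
        on_ch <- which(chrom == ch)
        genic <- IRanges::IRanges(gstart[on_ch] + 1, gend[on_ch])
        inter <- IRanges::gaps(IRanges::reduce(genic),
                               start = 1, end = seqlen[[ch]])
        inter <- inter[BiocGenerics::width(inter) >= rl]
        n_noise <- round(cfg$noise_rate *
                           sum(BiocGenerics::width(inter)) / 1000)
        if (n_noise > 0) {
          iv <- sample.int(length(inter), n_noise, replace = TRUE,
                           prob = BiocGenerics::width(inter))
          s <- vapply(iv, function(j) .uniform_starts(
            1L, BiocGenerics::start(inter)[j] - 1L,
            BiocGenerics::end(inter)[j], rl), integer(1))
          starts <- c(starts, s)
          lens <- c(lens, rep(rl, n_noise))
          isrt <- c(isrt, rep(FALSE, n_noise))
          chs <- c(chs, rep(ch, n_noise))
          tstr <- c(tstr, sample(c("+", "-"), n_noise, replace = TRUE))
        }
      }
    }
    list(starts = starts, lens = lens, is_rt = isrt, chrom = chs,
         tstrand = tstr)
  })

  flipc <- function(s) ifelse(s == "+", "-", "+")
  n0 <- length(sim$starts)
  raw1 <- .with_seed(cfg$seed + 2L, switch(
    cfg$protocol,
    forward = sim$tstrand,
    reverse = flipc(sim$tstrand),
    unstranded = sample(c("+", "-"), n0, replace = TRUE)))
  if (cfg$layout == "single") {
    rchrom <- sim$chrom; rstart <- sim$starts
    rend <- rstart + sim$lens
    rstrand <- raw1
    qname <- sprintf("r%06d", seq_len(n0))
    mate <- NA_integer_; paired <- FALSE
  } else {
    # each sampled start seeds a template: mate1 there, mate2 at the
    # other end of the insert (clipped into the chromosome).  Truncated
    # breadth-masking reads get a fully overlapping mate so pairs never
    # leak coverage into masked positions.
    full <- sim$lens == rl & !sim$is_rt
    m2start <- ifelse(full,
                      pmin(sim$starts + cfg$insert_size - rl,
                           seqlen[sim$chrom] - rl),
                      sim$starts)
    rchrom <- rep(sim$chrom, 2)
    rstart <- c(sim$starts, m2start)
    rend <- rstart + c(sim$lens, sim$lens)
    rstrand <- c(raw1, flipc(raw1))
    qname <- rep(sprintf("t%06d", seq_len(n0)), 2)
    mate <- rep(c(1L, 2L), each = n0)
    paired <- TRUE
  }
  blocks <- GenomicRanges::GRanges(
    seqnames = rchrom,
    ranges = IRanges::IRanges(start = rstart + 1, end = rend),
    strand = rstrand)
  reads <- read_set(S4Vectors::split(
      blocks, factor(seq_along(blocks), levels = seq_along(blocks))),
                    qname = qname, strand = rstrand, mate = mate,
                    paired = paired, seqlengths = seqlen)
  names(reads) <- NULL
  S4Vectors::metadata(reads)$total_mapped <- length(reads)

  rt <- cfg$readthrough_len
  plus <- strand == "+"
  truth <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    three_prime = a,
    readthrough_len = rt,
    breadth = cfg$readthrough_breadth,
    depth = cfg$readthrough_depth,
    dog_start = ifelse(rt > 0, ifelse(plus, a, a - rt), NA),
    dog_end = ifelse(rt > 0, ifelse(plus, a + rt, a), NA),
    callable = rt >= params$min_dog_len &
      cfg$readthrough_breadth >= params$min_dog_cov)
  structure(list(loci = loci, reads = reads, truth = truth,
                 chrom_len = seqlen, config = cfg),
            class = "dog_fixture")
}

#' Write a fixture to disk
#'
#' Emits the gene annotation as GTF, the reads as coordinate-sorted SAM,
#' and the planted-truth intervals as BED6.
#'
#' @param fixture a `dog_fixture`.
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- file.path(dir, "genes.gtf")
  loci <- fixture$loci
  lines <- sprintf(
    "%s\tdogscan_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    as.character(GenomeInfoDb::seqnames(loci)),
    BiocGenerics::start(loci), BiocGenerics::end(loci),
    as.character(BiocGenerics::strand(loci)),
    S4Vectors::mcols(loci)$gene_id, S4Vectors::mcols(loci)$gene_id)
  writeLines(lines, gtf)
  sam <- file.path(dir, "reads.sam")
  write_sam(fixture$reads, sam)
  truth <- file.path(dir, "truth.bed")
  tr <- fixture$truth[fixture$truth$readthrough_len > 0, , drop = FALSE]
  write_bed(dog_records(tr$chrom, tr$dog_start, tr$dog_end, tr$strand,
                        tr$gene_id), truth)
  c(gtf = gtf, sam = sam, truth = truth)
}

#' Downsample one fixture to a series of depths
#'
#' Reproduces the depth-dependence experiment: the same genome and planted
#' truth observed at several library depths, via the seeded downsampler.
#'
#' @param fixture a `dog_fixture`.
#' @param targets ascending read-count targets.
#' @param seed RNG seed for the downsampler.
#' @return a named list of read sets, one per target.
#' @export
depth_series <- function(fixture, targets, seed = 1L) {
  stopifnot(!is.unsorted(targets))
  out <- lapply(seq_along(targets), function(i)
    downsample_reads(fixture$reads, targets[i], seed = seed))
  names(out) <- as.character(targets)
  out
}
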