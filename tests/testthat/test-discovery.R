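sl <- c(chr1 = 1e6)
loci2 <- gene_loci(c("chr1", "chr1"), c(10000, 200000), c(12000, 202000),
                   c("+", "-"), c("A", "B"), seqlengths = sl)

test_that("genic reads are removed, strand-aware", {
  reads <- mk_reads("chr1",
                    c(10500, 50000, 11900),
                    c(10600, 50100, 12100),
                    c("+", "+", "-"), sl)
  kept <- filter_genic_reads(reads, loci2, stranded = TRUE)
  # fully genic removed; intergenic kept; antisense overlap kept
  expect_equal(length(kept), 2)
  kept_u <- filter_genic_reads(reads, loci2, stranded = FALSE)
  expect_equal(length(kept_u), 1)
  expect_equal(bed_start(read_blocks(kept_u)), 50000)
})

test_that("coverage breadth counts covered bases once", {
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), "+")
  none <- mk_reads("chr1", numeric(0), numeric(0), character(0), sl)
  expect_equal(coverage_fraction(none, iv), 0)
  one <- mk_reads("chr1", 0, 5, "+", sl)
  expect_equal(coverage_fraction(one, iv), 0.5)
  two <- mk_reads("chr1", c(0, 4), c(6, 10), "+", sl)
  expect_equal(coverage_fraction(two, iv, strand = "+"), 1.0)
  expect_equal(coverage_fraction(two, iv, strand = "-"), 0)
  # splice gap contributes no coverage
  spl <- mk_spliced_read("chr1", c(0, 8), c(2, 10), "+", sl)
  expect_equal(coverage_fraction(spl, iv), 0.4)
})

# one + gene at [10000,12000) with coverage painted downstream of 12000:
# each covered segment is tiled with 100-bp reads so genic filtering can
# act on individual reads
paint_downstream <- function(segments, strand = "+") {
  s0 <- integer(0); e0 <- integer(0)
  for (seg in segments) {
    lo <- seg[1] + 12000; hi <- seg[2] + 12000
    st <- unique(c(seq(lo, max(lo, hi - 100), by = 100),
                   max(lo, hi - 100)))
    s0 <- c(s0, st); e0 <- c(e0, pmin(st + 100, hi))
  }
  mk_reads("chr1", s0, e0, strand, sl)
}
one_gene <- gene_loci("chr1", 10000, 12000, "+", "A", seqlengths = sl)
p1000 <- dog_params(min_dog_len = 1000, min_dog_cov = 0.6,
                    window_len = 200, window_step = 100)

test_that("candidate detection thresholds coverage inclusively", {
  # 70% of the initial 1000 bases
  dogs <- discover_dogs(paint_downstream(list(c(0, 700))), one_gene,
                        p1000, stranded = TRUE)
  expect_equal(length(dogs), 1)
  expect_equal(S4Vectors::mcols(dogs)$dog_length, 1000)
  # just under the threshold
  none <- discover_dogs(paint_downstream(list(c(0, 599))), one_gene,
                        p1000, stranded = TRUE)
  expect_equal(length(none), 0)
  # exactly at the threshold (inclusive)
  exact <- discover_dogs(paint_downstream(list(c(0, 600))), one_gene,
                         p1000, stranded = TRUE)
  expect_equal(length(exact), 1)
})

test_that("elongation follows continuous coverage and stops at gaps", {
  # full coverage for 9000 bp, no neighbor: end at +9000 exactly
  dogs <- discover_dogs(paint_downstream(list(c(0, 9000))), one_gene,
                        p1000, stranded = TRUE)
  expect_equal(S4Vectors::mcols(dogs)$dog_length, 9000)
  expect_equal(bed_start(dogs), 12000)
  # nothing beyond the initial interval: length exactly min_dog_len
  dogs <- discover_dogs(paint_downstream(list(c(0, 1000))), one_gene,
                        p1000, stranded = TRUE)
  expect_equal(S4Vectors::mcols(dogs)$dog_length, 1000)
})

test_that("DoGs truncate at the nearest 3' neighbor", {
  pair <- gene_loci("chr1", c(10000, 18000), c(12000, 20000),
                    c("+", "+"), c("A", "N"), seqlengths = sl)
  # coverage runs to and past the neighbor at +6000
  reads <- paint_downstream(list(c(0, 7000)))
  dogs <- discover_dogs(reads, pair, p1000, stranded = TRUE)
  dogs <- dogs[gid(dogs) == "A"]
  expect_equal(bed_end(dogs), 18000)
})

test_that("genes with a too-close 3' neighbor are discarded", {
  tight <- gene_loci("chr1", c(10000, 12500), c(12000, 14000),
                     c("+", "+"), c("A", "N"), seqlengths = sl)
  reads <- paint_downstream(list(c(0, 500)))
  dogs <- discover_dogs(reads, tight, p1000, stranded = TRUE)
  expect_false("A" %in% gid(dogs))
})

test_that("discovery on a planted fixture recovers exactly the truth", {
  cfg <- fixture_config(n_genes = 3, readthrough_len = c(8000, 0, 0),
                        expression_depth = 10, seed = 7)
  fx <- generate_fixture(cfg)
  spec <- library_spec("single", "forward")
  reads <- normalize_strand(fx$reads, spec)
  dogs <- discover_dogs(reads, fx$loci, dog_params(), spec = spec,
                        chrom_len = fx$chrom_len)
  expect_equal(length(dogs), 1)
  expect_equal(gid(dogs), "G001")
  expect_lte(abs(S4Vectors::mcols(dogs)$dog_length - 8000), 100)
  # empty alignment set
  none <- discover_dogs(reads[0], fx$loci, dog_params(), spec = spec,
                        chrom_len = fx$chrom_len)
  expect_equal(length(none), 0)
})

test_that("mismatched chromosome naming raises a rename hint", {
  reads <- mk_reads("1", 100, 200, "+", c(`1` = 1e6))
  expect_error(
    discover_dogs(reads, one_gene, p1000, stranded = TRUE,
                  chrom_len = c(`1` = 1e6)),
    "rename")
})

test_that("raising min_dog_cov never increases DoG count or lengths", {
  case <- random_genome_case(101)
  covs <- seq(0.5, 0.9, by = 0.1)
  res <- lapply(covs, function(cv) {
    p <- dog_params(min_dog_len = case$params$min_dog_len,
                    min_dog_cov = cv)
    discover_dogs(case$reads, case$loci, p, stranded = case$stranded,
                  chrom_len = case$chrom_len)
  })
  for (i in seq_len(length(covs) - 1)) {
    lo <- res[[i]]; hi <- res[[i + 1]]
    expect_lte(length(hi), length(lo))
    shared <- intersect(gid(lo), gid(hi))
    for (g in shared)
      expect_lte(S4Vectors::mcols(hi[gid(hi) == g])$dog_length,
                 S4Vectors::mcols(lo[gid(lo) == g])$dog_length)
  }
})

test_that("stranded DoGs never overlap same-strand loci", {
  for (seed in 201:210) {
    case <- random_genome_case(seed)
    dogs <- discover_dogs(case$reads, case$loci, case$params,
                          stranded = TRUE, chrom_len = case$chrom_len)
    if (length(dogs) == 0) next
    hits <- GenomicRanges::findOverlaps(dogs, case$loci,
                                        ignore.strand = FALSE)
    expect_length(hits, 0)
  }
})

test_that("discovery matches the per-base brute-force oracle", {
  for (seed in 301:315) {
    case <- random_genome_case(seed)
    dogs <- discover_dogs(case$reads, case$loci, case$params,
                          stranded = case$stranded,
                          chrom_len = case$chrom_len)
    expect_equal(
      dogs_as_df(dogs),
      oracle_discover(case$reads, case$loci, case$params,
                      case$stranded, case$chrom_len))
  }
})
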