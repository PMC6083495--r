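loci1 <- gene_loci(c("chr1", "chr1"), c(1000, 20000), c(3000, 22000),
                   c("+", "-"), c("A", "B"),
                   seqlengths = c(chr1 = 50000))

test_that("unanimous single-end reads call a forward library", {
  s <- round(seq(1000, 2800, length.out = 1000))
  reads <- mk_reads("chr1", s, s + 100, "+", c(chr1 = 50000))
  spec <- infer_library_type(reads, loci1, sample_size = 1000)
  expect_equal(spec$layout, "single")
  expect_equal(spec$strandedness, "forward")
  expect_equal(spec$concordance_fraction, 1.0)
})

test_that("coin-flip concordance yields an unstranded call", {
  s <- seq(1000, 2998, by = 2)
  reads <- mk_reads("chr1", s, s + 1,
                    rep(c("+", "-"), length.out = length(s)),
                    c(chr1 = 50000))
  spec <- suppressWarnings(infer_library_type(reads, loci1))
  expect_equal(spec$strandedness, "unstranded")
  expect_lt(abs(spec$concordance_fraction - 0.5), 0.05)
})

test_that("paired reads with anti-sense mate-1 call a reverse library", {
  n <- 400
  s <- seq(1000, 2800, length.out = n)
  reads <- mk_reads("chr1", c(s, s + 100), c(s + 100, s + 200),
                    c(rep("-", n), rep("+", n)), c(chr1 = 50000),
                    qname = rep(sprintf("t%03d", 1:n), 2),
                    mate = rep(c(1L, 2L), each = n), paired = TRUE)
  spec <- suppressWarnings(infer_library_type(reads, loci1))
  expect_equal(spec$layout, "paired")
  expect_equal(spec$strandedness, "reverse")
})

test_that("strand inference ignores alignment order for unanimous input", {
  s <- seq(1000, 2800, by = 2)[1:500]
  reads <- mk_reads("chr1", s, s + 100, "+", c(chr1 = 50000))
  perm <- reads[rev(seq_along(reads))]
  s1 <- suppressWarnings(infer_library_type(reads, loci1))
  s2 <- suppressWarnings(infer_library_type(perm, loci1))
  expect_equal(s1$strandedness, s2$strandedness)
  expect_equal(s1$concordance_fraction, s2$concordance_fraction)
})

test_that("strand normalization applies the protocol model", {
  reads <- mk_reads("chr1", c(100, 300), c(200, 400), c("+", "-"),
                    c(chr1 = 50000), qname = c("t1", "t1"),
                    mate = c(1L, 2L), paired = TRUE)
  fwd <- normalize_strand(reads, library_spec("paired", "forward"))
  expect_equal(read_strand(fwd), c("+", "+"))
  rev <- normalize_strand(reads, library_spec("paired", "reverse"))
  expect_equal(read_strand(rev), c("-", "-"))
  single <- mk_reads("chr1", 100, 200, "-", c(chr1 = 50000))
  out <- normalize_strand(single, library_spec("single", "reverse"))
  expect_equal(read_strand(out), "+")
  uns <- normalize_strand(single, library_spec("single", "unstranded"))
  expect_equal(read_strand(uns), "-")
  expect_false(any(S4Vectors::mcols(uns)$informative))
  # block strands track the effective strand
  expect_equal(gr_strand(read_blocks(rev)), c("-", "-"))
})

test_that("downsampling is exact, seeded, and pair-atomic", {
  reads <- mk_reads("chr1", 1:1000 * 10, 1:1000 * 10 + 50, "+",
                    c(chr1 = 50000))
  d1 <- downsample_reads(reads, 100, seed = 7)
  d2 <- downsample_reads(reads, 100, seed = 7)
  expect_equal(length(d1), 100)
  expect_identical(S4Vectors::mcols(d1)$qname,
                   S4Vectors::mcols(d2)$qname)
  d3 <- downsample_reads(reads, 100, seed = 8)
  expect_false(identical(S4Vectors::mcols(d1)$qname,
                         S4Vectors::mcols(d3)$qname))
  expect_identical(downsample_reads(reads, 1000, seed = 1), reads)
  expect_error(downsample_reads(reads, 2000, seed = 1), "exceeds")
  n <- 300
  pr <- mk_reads("chr1", c(1:n * 10, 1:n * 10 + 60),
                 c(1:n * 10 + 50, 1:n * 10 + 110),
                 "+", c(chr1 = 50000),
                 qname = rep(sprintf("t%03d", 1:n), 2),
                 mate = rep(c(1L, 2L), each = n), paired = TRUE)
  dp <- downsample_reads(pr, 100, seed = 3)
  expect_equal(length(dp), 100)
  expect_true(all(table(S4Vectors::mcols(dp)$qname) == 2))
})

test_that("downsampling preserves per-chromosome proportions in expectation", {
  sl <- c(chr1 = 50000, chr2 = 50000)
  reads <- mk_reads(rep(c("chr1", "chr2"), c(300, 700)),
                    rep(1:1000 * 10, length.out = 1000),
                    rep(1:1000 * 10 + 50, length.out = 1000),
                    "+", sl)
  counts <- c(chr1 = 0, chr2 = 0)
  for (seed in 1:25) {
    d <- downsample_reads(reads, 200, seed = seed)
    tab <- table(gr_chrom(read_blocks(d)))
    counts <- counts + as.numeric(tab[names(counts)])
  }
  p <- stats::chisq.test(counts, p = c(0.3, 0.7))$p.value
  expect_gt(p, 1e-3)
})

test_that("preprocess_samples equalizes depth with the auto target", {
  cfg1 <- fixture_config(n_genes = 2, expression_depth = 10, seed = 1)
  cfg2 <- fixture_config(n_genes = 2, expression_depth = 8, seed = 2)
  r1 <- generate_fixture(cfg1)$reads
  r2 <- generate_fixture(cfg2)$reads
  loci <- generate_fixture(cfg1)$loci
  man <- suppressWarnings(preprocess_samples(
    list(a = r1, b = r2), loci, target = "auto", seed = 5))
  expect_equal(length(man$a$ds), min(length(r1), length(r2)))
  expect_equal(length(man$b$ds), min(length(r1), length(r2)))
  expect_error(suppressWarnings(preprocess_samples(
    list(a = r1, b = r2), loci, target = 1e6)), "exceeds")
})
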