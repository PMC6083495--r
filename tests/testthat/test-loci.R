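# in-memory annotation source shaped like read_gtf() output
mk_source <- function(chrom, start0, end0, strand, gene_id) {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start0 + 1, end0), strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = rep("transcript", length(gr)), gene_id = gene_id,
    transcript_id = if (length(gene_id)) paste0(gene_id, ".t")
                    else character(0))
  gr
}

test_that("a gene's locus is the union of its transcripts", {
  src <- mk_source("chr1", c(100, 300), c(500, 900), "+", c("G1", "G1"))
  loci <- build_loci(list(src))
  expect_equal(length(loci), 1)
  expect_equal(c(bed_start(loci), bed_end(loci)), c(100, 900))
  expect_equal(gid(loci), "G1")
})

test_that("the same gene is unified across annotation sources", {
  a <- mk_source("chr1", 100, 500, "+", "G1")
  b <- mk_source("chr1", 80, 600, "+", "G1")
  loci <- build_loci(list(a, b))
  expect_equal(length(loci), 1)
  expect_equal(c(bed_start(loci), bed_end(loci)), c(80, 600))
  expect_equal(S4Vectors::mcols(loci)$source_count, 2L)
})

test_that("opposite-strand loci at identical coordinates never merge", {
  a <- mk_source("chr1", 100, 500, "+", "G1")
  b <- mk_source("chr1", 100, 500, "-", "G2")
  loci <- build_loci(list(a, b))
  expect_equal(length(loci), 2)
  expect_setequal(gid(loci), c("G1", "G2"))
})

test_that("overlapping same-strand genes merge; longest contributor names the locus", {
  a <- mk_source("chr1", 100, 2000, "+", "LONG")
  b <- mk_source("chr1", 1500, 2400, "+", "short")
  loci <- build_loci(list(a, b))
  expect_equal(length(loci), 1)
  expect_equal(gid(loci), "LONG")
  expect_equal(S4Vectors::mcols(loci)$aliases, "short")
  expect_equal(c(bed_start(loci), bed_end(loci)), c(100, 2400))
  # book-ended (touching, zero overlap) loci stay separate
  c2 <- mk_source("chr1", c(100, 500), c(500, 900), "+", c("A", "B"))
  expect_equal(length(build_loci(list(c2))), 2)
})

test_that("locus building is independent of source order", {
  set.seed(1)
  srcs <- lapply(1:3, function(i)
    mk_source("chr1", sample(0:5000, 5), sample(6000:9000, 5),
              sample(c("+", "-"), 5, replace = TRUE),
              sprintf("s%d_g%d", i, 1:5)))
  l1 <- build_loci(srcs)
  l2 <- build_loci(rev(srcs))
  expect_equal(bed_start(l1), bed_start(l2))
  expect_equal(bed_end(l1), bed_end(l2))
  expect_equal(gr_strand(l1), gr_strand(l2))
})

test_that("every input interval is contained in exactly one output locus", {
  set.seed(2)
  src <- mk_source("chr1", sample(0:20000, 20), sample(21000:30000, 20),
                   sample(c("+", "-"), 20, replace = TRUE),
                   sprintf("g%02d", 1:20))
  loci <- build_loci(list(src))
  hits <- GenomicRanges::findOverlaps(src, loci, type = "within",
                                      ignore.strand = FALSE)
  expect_equal(S4Vectors::queryHits(hits), seq_along(src))
})

test_that("build_loci errors on unusable input", {
  expect_error(build_loci(list()), "source")
  empty <- mk_source(character(), numeric(), numeric(), character(),
                     character())
  expect_error(build_loci(list(empty)), "usable")
})

test_that("build_loci works from GTF files on disk", {
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\ttranscript\t101\t500\t.\t+\t.\tgene_id "G1";', f1)
  writeLines('chr1\tsrc\ttranscript\t81\t600\t.\t+\t.\tgene_id "G1";', f2)
  loci <- build_loci(c(f1, f2))
  expect_equal(c(bed_start(loci), bed_end(loci)), c(80, 600))
})

test_that("nearest 3' neighbor honors strand and overlap", {
  loci <- gene_loci("chr1", c(100, 9000), c(500, 12000), c("+", "+"),
                    c("q", "n"))
  expect_equal(nearest_downstream_neighbor(loci, 1, stranded = TRUE),
               9000)
  mixed <- gene_loci("chr1", c(100, 9000), c(500, 12000), c("+", "-"),
                     c("q", "n"))
  expect_true(is.na(
    nearest_downstream_neighbor(mixed, 1, stranded = TRUE)))
  expect_equal(nearest_downstream_neighbor(mixed, 1, stranded = FALSE),
               9000)
  # neighbor poking into the query from downstream: boundary 450, room 0
  ov <- gene_loci("chr1", c(100, 450), c(500, 5000), c("+", "-"),
                  c("q", "n"))
  expect_equal(nearest_downstream_neighbor(ov, 1, stranded = FALSE), 450)
  elig <- eligible_genes(ov, dog_params(min_dog_len = 1000),
                         stranded = FALSE, chrom_len = c(chr1 = 1e6))
  expect_false("q" %in% gid(elig))
})

test_that("neighbor search matches a linear-scan oracle on random genomes", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:50, 1)
    s0 <- sort(sample(0:100000, n))
    loci <- gene_loci("chr1", s0, s0 + sample(100:4000, n, replace = TRUE),
                      sample(c("+", "-"), n, replace = TRUE),
                      sprintf("g%02d", 1:n))
    for (stranded in c(TRUE, FALSE)) {
      got <- nearest_downstream_neighbor(loci, stranded = stranded)
      want <- vapply(seq_along(loci), function(i)
        oracle_neighbor(loci, i, stranded), numeric(1))
      expect_equal(got, want)
    }
  }
})
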