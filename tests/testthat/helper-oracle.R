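# Brute-force reference implementation of DoG discovery: per-base boolean
# coverage arrays plus an exhaustive window scan, written independently of
# the package's interval machinery.  Used to validate discover_dogs on
# small genomes.

oracle_neighbor <- function(loci, i, stranded) {
  lc <- gr_chrom(loci); ls0 <- bed_start(loci); le0 <- bed_end(loci)
  lst <- gr_strand(loci)
  a <- if (lst[i] == "+") le0[i] else ls0[i]
  lim <- NA_real_
  for (j in seq_along(loci)) {
    if (j == i || lc[j] != lc[i]) next
    if (stranded && lst[j] != lst[i]) next
    if (lst[i] == "+") {
      if (le0[j] > a) lim <- if (is.na(lim)) ls0[j] else min(lim, ls0[j])
    } else {
      if (ls0[j] < a) lim <- if (is.na(lim)) le0[j] else max(lim, le0[j])
    }
  }
  lim
}

oracle_discover <- function(reads, loci, params, stranded, chrom_len) {
  lc <- gr_chrom(loci); ls0 <- bed_start(loci); le0 <- bed_end(loci)
  lst <- gr_strand(loci); ids <- gid(loci)
  rstr <- read_strand(reads)
  rs <- lapply(seq_along(reads), function(i) {
    b <- reads[[i]]
    list(chrom = gr_chrom(b)[1], s0 = bed_start(b), e0 = bed_end(b),
         strand = rstr[i])
  })
  keep <- vapply(rs, function(r) {
    for (j in seq_along(loci)) {
      if (lc[j] != r$chrom) next
      if (stranded && lst[j] != r$strand) next
      if (any(r$s0 < le0[j] & r$e0 > ls0[j])) return(FALSE)
    }
    TRUE
  }, logical(1))
  rs <- rs[keep]
  cov <- list()
  for (r in rs) {
    k <- if (stranded) r$strand else "any"
    if (is.null(cov[[k]])) cov[[k]] <- list()
    if (is.null(cov[[k]][[r$chrom]]))
      cov[[k]][[r$chrom]] <- logical(chrom_len[[r$chrom]])
    for (b in seq_along(r$s0))
      cov[[k]][[r$chrom]][(r$s0[b] + 1):r$e0[b]] <- TRUE
  }
  frac <- function(k, ch, s0, e0) {
    v <- cov[[k]][[ch]]
    if (is.null(v) || e0 <= s0) return(0)
    sum(v[(s0 + 1):e0]) / (e0 - s0)
  }
  rows <- list()
  for (i in seq_along(loci)) {
    dirp <- lst[i] == "+"
    a <- if (dirp) le0[i] else ls0[i]
    lim <- oracle_neighbor(loci, i, stranded)
    if (is.na(lim)) lim <- if (dirp) chrom_len[[lc[i]]] else 0
    room <- max(0, if (dirp) lim - a else a - lim)
    if (room < params$min_dog_len) next
    k <- if (stranded) lst[i] else "any"
    f0 <- if (dirp) frac(k, lc[i], a, a + params$min_dog_len)
          else frac(k, lc[i], a - params$min_dog_len, a)
    if (f0 < params$min_dog_cov) next
    e <- params$min_dog_len
    o <- params$min_dog_len
    repeat {
      rem <- room - o
      if (rem <= 0) break
      w <- min(params$window_len, rem)
      fw <- if (dirp) frac(k, lc[i], a + o, a + o + w)
            else frac(k, lc[i], a - o - w, a - o)
      if (fw >= params$min_dog_cov) {
        e <- o + w
        if (w < params$window_len) break
      } else break
      o <- o + params$window_step
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = ids[i], chrom = lc[i],
      start0 = if (dirp) a else a - e,
      end0 = if (dirp) a + e else a,
      strand = lst[i], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start0 = numeric(), end0 = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start0, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

dogs_as_df <- function(dogs) {
  df <- data.frame(gene_id = gid(dogs), chrom = gr_chrom(dogs),
                   start0 = bed_start(dogs), end0 = bed_end(dogs),
                   strand = gr_strand(dogs), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start0, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# A randomized small genome: merged-style loci, background reads, and
# downstream runs of partially overlapping reads planted at ~60% of genes.
random_genome_case <- function(seed) {
  set.seed(seed)
  clen <- sample(40000:80000, 1)
  n_try <- sample(3:12, 1)
  s0 <- sort(sample(0:(clen - 3000), n_try))
  w <- sample(400:2500, n_try, replace = TRUE)
  e0 <- pmin(s0 + w, clen)
  st <- sample(c("+", "-"), n_try, replace = TRUE)
  keep <- rep(TRUE, n_try)
  for (i in seq_len(n_try)) {
    for (j in seq_len(i - 1)) {
      if (keep[j] && st[i] == st[j] && s0[i] < e0[j] && e0[i] > s0[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  loci <- gene_loci("chrA", s0[keep], e0[keep], st[keep],
                    sprintf("g%02d", which(keep)),
                    seqlengths = c(chrA = clen))
  params <- dog_params(min_dog_len = sample(c(1000, 1500, 2000), 1),
                       min_dog_cov = sample(c(0.5, 0.6, 0.7), 1))
  nbg <- sample(30:150, 1)
  bs <- sample(0:(clen - 200), nbg, replace = TRUE)
  bl <- sample(50:150, nbg, replace = TRUE)
  rs0 <- bs; re0 <- pmin(bs + bl, clen)
  rst <- sample(c("+", "-"), nbg, replace = TRUE)
  a <- three_prime_end(loci)
  lstr <- gr_strand(loci)
  for (i in seq_along(loci)) {
    if (stats::runif(1) >= 0.6) next
    runlen <- sample(500:6000, 1)
    pos <- 0
    while (pos < runlen) {
      len <- sample(60:160, 1)
      p0 <- if (lstr[i] == "+") a[i] + pos else a[i] - pos - len
      if (p0 >= 0 && p0 + len <= clen) {
        rs0 <- c(rs0, p0); re0 <- c(re0, p0 + len)
        rst <- c(rst, lstr[i])
      }
      pos <- pos + sample(c(60, 100, 140, 220), 1)
    }
  }
  reads <- mk_reads("chrA", rs0, re0, rst, seqlen = c(chrA = clen))
  list(loci = loci, reads = reads, params = params,
       chrom_len = c(chrA = clen),
       stranded = sample(c(TRUE, FALSE), 1))
}
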