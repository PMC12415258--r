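test_that("randomized placement is uniform over admissible starts", {
  gi <- genome_index(c(chr1 = 1000))
  w <- bed_ranges("chr1", 0, 100)        # width 100, starts 0..900
  set.seed(41)
  starts <- integer(10000)
  for (i in seq_len(10000))
    starts[i] <- start(randomize_windows(w, gi)) - 1L
  expect_true(all(starts >= 0 & starts <= 900))
  expect_true(all(width(randomize_windows(w, gi)) == 100))
  # chi-square GOF against uniform over 901 admissible starts, 10 bins
  obs <- tabulate(findInterval(starts, seq(0, 901, length.out = 11),
                               rightmost.closed = TRUE), 10)
  expect_gt(stats::chisq.test(obs)$p.value, 0.001)
})

test_that("forced and masked placements obey their constraints", {
  gi <- genome_index(c(chr1 = 500))
  w <- bed_ranges("chr1", 0, 500)        # width equals chromosome
  expect_equal(as_bed_df(randomize_windows(w, gi))[, c("start", "end")],
               data.frame(start = 0, end = 500))
  # masked middle third: no randomized window touches it
  mask <- bed_ranges("chr1", 160, 340)
  gim <- genome_index(c(chr1 = 500), mask = mask)
  wins <- bed_ranges(rep("chr1", 50), rep(0, 50), rep(30, 50))
  set.seed(43)
  for (i in 1:20) {
    r <- randomize_windows(wins, gim)
    expect_equal(count_query_hits(r, mask), 0L)
  }
  expect_error(randomize_windows(bed_ranges("chr1", 0, 400), gim),
               "no admissible placement")
})

test_that("empirical p-value follows the +1/(N+1) convention", {
  expect_equal(empirical_pvalue(10, c(0, 1, 2)), 0.25)
  expect_equal(empirical_pvalue(1, c(1, 1, 1)), 1)
  expect_equal(empirical_pvalue(0, c(1, 2, 3), "less"), 0.25)
  expect_error(empirical_pvalue(1, numeric(0)), "at least one")
})

test_that("perm_test handles degenerate inputs and is seed-deterministic", {
  gi <- genome_index(c(chr1 = 10000))
  w <- bed_ranges("chr1", c(100, 5000), c(200, 5100))
  expect_error(perm_test(GRanges(), bed_ranges("chr1", 0, 10), gi,
                         seed = 1), "non-empty")
  r0 <- perm_test(w, GRanges(), gi, n_perm = 99, seed = 1)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$p_value, 1)
  expect_false(r0$z_defined)
  g4 <- bed_ranges("chr1", c(150, 9000), c(180, 9100))
  r1 <- perm_test(w, g4, gi, n_perm = 199, seed = 7)
  r2 <- perm_test(w, g4, gi, n_perm = 199, seed = 7)
  expect_identical(r1$perm_counts, r2$perm_counts)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$observed, 1L)
  expect_equal(length(r1$perm_counts), 199L)
  expect_gte(r1$p_value, 1 / 200)
})

test_that("fast permutation counting equals count_query_hits and the oracle", {
  set.seed(47)
  chrom_len <- c(chr1 = 8000, chr2 = 4000)
  for (i in 1:50) {
    q <- random_granges(sample.int(50, 1), chrom_len, 150)
    s <- random_granges(sample.int(50, 1), chrom_len, 150)
    sidx <- g4coloc:::.overlap_subject_index(s)
    fast <- sum(g4coloc:::.any_overlap_fast(as.character(seqnames(q)),
                                            start(q), end(q), sidx))
    expect_identical(fast, count_query_hits(q, s))
    expect_identical(fast, oracle_count_hits(q, s, chrom_len))
  }
})

test_that("Monte-Carlo p matches the exact enumeration on the toy genome", {
  # one 1,000 bp chromosome, one 100 bp window, one G4
  gi <- genome_index(c(chr1 = 1000))
  g4 <- bed_ranges("chr1", 420, 450)
  w <- bed_ranges("chr1", 400, 500)      # overlaps: observed = 1
  p_true <- oracle_placement_prob(g4, 1000L, 100L)
  r <- perm_test(w, g4, gi, n_perm = 10000, seed = 53)
  expect_equal(r$observed, 1L)
  # exact p for alternative=greater is P(perm count >= 1) = p_true
  ci_half <- stats::qnorm(0.995) * sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(r$p_value - p_true), ci_half + 2 / 10001)
})

test_that("class overlap table gives per-class fractions", {
  gi <- genome_index(c(chr1 = 100000))
  bps <- data.frame(chrom = "chr1",
                    pos = c(1000L, 2000L, 3000L, 4000L, 9000L),
                    variant_class = c(rep("deletion", 4), "SNV"),
                    sample = "s1", end_role = "single")
  w <- make_windows(bps, 100, gi)
  g4 <- bed_ranges("chr1", c(990, 2990), c(1010, 3010))
  tab <- class_overlap_table(w, list(pqs = g4))
  del <- tab[tab$variant_class == "deletion", ]
  expect_equal(del$fraction, 0.5)
  expect_equal(del$n_windows, 4)
  snv <- tab[tab$variant_class == "SNV", ]
  expect_equal(snv$fraction, 0)
  # absent classes yield no row
  expect_false("inversion" %in% tab$variant_class)
  # fixture with hand-enumerated per-window overlaps
  hit <- overlapsAny(w, g4)
  for (cl in unique(tab$variant_class)) {
    idx <- grepl(cl, mcols(w)$variant_class)
    expect_equal(tab$fraction[tab$variant_class == cl],
                 mean(hit[idx]))
  }
})

test_that("perm_test with oracle counting substituted gives identical results", {
  gi <- genome_index(c(chr1 = 5000))
  set.seed(59)
  w <- random_granges(10, c(chr1 = 5000), 100)
  g4 <- random_granges(8, c(chr1 = 5000), 50)
  r <- perm_test(w, g4, gi, n_perm = 50, seed = 61)
  # replay the same seeded randomization, counting with the per-base oracle
  obs <- oracle_count_hits(w, g4, c(chr1 = 5000))
  set.seed(61)
  widths <- width(w)
  hits <- matrix(FALSE, nrow = 10, ncol = 50)
  for (wd in unique(widths)) {
    iw <- which(widths == wd)
    sp <- g4coloc:::.placement_space(gi, as.integer(wd))
    draws <- pmin(floor(stats::runif(length(iw) * 50) * sp$total) + 1,
                  sp$total)
    pl <- g4coloc:::.place(sp, draws, as.integer(wd))
    gq <- GRanges(pl$chrom, IRanges(pl$start, pl$end))
    hits[iw, ] <- vapply(seq_along(gq), function(k)
      oracle_count_hits(gq[k], g4, c(chr1 = 5000)) > 0, TRUE)
  }
  expect_identical(r$observed, obs)
  expect_equal(r$perm_counts, colSums(hits))
})
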