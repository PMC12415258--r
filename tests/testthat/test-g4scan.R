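test_that("find_g_runs reports maximal runs and matches the walk oracle", {
  expect_equal(nrow(find_g_runs("ACGTACGT", 3)), 0)
  runs <- find_g_runs("GGGTTAGGG", 3)
  expect_equal(runs$start, c(0, 6))
  expect_equal(runs$length, c(3, 3))
  # N breaks a run
  expect_equal(find_g_runs("GGGNGGG", 3)$start, c(0, 4))
  set.seed(5)
  for (i in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 1000, replace = TRUE,
                        prob = c(0.2, 0.2, 0.35, 0.2, 0.05)),
                 collapse = "")
    ml <- sample(2:4, 1)
    expect_equal(find_g_runs(seq, ml), oracle_g_runs(seq, ml))
  }
})

test_that("score_pqs implements the linear stability score", {
  expect_identical(score_pqs(c(3, 3, 3, 3), c(3, 3, 3)), 27L)
  expect_identical(score_pqs(c(3, 3, 3, 3), c(1, 1, 1)), 39L)
  expect_identical(score_pqs(c(4, 4, 4, 4), c(1, 1, 1)), 54L)
  expect_identical(
    score_pqs(c(3, 3, 3, 2), c(1, 1, 1), c(FALSE, FALSE, FALSE, TRUE)), 21L)
  # tract lengths cap at 6
  expect_identical(score_pqs(c(8, 8, 8, 8), c(1, 1, 1)),
                   score_pqs(c(6, 6, 6, 6), c(1, 1, 1)))
  expect_error(score_pqs(c(3, 3, 3), c(1, 1, 1)), "exactly 4")
  expect_error(score_pqs(c(3, 3, 3, 2), c(1, 1, 1)), ">= 3")
  expect_error(score_pqs(c(3, 3, 3, 3), c(1, 1, -1)), ">= 0")
})

test_that("score is monotone in tracts, loops and defects", {
  set.seed(7)
  for (i in 1:50) {
    tr <- sample(3:7, 4, replace = TRUE)
    lp <- sample(1:12, 3, replace = TRUE)
    s0 <- score_pqs(tr, lp)
    j <- sample.int(4, 1)
    tr2 <- tr; tr2[j] <- tr2[j] + 1L
    expect_gte(score_pqs(tr2, lp), s0)             # non-decreasing in tracts
    if (all(tr < 6)) expect_gt(score_pqs(tr + 1L, lp), s0)
    k <- sample.int(3, 1)
    lp2 <- lp; lp2[k] <- lp2[k] + 1L
    expect_lt(score_pqs(tr, lp2), s0)              # strictly decreasing in loops
    # one defect costs exactly 12
    expect_identical(
      s0 - score_pqs(tr, lp, c(TRUE, FALSE, FALSE, FALSE)), 12L)
  }
})

test_that("scan_pqs parses the canonical forced motif", {
  hits <- scan_pqs("GGGTGGGTGGGTGGG")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0)
  expect_equal(hits$end, 15)
  expect_equal(hits$score, 39)
  expect_equal(hits$tracts, "3,3,3,3")
  expect_equal(hits$loops, "1,1,1")
  expect_equal(nrow(scan_pqs(strrep("ACAC", 10))), 0)
  expect_equal(nrow(scan_pqs("")), 0)
})

test_that("candidate enumeration matches the exhaustive oracle", {
  p <- scan_params()
  set.seed(13)
  for (i in 1:40) {
    seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE,
                        prob = c(0.2, 0.2, 0.4, 0.2)), collapse = "")
    got <- scan_pqs(seq, p, all_candidates = TRUE)
    want <- oracle_pqs_candidates(seq, p)
    expect_equal(got[c("start", "end", "score")],
                 want[c("start", "end", "score")],
                 ignore_attr = TRUE)
  }
})

test_that("greedy selection matches the naive greedy and toy exhaustive optimum", {
  p <- scan_params()
  set.seed(17)
  for (i in 1:100) {
    n <- sample.int(30, 1)
    s <- sample.int(500, n, replace = TRUE)
    cand <- data.frame(start = s, end = s + sample.int(40, n, replace = TRUE),
                       score = sample.int(80, n, replace = TRUE),
                       n_defective = 0L, tracts = "3,3,3,3", loops = "1,1,1")
    got <- g4coloc:::.greedy_select(cand)
    want <- oracle_greedy(cand)
    expect_equal(got[c("start", "end", "score")],
                 want[c("start", "end", "score")], ignore_attr = TRUE)
  }
  # toy with two overlapping parses: greedy equals the max-total-score
  # non-overlapping subset found by exhaustive search
  seq <- "GGGTGGGTGGGTGGGTGGG"
  cand <- scan_pqs(seq, p, all_candidates = TRUE)
  sel <- scan_pqs(seq, p)
  subsets <- unlist(lapply(seq_len(nrow(cand)), function(k)
    utils::combn(nrow(cand), k, simplify = FALSE)), recursive = FALSE)
  ok <- Filter(function(ix) {
    if (length(ix) < 2) return(TRUE)
    s <- cand$start[ix]; e <- cand$end[ix]
    all(outer(s, e, `>=`) | outer(e, s, `<=`) | diag(length(ix)) == 1)
  }, subsets)
  best <- max(vapply(ok, function(ix) sum(cand$score[ix]), 1))
  expect_equal(sum(sel$score), best)
})

test_that("reported same-strand hits never overlap", {
  set.seed(19)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                        prob = c(0.18, 0.18, 0.46, 0.18)), collapse = "")
    hits <- scan_pqs(seq)
    if (nrow(hits) > 1)
      expect_true(all(hits$start[-1] >= hits$end[-nrow(hits)]))
  }
})

test_that("minus-strand scanning is strand-symmetric", {
  # C-tract motif is found on the minus strand over the same region
  seq <- c(chrA = "AAACCCACCCACCCACCCAAA")
  hits <- scan_genome(seq)
  expect_equal(length(hits), 1)
  expect_equal(as.character(strand(hits)), "-")
  df <- as_bed_df(hits)
  expect_equal(c(df$start, df$end), c(3, 18))
  # mirror property on random sequences
  set.seed(23)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE,
                      prob = c(0.15, 0.3, 0.4, 0.15)), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    h1 <- scan_genome(c(chr = s))
    h2 <- scan_genome(c(chr = rc))
    L <- nchar(s)
    # reflect h2 back through the midpoint and swap strands
    sw <- c(`+` = "-", `-` = "+")[as.character(strand(h2))]
    key1 <- sort(paste(start(h1), end(h1), strand(h1)))
    key2 <- sort(paste(L - end(h2) + 1L, L - start(h2) + 1L, sw))
    expect_identical(key1, key2)
  }
})

test_that("scan output is byte-deterministic and duplicate names error", {
  set.seed(29)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE,
                    prob = c(0.17, 0.17, 0.49, 0.17)), collapse = "")
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(scan_genome(c(chr1 = s)), f1)
  write_bed(scan_genome(c(chr1 = s)), f2)
  expect_identical(readLines(f1), readLines(f2))
  x <- Biostrings::DNAStringSet(c(a = "ACGT", a = "ACGT"))
  expect_error(scan_genome(x), "duplicate")
})

test_that("defective 2-G tracts are found only when allowed and cost 12", {
  seq <- "GGGTGGGTGGGTGG"          # last tract only 2 Gs
  expect_equal(nrow(scan_pqs(seq)), 0)
  hits <- scan_pqs(seq, scan_params(allow_defect = TRUE))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_defective, 1)
  expect_equal(hits$score, score_pqs(c(3, 3, 3, 2), c(1, 1, 1),
                                     c(FALSE, FALSE, FALSE, TRUE)))
  # two short tracts are never combined into one hit
  expect_equal(nrow(scan_pqs("GGTGGGTGGGTGG",
                             scan_params(allow_defect = TRUE))), 0)
})

test_that("scan_params enforces its invariants", {
  expect_error(scan_params(loop_min = -1), "loop_min")
  expect_error(scan_params(loop_min = 5, loop_max = 2), "loop_min")
  expect_error(scan_params(max_width = 10), "max_width")
  expect_silent(scan_params(max_width = 15, loop_min = 1, min_tract = 3))
})
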