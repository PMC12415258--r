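test_that("VCF small variants map to 0-based breakpoints by class", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c("chr1\t100\t.\tA\tT\t.\tPASS\t.",
                   "chr1\t100\t.\tACGT\tA\t.\tPASS\t.",
                   "chr1\t200\t.\tC\tCTTT\t.\tPASS\t."), path)
  bps <- breakpoints_from_vcf(path, "s1")
  expect_equal(bps$pos[bps$variant_class == "SNV"], 99)
  expect_equal(bps$end_role[bps$variant_class == "SNV"], "single")
  del <- bps[bps$variant_class == "deletion", ]
  expect_equal(del$pos, c(100, 103))
  expect_equal(del$end_role, c("start", "end"))
  expect_equal(bps$pos[bps$variant_class == "insertion"], 200)
  expect_true(all(bps$sample == "s1"))
})

test_that("breakpoint count follows the per-class formulas on a random VCF", {
  set.seed(31)
  n_snv <- 17; n_ins <- 12; n_del <- 21
  rows <- c(
    sprintf("chr1\t%d\t.\tA\tG\t.\tPASS\t.", sample(1000:9000, n_snv)),
    sprintf("chr1\t%d\t.\tC\tCAT\t.\tPASS\t.", sample(1000:9000, n_ins)),
    sprintf("chr1\t%d\t.\t%s\tT\t.\tPASS\t.", sample(1000:9000, n_del),
            vapply(sample(2:10, n_del, replace = TRUE),
                   function(k) paste0("T", strrep("A", k - 1)), "")))
  path <- write_test_vcf(rows, withr::local_tempfile(fileext = ".vcf"))
  bps <- breakpoints_from_vcf(path, "s1")
  expect_equal(nrow(bps), n_snv + n_ins + 2L * n_del)
})

test_that("multi-allelic and symbolic records are handled per policy", {
  path <- write_test_vcf("chr1\t50\t.\tA\tT,G\t.\tPASS\t.",
                         withr::local_tempfile(fileext = ".vcf"))
  bps <- breakpoints_from_vcf(path, "s1")
  expect_equal(nrow(bps), 2)
  expect_error(breakpoints_from_vcf(path, "s1", multiallelic = "reject"),
               "multi-allelic")
  path2 <- write_test_vcf("chr1\t50\t.\tA\t<DEL>\t.\tPASS\t.",
                          withr::local_tempfile(fileext = ".vcf"))
  expect_error(breakpoints_from_vcf(path2, "s1"), "BEDPE")
})

test_that("BEDPE records yield two midpoint breakpoints with mapped classes", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t100\t101\tchr5\t200\t201\tsv1\t.\t+\t-\tTRA",
               "chr1\t100\t110\tchr1\t500\t510\tsv2\t.\t+\t-\tDEL"), path)
  bps <- breakpoints_from_bedpe(path, "s1")
  expect_equal(nrow(bps), 4)
  tra <- bps[bps$variant_class == "translocation", ]
  expect_equal(tra$chrom, c("chr1", "chr5"))
  expect_equal(tra$pos, c(100, 200))
  expect_equal(tra$end_role, c("mate_A", "mate_B"))
  expect_equal(bps$pos[bps$variant_class == "deletion"], c(105, 505))
  writeLines("chr1\t1\t2\tchr1\t5\t6\tx\t.\t+\t-\tWEIRD", path)
  expect_error(breakpoints_from_bedpe(path, "s1"), "known aliases")
})

test_that("copy-number segment boundaries become breakpoints except at termini", {
  gi <- genome_index(c(chr13 = 10000))
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("chr13\t1000\t5000\tloss",
               "chr13\t0\t10000\tgain",          # whole chromosome
               "chr13\t6000\t10000\t-0.8"), path)
  bps <- breakpoints_from_segments(path, "s1", genome = gi)
  loss <- bps[bps$variant_class == "CN_loss", ]
  expect_equal(sort(loss$pos), c(1000, 5000, 6000))
  expect_false(any(bps$pos %in% c(0, 10000)))
  expect_equal(sum(bps$variant_class == "CN_gain"), 0)
  writeLines("chr13\t500\t400\tgain", path)
  expect_error(breakpoints_from_segments(path, "s1"), "start >= end")
  writeLines("chr13\t500\t600\tweird", path)
  expect_error(breakpoints_from_segments(path, "s1"), "unrecognized")
})

test_that("windows are centered, clipped, deduplicated and sorted", {
  gi <- genome_index(c(chr1 = 10000))
  bps <- data.frame(chrom = "chr1", pos = c(500L, 20L, 500L),
                    variant_class = c("deletion", "SNV", "deletion"),
                    sample = "s1",
                    end_role = c("start", "single", "start"))
  w <- make_windows(bps, 100, gi)
  df <- as_bed_df(w)
  expect_equal(nrow(df), 2)                    # dedupe collapsed the repeat
  expect_equal(df$start, c(0, 450))
  expect_equal(df$end, c(70, 550))             # clipped at chromosome start
  expect_equal(mcols(w)$n_breakpoints, c(1L, 2L))
  raw <- make_windows(bps, 100, gi, dedupe = FALSE)
  expect_equal(length(raw), 3)
  # mixed-class duplicates keep both class labels
  bps$variant_class <- c("deletion", "SNV", "SNV")
  w2 <- make_windows(bps, 100, gi)
  expect_equal(mcols(w2)$variant_class[2], "SNV,deletion")
  expect_error(make_windows(bps, 99, gi), "even")
  bps$pos[1] <- 20000L
  expect_error(make_windows(bps, 100, gi), "bounds")
})

test_that("window construction is order-independent", {
  gi <- genome_index(c(chr1 = 50000, chr2 = 30000))
  set.seed(37)
  bps <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                    pos = sample.int(29000, 40),
                    variant_class = sample(VARIANT_CLASSES, 40, replace = TRUE),
                    sample = "s1", end_role = "single")
  w1 <- make_windows(bps, 1000, gi)
  w2 <- make_windows(bps[sample(nrow(bps)), ], 1000, gi)
  expect_equal(as_bed_df(w1), as_bed_df(w2))
})
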