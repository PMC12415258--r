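# Independent brute-force oracles used to validate the optimized
# implementations, plus small random-instance generators. All oracles
# are deliberately naive (per-base marking, full enumeration) and share
# no code with the package internals.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# per-base oracle for the count-once overlap statistic
oracle_count_hits <- function(queries, subjects, chrom_len) {
  covered <- lapply(chrom_len, function(len) logical(len))
  for (i in seq_along(subjects)) {
    c <- as.character(seqnames(subjects)[i])
    covered[[c]][start(subjects)[i]:end(subjects)[i]] <- TRUE
  }
  hits <- 0L
  for (i in seq_along(queries)) {
    c <- as.character(seqnames(queries)[i])
    if (!is.null(covered[[c]]) &&
        any(covered[[c]][start(queries)[i]:end(queries)[i]]))
      hits <- hits + 1L
  }
  hits
}

# per-base oracle for binned density: mark coverage count and best
# score per base, then reduce over each bin
oracle_density <- function(hits, region_start1, region_end1, bin_size) {
  len <- region_end1 - region_start1 + 1L
  cov <- integer(len)
  bs <- seq(region_start1, region_end1, by = bin_size)
  be <- pmin(bs + bin_size - 1L, region_end1)
  count <- integer(length(bs)); max_score <- numeric(length(bs))
  for (b in seq_along(bs)) {
    for (i in seq_along(hits)) {
      if (start(hits)[i] <= be[b] && end(hits)[i] >= bs[b]) {
        count[b] <- count[b] + 1L
        max_score[b] <- max(max_score[b], mcols(hits)$score[i])
      }
    }
  }
  list(count = count, max_score = max_score)
}

# character-walk oracle for G runs
oracle_g_runs <- function(seq, min_len) {
  ch <- strsplit(toupper(seq), "")[[1]]
  starts <- integer(0); lens <- integer(0)
  run <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "G") run <- run + 1L
    else {
      if (run >= min_len) {
        starts <- c(starts, i - 1L - run); lens <- c(lens, run)
      }
      run <- 0L
    }
  }
  if (run >= min_len) {
    starts <- c(starts, length(ch) - run); lens <- c(lens, run)
  }
  data.frame(start = starts, length = lens)
}

# exhaustive PQS candidate enumeration: every quadruple of maximal
# G-runs, every prefix-length assignment; per quadruple keep the best
# parse under (score desc, width asc). Canonical tracts only.
oracle_pqs_candidates <- function(seq, params) {
  runs <- oracle_g_runs(seq, params$min_tract)
  n <- nrow(runs)
  out <- data.frame(start = integer(0), end = integer(0),
                    score = integer(0))
  if (n < 4L) return(out)
  score_fun <- function(tr, lp)
    15L * min(min(tr), 6L) + 3L * (sum(pmin(tr, 6L)) - 4L * min(min(tr), 6L)) -
      2L * sum(lp)
  for (q in utils::combn(n, 4, simplify = FALSE)) {
    s <- runs$start[q]; L <- runs$length[q]
    best <- NULL
    for (t1 in params$min_tract:L[1])
      for (t2 in params$min_tract:L[2])
        for (t3 in params$min_tract:L[3])
          for (t4 in params$min_tract:L[4]) {
            lp <- c(s[2] - s[1] - t1, s[3] - s[2] - t2, s[4] - s[3] - t3)
            if (any(lp < params$loop_min) || any(lp > params$loop_max))
              next
            w <- s[4] + t4 - s[1]
            if (w > params$max_width) next
            sc <- score_fun(c(t1, t2, t3, t4), lp)
            cand <- list(start = s[1], end = s[4] + t4, score = sc, w = w)
            if (is.null(best) || sc > best$score ||
                (sc == best$score && w < best$w))
              best <- cand
          }
    if (!is.null(best))
      out <- rbind(out, data.frame(start = best$start, end = best$end,
                                   score = best$score))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# naive greedy selection replicate: repeatedly take the best remaining
# candidate (score desc, start asc, width asc) compatible with the
# current selection
oracle_greedy <- function(cand) {
  sel <- cand[0, , drop = FALSE]
  repeat {
    ok <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand)))
      if (nrow(sel) && any(cand$start[i] < sel$end & cand$end[i] > sel$start))
        ok[i] <- FALSE
    pool <- cand[ok, , drop = FALSE]
    if (!nrow(pool)) break
    o <- order(-pool$score, pool$start, pool$end - pool$start)
    sel <- rbind(sel, pool[o[1], , drop = FALSE])
    cand <- pool[-o[1], , drop = FALSE]
  }
  sel <- sel[order(sel$start), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

# random interval set on a toy genome (BED-style coordinates in, 1-based
# GRanges out)
random_granges <- function(n, chrom_len, max_width = 200) {
  chroms <- names(chrom_len)
  c <- sample(chroms, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(chrom_len[[c[i]]] - w[i] + 1L, 1L), 1L)
  GRanges(c, IRanges(s, width = w))
}

# exact overlap probability for a single window of width w placed
# uniformly on one chromosome, against a fixed subject set
oracle_placement_prob <- function(g4s, chrom_len, w) {
  hits <- 0L
  for (s in 1:(chrom_len - w + 1L)) {
    e <- s + w - 1L
    if (any(start(g4s) <= e & end(g4s) >= s)) hits <- hits + 1L
  }
  hits / (chrom_len - w + 1L)
}

# write a minimal sites-only VCF
write_test_vcf <- function(rows, path, contigs = c(chr1 = 100000L)) {
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       contigs),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}
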