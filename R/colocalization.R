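# Placement space for width-preserving random re-placement.
# For a width w, the admissible starts on each chromosome are the
# starts (1-based) at which a w-bp window fits entirely inside an
# unmasked segment. Returns per-segment tables plus the total count,
# so a chromosome is chosen with probability proportional to its
# number of admissible positions.
.placement_space <- function(genome, width) {
  lens <- genome$seqlengths
  segs_chrom <- character(0); segs_start <- integer(0); segs_n <- numeric(0)
  for (chrom in names(lens)) {
    if (is.null(genome$mask)) {
      free <- IRanges(1L, lens[[chrom]])
    } else {
      m <- genome$mask[as.character(seqnames(genome$mask)) == chrom]
      free <- setdiff(IRanges(1L, lens[[chrom]]), ranges(m))
    }
    free <- free[width(free) >= width]
    if (length(free)) {
      segs_chrom <- c(segs_chrom, rep(chrom, length(free)))
      segs_start <- c(segs_start, start(free))
      segs_n <- c(segs_n, width(free) - width + 1)
    }
  }
  total <- sum(segs_n)
  if (total < 1)
    stop("no admissible placement for a window of width ", width)
  list(chrom = segs_chrom, seg_start = segs_start, n = segs_n,
       cum = cumsum(segs_n), total = total)
}

# map k draws (uniform integers in 1..space$total) to (chrom, start, end)
.place <- function(space, draws, width) {
  seg <- findInterval(draws - 1, space$cum) + 1L
  offset <- draws - c(0, space$cum)[seg] - 1
  start <- space$seg_start[seg] + offset
  list(chrom = space$chrom[seg], start = start, end = start + width - 1L)
}

.draw_uniform <- function(n, total) {
  # uniform integers in 1..total without 32-bit overflow concerns
  pmin(floor(runif(n) * total) + 1, total)
}

#' Randomly re-place windows on the genome
#'
#' Each window is independently re-placed uniformly over all unmasked
#' genome positions that admit its full width; the chromosome is chosen
#' with probability proportional to its number of admissible positions.
#' Widths and metadata are preserved; randomized windows may overlap
#' one another, and never intersect the genome mask.
#'
#' @param windows `GRanges` of windows.
#' @param genome A `genome_index` (with optional mask).
#' @param seed Optional integer seed for reproducibility.
#' @return `GRanges` of the same length, widths and metadata.
#' @export
randomize_windows <- function(windows, genome, seed = NULL) {
  stopifnot(is(windows, "GRanges"), inherits(genome, "genome_index"))
  if (!is.null(seed)) set.seed(seed)
  w <- width(windows)
  new_chrom <- character(length(windows))
  new_start <- integer(length(windows))
  for (wd in unique(w)) {
    i <- which(w == wd)
    space <- .placement_space(genome, wd)
    p <- .place(space, .draw_uniform(length(i), space$total), wd)
    new_chrom[i] <- p$chrom
    new_start[i] <- p$start
  }
  out <- GRanges(new_chrom, IRanges(new_start, width = w),
                 strand = strand(windows))
  mcols(out) <- mcols(windows)
  out
}

#' Empirical permutation p-value
#'
#' `(1 + # permuted statistics at least as extreme as observed) /
#' (n_perm + 1)`; never zero, with attainable floor `1 / (n_perm + 1)`.
#'
#' @param observed Observed statistic.
#' @param perm_counts Vector of permuted statistics.
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return The empirical p-value.
#' @examples
#' empirical_pvalue(10, c(0, 1, 2))  # 0.25
#' @export
empirical_pvalue <- function(observed, perm_counts,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(perm_counts)
  if (n < 1L) stop("need at least one permutation")
  extreme <- if (alternative == "greater") sum(perm_counts >= observed)
             else sum(perm_counts <= observed)
  (1 + extreme) / (n + 1)
}

#' Permutation test of window/G4 colocalization
#'
#' The statistic is the count-once overlap: the number of windows
#' overlapping at least one G4 interval. Its null distribution is
#' obtained by repeatedly re-placing every window uniformly at random
#' on the unmasked genome (width-preserving, chromosome chosen
#' proportionally to admissible positions) and recounting. The
#' empirical p-value uses the `+1/(N+1)` convention, so with
#' `n_perm = 999` the attainable floor is exactly 0.001.
#'
#' @param windows `GRanges` of breakpoint windows (non-empty).
#' @param g4s `GRanges` of G4 intervals; may be empty (then the
#'   observed count is 0 and, under `"greater"`, p = 1).
#' @param genome A `genome_index`.
#' @param n_perm Number of permutations (default 999).
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @param seed Integer seed; identical inputs and seed give an
#'   identical result.
#' @return An `overlap_result` list: `n_windows`, `observed`,
#'   `observed_fraction`, `perm_counts`, `n_perm`, `p_value`,
#'   `z_score` (`NA` with `z_defined = FALSE` when the permuted
#'   counts are constant), `alternative`, `seed`.
#' @export
perm_test <- function(windows, g4s, genome, n_perm = 999,
                      alternative = c("greater", "less"), seed = NULL) {
  stopifnot(is(windows, "GRanges"), is(g4s, "GRanges"),
            inherits(genome, "genome_index"))
  alternative <- match.arg(alternative)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(windows) == 0L) stop("'windows' must be non-empty")
  if (!is.null(seed)) set.seed(seed)

  observed <- count_query_hits(windows, g4s)
  sidx <- .overlap_subject_index(g4s)
  w <- width(windows)
  n <- length(windows)
  spaces <- lapply(setNames(nm = unique(w)), function(wd)
    .placement_space(genome, as.integer(wd)))

  perm_counts <- integer(n_perm)
  chunk <- max(1L, min(n_perm, as.integer(5e6 %/% n)))
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    hits <- matrix(FALSE, nrow = n, ncol = k)
    for (wd in unique(w)) {
      i <- which(w == wd)
      space <- spaces[[as.character(wd)]]
      p <- .place(space, .draw_uniform(length(i) * k, space$total),
                  as.integer(wd))
      hits[i, ] <- .any_overlap_fast(p$chrom, p$start, p$end, sidx)
    }
    perm_counts[(done + 1L):(done + k)] <- colSums(hits)
    done <- done + k
  }

  p <- empirical_pvalue(observed, perm_counts, alternative)
  s <- stats::sd(perm_counts)
  z <- if (is.na(s) || s == 0) NA_real_ else (observed - mean(perm_counts)) / s
  structure(list(n_windows = n, observed = observed,
                 observed_fraction = observed / n,
                 perm_counts = perm_counts, n_perm = n_perm,
                 p_value = p, z_score = z,
                 z_defined = !is.na(z), alternative = alternative,
                 seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Permutation overlap test (%s)\n  windows: %d, overlapping G4s: %d (%.1f%%)\n  permutations: %d, perm mean: %.2f\n  empirical p = %.4g%s\n",
    x$alternative, x$n_windows, x$observed, 100 * x$observed_fraction,
    x$n_perm, mean(x$perm_counts), x$p_value,
    if (x$z_defined) sprintf(", z = %.2f", x$z_score) else ", z undefined"))
  invisible(x)
}

#' Per-class overlap fractions of breakpoint windows with G4 sets
#'
#' For each variant class, window size and G4 set, the fraction of
#' that class's windows overlapping at least one interval of the set.
#' A window whose collapsed `variant_class` lists several classes
#' (duplicate-coordinate windows merged by [make_windows()]) counts
#' toward each listed class. Classes absent from the input yield no
#' row.
#'
#' @param windows `GRanges` from [make_windows()] (carrying
#'   `variant_class` and `window_size` metadata).
#' @param g4_sets Named list of `GRanges` (a bare `GRanges` is treated
#'   as a single set named `"g4"`).
#' @return data.frame with columns `variant_class`, `window_size`,
#'   `g4_set`, `n_windows`, `n_overlap`, `fraction`.
#' @export
class_overlap_table <- function(windows, g4_sets) {
  stopifnot(is(windows, "GRanges"))
  if (is(g4_sets, "GRanges")) g4_sets <- list(g4 = g4_sets)
  stopifnot(is.list(g4_sets), !is.null(names(g4_sets)))
  cls_list <- strsplit(mcols(windows)$variant_class, ",", fixed = TRUE)
  rows <- list()
  for (set_name in names(g4_sets)) {
    hit <- overlapsAny(windows, g4_sets[[set_name]], ignore.strand = TRUE)
    idx <- rep(seq_along(windows), lengths(cls_list))
    cls <- unlist(cls_list)
    for (ws in unique(mcols(windows)$window_size)) {
      in_ws <- mcols(windows)$window_size[idx] == ws
      for (cl in sort(unique(cls[in_ws]))) {
        i <- idx[in_ws & cls == cl]
        rows[[length(rows) + 1L]] <- data.frame(
          variant_class = cl, window_size = ws, g4_set = set_name,
          n_windows = length(i), n_overlap = sum(hit[i]),
          fraction = sum(hit[i]) / length(i), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant_class = character(0),
                      window_size = integer(0), g4_set = character(0),
                      n_windows = integer(0), n_overlap = integer(0),
                      fraction = numeric(0))
  rownames(out) <- NULL
  out
}
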