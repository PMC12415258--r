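#' Parameters for the PQS scanner
#'
#' A putative quadruplex sequence (PQS) is parsed as four G-tracts of
#' at least `min_tract` consecutive guanines separated by three loops
#' of `loop_min`--`loop_max` nt, the whole motif spanning at most
#' `max_width` bp. With `allow_defect = TRUE` a single tract may be
#' defective: shortened to a 2-G run. Hits scoring below
#' `score_threshold` are dropped; the conventional high-stability cut
#' in this analysis is a score of 50.
#'
#' @param min_tract Minimum G-tract length for a canonical tract
#'   (default 3).
#' @param loop_min,loop_max Loop length bounds in nt (defaults 1 and 12).
#' @param max_width Maximum motif span in bp (default 50).
#' @param allow_defect Permit one defective (2-G) tract per hit
#'   (default `FALSE`).
#' @param score_threshold Minimum reported score (default 0).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(min_tract = 3L, loop_min = 1L, loop_max = 12L,
                        max_width = 50L, allow_defect = FALSE,
                        score_threshold = 0L) {
  p <- list(min_tract = as.integer(min_tract),
            loop_min = as.integer(loop_min),
            loop_max = as.integer(loop_max),
            max_width = as.integer(max_width),
            allow_defect = isTRUE(allow_defect),
            score_threshold = as.integer(score_threshold))
  if (p$min_tract < 2L) stop("min_tract must be >= 2")
  if (p$loop_min < 0L) stop("loop_min must be >= 0")
  if (p$loop_min > p$loop_max) stop("loop_min must be <= loop_max")
  if (p$max_width < 4L * p$min_tract + 3L * p$loop_min)
    stop("max_width too small for four tracts and three loops")
  structure(p, class = "scan_params")
}

#' Find maximal runs of consecutive guanines
#'
#' @param seq A single DNA string over `{A,C,G,T,N}` (case-insensitive);
#'   `N` breaks a run.
#' @param min_len Minimum run length to report (`>= 2`).
#' @return data.frame with columns `start` (0-based), `length`; runs are
#'   maximal, non-overlapping and in left-to-right order.
#' @export
find_g_runs <- function(seq, min_len = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L, min_len >= 2L)
  m <- gregexpr(sprintf("G{%d,}", as.integer(min_len)), toupper(seq))[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), length = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             length = attr(m, "match.length"))
}

# tracts capped at 6 for scoring; min tract likewise capped
.SCORE_TRACT_CAP <- 6L

#' Score a PQS parse
#'
#' The stability score is a linear function of the motif geometry:
#' `15 * t_min + 3 * (G_total - 4 * t_min) - 2 * L_total - 12 * D`,
#' where `t_min` is the shortest tract length (capped at 6), `G_total`
#' the sum of tract lengths (each capped at 6), `L_total` the summed
#' loop length, and `D` the number of defective tracts (0 or 1).
#' Longer, more even tracts raise the score; long loops and defects
#' lower it. Canonical `(G3 N1-12)3 G3` motifs score roughly 25--45;
#' long-tract short-loop motifs exceed 50.
#'
#' @param tracts Integer vector of 4 tract lengths (G counts).
#' @param loops Integer vector of 3 loop lengths (nt, `>= 0`).
#' @param defective Logical vector of 4 flags; at most one may be set,
#'   and non-defective tracts must have length `>= 3` (defective
#'   tracts `>= 2`).
#' @return Integer score.
#' @examples
#' score_pqs(c(3, 3, 3, 3), c(3, 3, 3))            # 27
#' score_pqs(c(3, 3, 3, 3), c(1, 1, 1))            # 39
#' @export
score_pqs <- function(tracts, loops, defective = rep(FALSE, 4)) {
  if (length(tracts) != 4L || length(loops) != 3L || length(defective) != 4L)
    stop("a PQS has exactly 4 tracts, 3 loops and 4 defect flags")
  if (sum(defective) > 1L) stop("at most one defective tract is allowed")
  if (any(tracts < 2L)) stop("tract lengths must be >= 2")
  if (any(tracts[!defective] < 3L))
    stop("non-defective tracts must have length >= 3")
  if (any(loops < 0L)) stop("loop lengths must be >= 0")
  t_min <- min(min(tracts), .SCORE_TRACT_CAP)
  g_tot <- sum(pmin(tracts, .SCORE_TRACT_CAP))
  as.integer(15L * t_min + 3L * (g_tot - 4L * t_min) -
               2L * sum(loops) - 12L * sum(defective))
}

# Candidate generation for one strand of one sequence.
#
# One candidate per admissible choice of four G-runs. Tract lengths are
# realized as prefixes of the maximal runs; because the score strictly
# increases with any interior tract extension (a base moved from loop
# to tract) and is non-increasing in width, the per-quadruple optimum
# under the (score desc, width asc) tie-break is closed-form:
#   interior tracts: longest prefix leaving a loop >= loop_min
#   last tract:      capped at 6 (score plateau) and by max_width
.scan_candidates <- function(seq, params) {
  runs <- find_g_runs(seq, params$min_tract)
  runs$defective <- rep(FALSE, nrow(runs))
  if (params$allow_defect) {
    r2 <- find_g_runs(seq, 2L)
    r2 <- r2[r2$length == 2L, , drop = FALSE]
    if (nrow(r2)) {
      r2$defective <- TRUE
      runs <- rbind(runs, r2)
    }
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = integer(0), n_defective = integer(0),
                      tracts = character(0), loops = character(0))
  n <- nrow(runs)
  if (n < 4L) return(empty)
  runs <- runs[order(runs$start), , drop = FALSE]
  s <- runs$start; L <- runs$length; def <- runs$defective
  tmin <- ifelse(def, 2L, params$min_tract)
  lo_min <- params$loop_min; lo_max <- params$loop_max
  # successor run j is loop-feasible after run i iff some prefix t of i
  # leaves a loop in [loop_min, loop_max]
  succ <- vector("list", n)
  for (i in seq_len(n)) {
    j <- which(s > s[i] &
                 s - s[i] - L[i] <= lo_max &      # shortest loop attainable
                 s - s[i] - tmin[i] >= lo_min)    # longest loop attainable
    succ[[i]] <- j[s[j] + tmin[j] - s[i] <= params$max_width]
  }
  res_start <- integer(0); res_end <- integer(0); res_score <- integer(0)
  res_def <- integer(0); res_tr <- character(0); res_lp <- character(0)

  # best prefix for an interior tract i followed by run at position sj
  interior <- function(i, sj) {
    t <- min(L[i], sj - s[i] - lo_min)
    if (t < tmin[i] || sj - s[i] - t > lo_max) return(NA_integer_)
    if (def[i]) {                       # defective tract length fixed at 2
      lp <- sj - s[i] - 2L
      if (lp < lo_min || lp > lo_max) return(NA_integer_)
      return(2L)
    }
    t
  }
  for (a in seq_len(n)) {
    for (b in succ[[a]]) {
      ta <- interior(a, s[b]); if (is.na(ta)) next
      for (c in succ[[b]]) {
        if (def[a] + def[b] > 1L && def[a] && def[b]) next
        tb <- interior(b, s[c]); if (is.na(tb)) next
        for (d in succ[[c]]) {
          ndef <- def[a] + def[b] + def[c] + def[d]
          if (ndef > 1L) next
          tc <- interior(c, s[d]); if (is.na(tc)) next
          room <- params$max_width - (s[d] - s[a])
          td <- if (def[d]) 2L else min(L[d], .SCORE_TRACT_CAP, room)
          if (td < tmin[d] || td > room) next
          tr <- c(ta, tb, tc, td)
          lp <- c(s[b] - s[a] - ta, s[c] - s[b] - tb, s[d] - s[c] - tc)
          sc <- score_pqs(tr, lp, c(def[a], def[b], def[c], def[d]))
          res_start <- c(res_start, s[a])
          res_end <- c(res_end, s[d] + td)
          res_score <- c(res_score, sc)
          res_def <- c(res_def, ndef)
          res_tr <- c(res_tr, paste(tr, collapse = ","))
          res_lp <- c(res_lp, paste(lp, collapse = ","))
        }
      }
    }
  }
  if (!length(res_start)) return(empty)
  data.frame(start = res_start, end = res_end, score = res_score,
             n_defective = res_def, tracts = res_tr, loops = res_lp)
}

# greedy maximal non-overlapping subset: score desc, start asc, width asc
.greedy_select <- function(cand) {
  if (!nrow(cand)) return(cand)
  o <- order(-cand$score, cand$start, cand$end - cand$start)
  cand <- cand[o, , drop = FALSE]
  sel_start <- integer(0); sel_end <- integer(0); keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < sel_end & cand$end[i] > sel_start)) {
      keep <- c(keep, i)
      sel_start <- c(sel_start, cand$start[i])
      sel_end <- c(sel_end, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Scan one strand of a DNA sequence for PQS
#'
#' Enumerates every admissible choice of four G-runs (one candidate per
#' choice, with tract prefixes realizing the best-scoring valid parse),
#' scores each with [score_pqs()], and by default reduces the candidate
#' set to a maximal non-overlapping subset chosen greedily by
#' (score desc, leftmost, shortest). Candidates below
#' `params$score_threshold` are dropped.
#'
#' @param seq A single DNA string (the strand actually scanned).
#' @param params A [scan_params()] object.
#' @param all_candidates Return the full pre-greedy candidate set
#'   (overlaps permitted), as used for density profiling.
#' @return data.frame with 0-based half-open `start`/`end`, `score`,
#'   `n_defective`, and comma-encoded `tracts`/`loops`, sorted by start.
#' @examples
#' scan_pqs("GGGTGGGTGGGTGGG", scan_params())  # one hit, score 39
#' @export
scan_pqs <- function(seq, params = scan_params(), all_candidates = FALSE) {
  stopifnot(inherits(params, "scan_params"))
  if (!nzchar(seq))
    return(.scan_candidates("", params))
  cand <- .scan_candidates(seq, params)
  if (!all_candidates) cand <- .greedy_select(cand)
  cand <- cand[cand$score >= params$score_threshold, , drop = FALSE]
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

.strand_hits_to_gr <- function(cand, chrom, strand, seqlen) {
  if (!nrow(cand)) return(GRanges())
  if (strand == "-") {
    new_start <- seqlen - cand$end
    new_end <- seqlen - cand$start
    cand$start <- new_start
    cand$end <- new_end
    cand <- cand[order(cand$start), , drop = FALSE]
  }
  gr <- bed_ranges(chrom, cand$start, cand$end, strand = strand)
  mcols(gr)$name <- paste0("t", cand$tracts, ";l", cand$loops,
                           ifelse(cand$n_defective > 0,
                                  paste0(";d", cand$n_defective), ""))
  mcols(gr)$score <- cand$score
  gr
}

#' Scan a genome for PQS on both strands
#'
#' Plus-strand hits come from scanning each sequence directly; minus
#' strand hits from scanning the reverse complement, mapped back to
#' forward coordinates. Greedy non-overlap resolution is applied per
#' strand; hits on opposite strands may overlap.
#'
#' @param x A [Biostrings::DNAStringSet] (names become chromosome
#'   names; duplicates are an error) or a named character vector.
#' @param params A [scan_params()] object.
#' @param all_candidates Return all pre-greedy candidates.
#' @return `GRanges` sorted by (chrom, start) with metadata columns
#'   `name` (tract/loop structure) and `score`.
#' @export
scan_genome <- function(x, params = scan_params(), all_candidates = FALSE) {
  if (is.character(x)) x <- DNAStringSet(x)
  stopifnot(is(x, "DNAStringSet"))
  if (is.null(names(x))) stop("sequences must be named")
  if (anyDuplicated(names(x)))
    stop("duplicate sequence names: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  out <- list()
  for (i in seq_along(x)) {
    chrom <- names(x)[i]
    fwd <- as.character(x[[i]])
    rev <- as.character(reverseComplement(x[[i]]))
    hp <- .strand_hits_to_gr(scan_pqs(fwd, params, all_candidates),
                             chrom, "+", nchar(fwd))
    hm <- .strand_hits_to_gr(scan_pqs(rev, params, all_candidates),
                             chrom, "-", nchar(fwd))
    out[[i]] <- suppressWarnings(c(hp, hm))
  }
  # per-chromosome hit sets necessarily have disjoint seqlevels
  gr <- suppressWarnings(do.call(c, out))
  gr[order(as.character(seqnames(gr)), start(gr), end(gr),
           as.character(strand(gr)))]
}

#' Scan a FASTA file for PQS on both strands
#'
#' @param path Path to a (multi-record) FASTA file.
#' @inheritParams scan_genome
#' @return As [scan_genome()].
#' @export
scan_fasta <- function(path, params = scan_params(), all_candidates = FALSE) {
  x <- readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  scan_genome(x, params, all_candidates)
}
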