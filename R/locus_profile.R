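#' Parse a 1-based region string
#'
#' @param region A string `"chrom:start-end"` with 1-based inclusive
#'   coordinates (commas in numbers tolerated), or a length-1 `GRanges`
#'   returned unchanged.
#' @return A length-1 `GRanges`.
#' @export
parse_region <- function(region) {
  if (is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    return(granges(region))
  }
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region '", region, "'; expected chrom:start-end")
  s <- as.numeric(gsub(",", "", m[3])); e <- as.numeric(gsub(",", "", m[4]))
  if (s < 1 || e < s) stop("region requires 1 <= start <= end")
  GRanges(m[2], IRanges(s, e))
}

#' Binned G4 density and stability profile of a locus
#'
#' Tiles `region` with `bin_size` bins (the last bin may be short) and
#' records, per bin, the number of PQS hits overlapping the bin and the
#' maximum hit score (0 for empty bins). A hit spanning several bins
#' contributes to each of them, so the binned counts sum to at least
#' the number of hits in the region. Density is intended to be computed
#' on the full pre-greedy candidate set
#' (`scan_genome(..., all_candidates = TRUE)`), where overlapping
#' candidates indicate G4-dense sequence.
#'
#' @param hits `GRanges` of scored PQS hits (metadata column `score`).
#' @param region A length-1 `GRanges` or `"chrom:start-end"` string
#'   (1-based inclusive).
#' @param bin_size Bin width in bp (`>= 1`; default 100).
#' @param genome Optional `genome_index`; when supplied, a region
#'   outside the genome is an error.
#' @return A `g4_density_track`: data.frame with columns `chrom`,
#'   `start`, `end` (BED coordinates), `count`, `max_score`, with the
#'   region and bin size as attributes.
#' @export
density_track <- function(hits, region, bin_size = 100L, genome = NULL) {
  stopifnot(is(hits, "GRanges"))
  region <- parse_region(region)
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) stop("bin_size must be >= 1")
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_index"))
    chrom <- as.character(seqnames(region))
    if (!chrom %in% names(genome$seqlengths))
      stop("unknown chromosome: ", chrom)
    if (start(region) < 1L || end(region) > genome$seqlengths[[chrom]])
      stop("region outside chromosome bounds")
  }
  bs <- seq(start(region), end(region), by = bin_size)
  be <- pmin(bs + bin_size - 1L, end(region))
  bins <- GRanges(seqnames(region), IRanges(bs, be))
  count <- countOverlaps(bins, hits, ignore.strand = TRUE)
  max_score <- numeric(length(bins))
  ov <- findOverlaps(bins, hits, ignore.strand = TRUE)
  if (length(ov)) {
    agg <- tapply(mcols(hits)$score[subjectHits(ov)], queryHits(ov), max)
    max_score[as.integer(names(agg))] <- as.numeric(agg)
  }
  out <- data.frame(chrom = as.character(seqnames(bins)),
                    start = start(bins) - 1L, end = end(bins),
                    count = as.integer(count), max_score = max_score,
                    stringsAsFactors = FALSE)
  structure(out, class = c("g4_density_track", "data.frame"),
            region = region, bin_size = bin_size)
}

#' Census of total and high-stability G4 hits
#'
#' Counts all hits and those at or above a stability score threshold
#' (the conventional high-stability cut is 50; "above" is read
#' inclusively by default, switchable with `inclusive = FALSE`).
#'
#' @param hits `GRanges` of scored PQS hits (or any object with a
#'   `score` metadata column / `score` column).
#' @param threshold Score threshold (default 50).
#' @param inclusive Count hits with `score >= threshold` (default);
#'   `FALSE` uses a strict `>`.
#' @return Named integer vector `c(total, high)`.
#' @export
high_stability_census <- function(hits, threshold = 50, inclusive = TRUE) {
  score <- if (is(hits, "GRanges")) mcols(hits)$score else hits$score
  if (is.null(score)) score <- numeric(0)
  high <- if (inclusive) sum(score >= threshold) else sum(score > threshold)
  c(total = length(score), high = as.integer(high))
}
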