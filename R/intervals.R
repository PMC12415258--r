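#' Genome index: chromosome lengths plus an optional exclusion mask
#'
#' A `genome_index` records the shuffling domain for the permutation
#' test: an ordered set of chromosome names with their lengths, and
#' optionally a mask of excluded regions (e.g. assembly gaps) that
#' randomized windows must never intersect.
#'
#' @param seqlengths Named integer/numeric vector of chromosome lengths
#'   (bp, all `>= 1`; names unique).
#' @param mask Optional [GenomicRanges::GRanges] of excluded regions;
#'   every mask range must lie within its chromosome bounds.
#' @return An object of class `genome_index` with elements `seqlengths`
#'   (named integer) and `mask` (`GRanges` or `NULL`).
#' @examples
#' gi <- genome_index(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_index <- function(seqlengths, mask = NULL) {
  if (is.null(names(seqlengths)) || anyNA(names(seqlengths)) ||
      any(names(seqlengths) == ""))
    stop("'seqlengths' must be a named vector of chromosome lengths")
  if (anyDuplicated(names(seqlengths)))
    stop("duplicate chromosome names: ",
         paste(unique(names(seqlengths)[duplicated(names(seqlengths))]),
               collapse = ", "))
  lens <- as.integer(round(seqlengths))
  if (anyNA(lens) || any(lens < 1L))
    stop("all chromosome lengths must be positive integers")
  names(lens) <- names(seqlengths)
  if (!is.null(mask)) {
    stopifnot(is(mask, "GRanges"))
    m_chr <- as.character(seqnames(mask))
    bad <- !(m_chr %in% names(lens))
    if (any(bad))
      stop("mask chromosome not in genome: ",
           paste(unique(m_chr[bad]), collapse = ", "))
    if (any(start(mask) < 1L) || any(end(mask) > lens[m_chr]))
      stop("mask intervals must lie within chromosome bounds")
    mask <- reduce(granges(mask), ignore.strand = TRUE)
  }
  structure(list(seqlengths = lens, mask = mask), class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$seqlengths), "chromosome(s),",
      format(sum(as.numeric(x$seqlengths)), big.mark = ","), "bp total\n")
  if (!is.null(x$mask))
    cat("  mask:", length(x$mask), "region(s),",
        format(sum(width(x$mask)), big.mark = ","), "bp masked\n")
  invisible(x)
}

#' Read a two-column chrom.sizes file into a genome index
#'
#' @param path Tab-separated file with columns name and length.
#' @param mask Optional mask `GRanges` passed through to [genome_index()].
#' @return A `genome_index`.
#' @export
read_chrom_sizes <- function(path, mask = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  genome_index(setNames(df$length, df$chrom), mask = mask)
}

#' Write a genome index as a chrom.sizes file
#' @param genome A `genome_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_index"))
  writeLines(paste(names(genome$seqlengths), genome$seqlengths, sep = "\t"),
             path)
  invisible(path)
}

.seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome$seqlengths),
          seqlengths = unname(genome$seqlengths))
}

#' Construct a GRanges from BED-style (0-based, half-open) coordinates
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @param strand Strand (`"+"`, `"-"` or `"."`/`"*"`).
#' @param ... Further metadata columns (e.g. `name`, `score`).
#' @return A `GRanges` (internally 1-based, closed).
#' @export
bed_ranges <- function(chrom, start, end, strand = "*", ...) {
  if (any(start < 0) || any(end <= start))
    stop("BED coordinates require 0 <= start < end")
  strand <- ifelse(strand == ".", "*", strand)
  GRanges(chrom, IRanges(start + 1L, end), strand = strand, ...)
}

#' View a GRanges in BED coordinates
#'
#' @param gr A `GRanges`.
#' @return A data.frame with 0-based half-open `start`/`end`, `strand`
#'   (`"."` for unstranded) and any metadata columns.
#' @export
as_bed_df <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = end(gr),
                   stringsAsFactors = FALSE)
  st <- as.character(strand(gr))
  df$strand <- ifelse(st == "*", ".", st)
  md <- as.data.frame(mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  rownames(df) <- NULL
  df
}

#' Clip an interval to its chromosome bounds
#'
#' Intersects each range with `[0, chrom_length)`; ranges falling
#' entirely outside their chromosome are dropped. Zero-length results
#' are never returned.
#'
#' @param gr A `GRanges`.
#' @param genome A `genome_index`; every chromosome of `gr` must be
#'   present (unknown chromosomes raise an error naming them).
#' @return The clipped `GRanges` (possibly shorter than the input).
#' @export
clip_to_chrom <- function(gr, genome) {
  stopifnot(is(gr, "GRanges"), inherits(genome, "genome_index"))
  chr <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chr), names(genome$seqlengths))
  if (length(unknown))
    stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  lens <- genome$seqlengths[chr]
  new_start <- pmax(start(gr), 1L)
  new_end <- pmin(end(gr), lens)
  keep <- new_start <= new_end
  gr <- gr[keep]
  ranges(gr) <- IRanges(new_start[keep], new_end[keep])
  gr
}

#' Do two intervals overlap?
#'
#' Half-open semantics: ranges sharing only a boundary (BED `a.end ==
#' b.start`) do not overlap. Strand is ignored unless
#' `strand_aware = TRUE`, in which case `+` and `-` never overlap
#' (unstranded `*` matches either).
#'
#' @param a,b `GRanges` of equal length (or one of length 1, recycled);
#'   compared element-wise.
#' @param strand_aware Require compatible strands (default `FALSE`).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b, strand_aware = FALSE) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  hit <- as.character(seqnames(a)) == as.character(seqnames(b)) &
    start(a) <= end(b) & start(b) <= end(a)
  if (strand_aware) {
    sa <- as.character(strand(a)); sb <- as.character(strand(b))
    hit <- hit & (sa == "*" | sb == "*" | sa == sb)
  }
  unname(hit)
}

#' Count queries overlapping at least one subject
#'
#' The count-once overlap statistic: the number of query ranges that
#' overlap one or more subject ranges, each query counted at most once
#' however many subjects it touches. Strand is ignored.
#'
#' @param queries,subjects `GRanges`.
#' @return A single integer, invariant to input order.
#' @export
count_query_hits <- function(queries, subjects) {
  stopifnot(is(queries, "GRanges"), is(subjects, "GRanges"))
  if (length(queries) == 0L || length(subjects) == 0L) return(0L)
  sum(overlapsAny(queries, subjects, ignore.strand = TRUE))
}

# Fast ANY-overlap test used inside the permutation loop.
# Subject preprocessing: per-chromosome start-sorted starts plus the
# running maximum of ends, so each query needs one findInterval call.
.overlap_subject_index <- function(subjects) {
  if (length(subjects) == 0L) return(list())
  chr <- as.character(seqnames(subjects))
  out <- list()
  for (c in unique(chr)) {
    i <- which(chr == c)
    o <- order(start(subjects)[i])
    s <- start(subjects)[i][o]
    e <- cummax(end(subjects)[i][o])
    out[[c]] <- list(start = s, cummax_end = e)
  }
  out
}

# q_chrom: character; q_start/q_end: 1-based closed. Returns logical.
.any_overlap_fast <- function(q_chrom, q_start, q_end, sidx) {
  hit <- logical(length(q_chrom))
  if (!length(sidx)) return(hit)
  for (c in unique(q_chrom)) {
    si <- sidx[[c]]
    if (is.null(si)) next
    i <- which(q_chrom == c)
    k <- findInterval(q_end[i], si$start)
    ok <- k >= 1L
    ok[ok] <- si$cummax_end[k[ok]] >= q_start[i][ok]
    hit[i] <- ok
  }
  hit
}

#' Read a BED3/BED6 file
#'
#' Tab-separated, no header; columns chrom, start, end and optionally
#' name, score, strand. Malformed lines are rejected with the offending
#' line number; records with `start >= end` are rejected.
#'
#' @param path BED file path.
#' @return `GRanges` with metadata columns `name` and `score` when
#'   present in the file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines))
    return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": requires 0 <= start < end")
  name <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  score <- if (all(nf >= 5L))
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))) else NULL
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, "", 6L) else "*"
  gr <- bed_ranges(chrom, start, end, strand = strand)
  if (!is.null(name)) mcols(gr)$name <- name
  if (!is.null(score)) mcols(gr)$score <- score
  gr
}

.fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write intervals as BED
#'
#' Emits BED6 when `name`, `score` or strand information is present,
#' BED3 otherwise. Output is byte-deterministic for a given input.
#'
#' @param gr A `GRanges`; metadata columns `name` and `score` are used
#'   when present (missing values written as `.` and `0`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  chrom <- as.character(seqnames(gr))
  start0 <- .fmt_int(start(gr) - 1L)
  end0 <- .fmt_int(end(gr))
  md <- mcols(gr)
  st <- as.character(strand(gr))
  bed6 <- "name" %in% names(md) || "score" %in% names(md) || any(st != "*")
  if (bed6) {
    name <- if ("name" %in% names(md)) as.character(md$name) else
      rep(".", length(gr))
    name[is.na(name)] <- "."
    score <- if ("score" %in% names(md)) md$score else rep(0, length(gr))
    score[is.na(score)] <- 0
    lines <- paste(chrom, start0, end0, name, .fmt_int(score),
                   ifelse(st == "*", ".", st), sep = "\t")
  } else {
    lines <- paste(chrom, start0, end0, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a binned value track as bedGraph
#'
#' @param bins A `GRanges` (or a data.frame with `chrom`/`start`/`end`
#'   in BED coordinates) tiling the region of interest.
#' @param values Numeric vector, one value per bin.
#' @param path Output path.
#' @param track_name Optional track line name; omitted when `NULL`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, values, path, track_name = NULL) {
  if (is(bins, "GRanges")) {
    chrom <- as.character(seqnames(bins))
    start0 <- start(bins) - 1L
    end0 <- end(bins)
  } else {
    chrom <- bins$chrom; start0 <- bins$start; end0 <- bins$end
  }
  stopifnot(length(values) == length(chrom))
  lines <- paste(chrom, .fmt_int(start0), .fmt_int(end0),
                 format(values, scientific = FALSE, trim = TRUE), sep = "\t")
  if (!is.null(track_name))
    lines <- c(sprintf('track type=bedGraph name="%s"', track_name), lines)
  writeLines(lines, path)
  invisible(path)
}
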