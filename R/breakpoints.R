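#' @rdname breakpoints_from_vcf
#' @format NULL
#' @export
VARIANT_CLASSES <- c("SNV", "insertion", "deletion", "inversion",
                     "translocation", "tandem_duplication",
                     "CN_gain", "CN_loss")

.bp_df <- function(chrom = character(0), pos = integer(0),
                   variant_class = character(0), sample = character(0),
                   end_role = character(0)) {
  stopifnot(all(variant_class %in% VARIANT_CLASSES))
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             variant_class = variant_class, sample = as.character(sample),
             end_role = end_role, stringsAsFactors = FALSE)
}

#' Extract breakpoints from variant call files
#'
#' Breakpoints are single 0-based genomic positions derived from the
#' ends of variant calls, each carrying a variant class from the closed
#' vocabulary `VARIANT_CLASSES` and a sample id.
#'
#' `breakpoints_from_vcf()` handles sequence-resolved small variants
#' (1-based VCF positions, converted internally): an SNV at VCF
#' position `P` yields one breakpoint at `P - 1`; a deletion of `r - 1`
#' bases (`nchar(REF) = r`, `nchar(ALT) = 1`) yields breakpoints at `P`
#' (first deleted base) and `P + r - 1` (one past the last deleted
#' base), its two "ends"; an insertion yields one breakpoint at the
#' junction `P`. Symbolic ALT alleles (`<DEL>`, breakend notation) are
#' rejected -- structural variants enter via BEDPE.
#'
#' @param path Input file path.
#' @param sample Sample identifier attached to every breakpoint.
#' @param multiallelic `"split"` (default) expands comma-separated ALT
#'   alleles into one pseudo-record each; `"reject"` raises an error.
#' @return data.frame with columns `chrom`, `pos` (0-based),
#'   `variant_class`, `sample`, `end_role`.
#' @export
breakpoints_from_vcf <- function(path, sample,
                                 multiallelic = c("split", "reject")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (!nrow(fix)) return(.bp_df())
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "reject")
      stop("multi-allelic record at ", chrom[multi][1], ":", pos[multi][1])
    alts <- strsplit(alt, ",", fixed = TRUE)
    k <- lengths(alts)
    chrom <- rep(chrom, k); pos <- rep(pos, k); ref <- rep(ref, k)
    alt <- unlist(alts)
  }
  if (any(grepl("[][<>]", alt)))
    stop("symbolic/breakend ALT alleles are not supported here; ",
         "supply structural variants as BEDPE")
  rl <- nchar(ref); al <- nchar(alt)
  out <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    out[[i]] <-
      if (rl[i] == 1L && al[i] == 1L) {
        .bp_df(chrom[i], pos[i] - 1L, "SNV", sample, "single")
      } else if (rl[i] > 1L && al[i] == 1L) {
        .bp_df(rep(chrom[i], 2), c(pos[i], pos[i] + rl[i] - 1L),
               rep("deletion", 2), rep(sample, 2), c("start", "end"))
      } else if (rl[i] == 1L && al[i] > 1L) {
        .bp_df(chrom[i], pos[i], "insertion", sample, "single")
      } else {
        stop("unsupported allele pair at ", chrom[i], ":", pos[i],
             " (REF=", ref[i], ", ALT=", alt[i], ")")
      }
  }
  do.call(rbind, out)
}

# default label -> class alias table for BEDPE SV classes
.SV_ALIASES <- c(
  DEL = "deletion", deletion = "deletion", Deletion = "deletion",
  INV = "inversion", inversion = "inversion", Inversion = "inversion",
  TRA = "translocation", BND = "translocation", CTX = "translocation",
  translocation = "translocation", Translocation = "translocation",
  DUP = "tandem_duplication", TD = "tandem_duplication",
  tandem_duplication = "tandem_duplication",
  `tandem-duplication` = "tandem_duplication",
  tandem_dup = "tandem_duplication"
)

#' @rdname breakpoints_from_vcf
#' @param class_col Column index holding the SV class label
#'   (default 11, the first column after the 10 standard BEDPE fields).
#' @param aliases Named character vector mapping class labels found in
#'   the file to `VARIANT_CLASSES` entries; unknown labels raise an
#'   error listing the known aliases.
#' @details `breakpoints_from_bedpe()` reads tab-separated BEDPE
#'   (0-based half-open end intervals); each record contributes two
#'   breakpoints, the midpoints (rounded down) of its two end
#'   intervals, with roles `mate_A`/`mate_B`.
#' @export
breakpoints_from_bedpe <- function(path, sample, class_col = 11L,
                                   aliases = .SV_ALIASES) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (!nrow(df)) return(.bp_df())
  if (ncol(df) < class_col)
    stop("BEDPE has ", ncol(df), " columns; class column ", class_col,
         " not present")
  lab <- as.character(df[[class_col]])
  unknown <- setdiff(unique(lab), names(aliases))
  if (length(unknown))
    stop("unknown SV class label(s): ", paste(unknown, collapse = ", "),
         "; known aliases: ", paste(names(aliases), collapse = ", "))
  cls <- unname(aliases[lab])
  mid_a <- (df[[2]] + df[[3]]) %/% 2L
  mid_b <- (df[[5]] + df[[6]]) %/% 2L
  n <- nrow(df)
  idx <- rep(seq_len(n), each = 2L)
  .bp_df(chrom = as.character(rbind(df[[1]], df[[4]])),
         pos = as.integer(rbind(mid_a, mid_b)),
         variant_class = cls[idx], sample = rep(sample, 2L * n),
         end_role = rep(c("mate_A", "mate_B"), n))
}

#' @rdname breakpoints_from_vcf
#' @param genome Optional `genome_index`; when given, segment
#'   boundaries coinciding with a chromosome terminus (position 0 or
#'   the chromosome length) are dropped, since a telomere-touching
#'   segment has no interior junction there.
#' @details `breakpoints_from_segments()` reads tab-separated
#'   copy-number segments `chrom start end state` (0-based half-open)
#'   where `state` is `gain`/`loss` or a signed log2 ratio (positive
#'   maps to gain, negative to loss; exactly 0 is an error). Each
#'   segment contributes its start and end boundary as breakpoints of
#'   class `CN_gain` or `CN_loss`.
#' @export
breakpoints_from_segments <- function(path, sample, genome = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (!nrow(df)) return(.bp_df())
  if (ncol(df) < 4L) stop("segment file needs columns chrom/start/end/state")
  if (any(df[[2]] >= df[[3]]))
    stop("segment with start >= end at line ",
         which(df[[2]] >= df[[3]])[1])
  state <- as.character(df[[4]])
  num <- suppressWarnings(as.numeric(state))
  cls <- ifelse(state %in% c("gain", "+"), "CN_gain",
         ifelse(state %in% c("loss", "-"), "CN_loss",
         ifelse(!is.na(num) & num > 0, "CN_gain",
         ifelse(!is.na(num) & num < 0, "CN_loss", NA))))
  if (anyNA(cls))
    stop("unrecognized copy-number state: ",
         paste(unique(state[is.na(cls)]), collapse = ", "))
  n <- nrow(df)
  chrom <- as.character(df[[1]])
  out <- .bp_df(chrom = rep(chrom, each = 2L),
                pos = as.integer(rbind(df[[2]], df[[3]])),
                variant_class = rep(cls, each = 2L),
                sample = rep(sample, 2L * n),
                end_role = rep(c("start", "end"), n))
  # drop boundaries at chromosome termini
  keep <- out$pos != 0L
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_index"))
    lens <- genome$seqlengths[out$chrom]
    if (anyNA(lens))
      stop("unknown chromosome: ",
           paste(unique(out$chrom[is.na(lens)]), collapse = ", "))
    keep <- keep & out$pos != lens
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build fixed-width windows around breakpoints
#'
#' Each breakpoint at position `pos` becomes a window
#' `[pos - w/2, pos + w/2)` (0-based half-open) clipped to its
#' chromosome, so windows have exactly `window_size` bp except at
#' chromosome edges. With `dedupe = TRUE` (default) windows with
#' identical coordinates collapse to one record -- duplicate calls then
#' cannot inflate the permutation statistic -- with the contributing
#' classes retained as a comma-joined sorted list.
#'
#' @param bps Breakpoint data.frame as returned by the
#'   `breakpoints_from_*` parsers (rows from several parsers may be
#'   `rbind`ed together).
#' @param window_size Window width in bp (even, `>= 2`); the headline
#'   analysis uses 100 and 1000.
#' @param genome A `genome_index`; breakpoints outside
#'   `[0, chrom_length]` are an error.
#' @param dedupe Collapse coordinate-identical windows (default `TRUE`).
#' @return `GRanges` sorted by (chrom, start) with metadata columns
#'   `variant_class` (comma-joined when collapsed), `sample`,
#'   `window_size`, `n_breakpoints` and `name`
#'   (`variant_class|sample`).
#' @export
make_windows <- function(bps, window_size, genome, dedupe = TRUE) {
  stopifnot(inherits(genome, "genome_index"))
  window_size <- as.integer(window_size)
  if (window_size < 2L || window_size %% 2L != 0L)
    stop("window_size must be an even integer >= 2")
  if (!nrow(bps)) stop("no breakpoints supplied")
  lens <- genome$seqlengths[bps$chrom]
  if (anyNA(lens))
    stop("unknown chromosome: ",
         paste(unique(bps$chrom[is.na(lens)]), collapse = ", "))
  if (any(bps$pos < 0L | bps$pos > lens))
    stop("breakpoint position outside chromosome bounds")
  h <- window_size %/% 2L
  start0 <- pmax(bps$pos - h, 0L)
  end0 <- pmin(bps$pos + h, lens)
  key <- paste(bps$chrom, start0, end0, sep = ":")
  if (dedupe) {
    grp <- split(seq_along(key), key)
  } else {
    grp <- as.list(seq_along(key))
  }
  first <- vapply(grp, `[`, 1L, 1L)
  cls <- vapply(grp, function(i)
    paste(sort(unique(bps$variant_class[i])), collapse = ","), "")
  smp <- vapply(grp, function(i)
    paste(sort(unique(bps$sample[i])), collapse = ","), "")
  gr <- bed_ranges(bps$chrom[first], start0[first], end0[first])
  mcols(gr)$variant_class <- unname(cls)
  mcols(gr)$sample <- unname(smp)
  mcols(gr)$window_size <- window_size
  mcols(gr)$n_breakpoints <- unname(lengths(grp))
  mcols(gr)$name <- paste(cls, smp, sep = "|")
  gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}
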