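#' Configuration for an end-to-end colocalization run
#'
#' Collects every path and parameter that affects the analysis so a
#' run is reproducible from its config and seed alone.
#'
#' @param chrom_sizes Path to a chrom.sizes file (or a `genome_index`).
#' @param variants Named list of variant file paths by source:
#'   `small` (VCF), `sv` (BEDPE), `cnv` (SEG). Only the sources listed
#'   in `sources` are read.
#' @param g4_sets Named list of G4 BED paths (or `GRanges`), e.g. the
#'   computationally predicted set plus experimentally derived sets.
#' @param outdir Output directory.
#' @param sample_id Sample identifier.
#' @param window_sizes Window widths in bp (default `c(100, 1000)`).
#' @param sources Subset of `c("small", "sv", "cnv")` to analyse.
#' @param n_perm Permutations per test (default 999, giving a p-value
#'   floor of 0.001).
#' @param alternative `"greater"` or `"less"`.
#' @param seed Integer seed (mandatory).
#' @param mask Optional mask BED path or `GRanges`.
#' @param dedupe Collapse identical windows (default `TRUE`).
#' @return A `run_config` list.
#' @export
run_config <- function(chrom_sizes, variants, g4_sets, outdir,
                       sample_id = "sample", window_sizes = c(100, 1000),
                       sources = names(variants), n_perm = 999,
                       alternative = "greater", seed, mask = NULL,
                       dedupe = TRUE) {
  window_sizes <- as.integer(window_sizes)
  if (any(window_sizes < 2L) || any(window_sizes %% 2L != 0L))
    stop("window sizes must be positive even integers")
  if (as.integer(n_perm) < 1L) stop("n_perm must be >= 1")
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for permutation runs")
  sources <- match.arg(sources, c("small", "sv", "cnv"),
                       several.ok = TRUE)
  if (is.null(names(g4_sets))) stop("g4_sets must be named")
  structure(list(chrom_sizes = chrom_sizes, variants = variants,
                 g4_sets = g4_sets, outdir = outdir,
                 sample_id = sample_id, window_sizes = window_sizes,
                 sources = sources, n_perm = as.integer(n_perm),
                 alternative = alternative, seed = as.integer(seed),
                 mask = mask, dedupe = isTRUE(dedupe)),
            class = "run_config")
}

.load_genome_index <- function(config) {
  mask <- config$mask
  if (is.character(mask)) mask <- read_bed(mask)
  if (inherits(config$chrom_sizes, "genome_index")) {
    gi <- config$chrom_sizes
    if (!is.null(mask)) gi <- genome_index(gi$seqlengths, mask)
    gi
  } else {
    read_chrom_sizes(config$chrom_sizes, mask = mask)
  }
}

.load_g4_set <- function(x) if (is.character(x)) read_bed(x) else x

.collect_breakpoints <- function(config, genome) {
  parts <- list()
  v <- config$variants
  if ("small" %in% config$sources && !is.null(v$small) && !is.na(v$small))
    parts$small <- breakpoints_from_vcf(v$small, config$sample_id)
  if ("sv" %in% config$sources && !is.null(v$sv) && !is.na(v$sv))
    parts$sv <- breakpoints_from_bedpe(v$sv, config$sample_id)
  if ("cnv" %in% config$sources && !is.null(v$cnv) && !is.na(v$cnv))
    parts$cnv <- breakpoints_from_segments(v$cnv, config$sample_id,
                                           genome = genome)
  if (!length(parts)) stop("no variant sources available")
  do.call(rbind, c(parts, make.row.names = FALSE))
}

.input_manifest <- function(config) {
  paths <- c(unlist(config$variants[config$sources], use.names = FALSE),
             if (is.character(config$chrom_sizes)) config$chrom_sizes,
             unlist(Filter(is.character, config$g4_sets),
                    use.names = FALSE),
             if (is.character(config$mask)) config$mask)
  paths <- unname(paths[!is.na(paths)])
  if (!length(paths)) return(list())
  md5 <- tools::md5sum(paths)
  lapply(seq_along(paths), function(i)
    list(path = paths[i], md5 = unname(md5[i])))
}

.result_to_list <- function(r, keep_perm = FALSE) {
  out <- list(n_windows = r$n_windows, observed = r$observed,
              observed_fraction = r$observed_fraction,
              n_perm = r$n_perm, p_value = r$p_value,
              z_score = if (r$z_defined) r$z_score else NULL,
              z_defined = r$z_defined, alternative = r$alternative,
              perm_mean = mean(r$perm_counts),
              perm_sd = stats::sd(r$perm_counts))
  if (keep_perm) out$perm_counts <- r$perm_counts
  out
}

#' Run the full colocalization analysis
#'
#' Parses the configured variant sources into breakpoints, builds
#' windows at each configured size, and runs the permutation overlap
#' test for every (window size, G4 set) pair. Writes a JSON report, a
#' per-class overlap TSV, optionally the permuted counts, and a run
#' manifest with the seed and an MD5 of every input. On error any
#' partial outputs are removed.
#'
#' @param config A [run_config()].
#' @param write_perm_counts Also write permuted counts as TSV for
#'   plotting (default `FALSE`).
#' @return Invisibly, a nested list of `overlap_result`s indexed as
#'   `results[[window_size]][[g4_set]]`, plus the class table.
#' @export
run_colocalization <- function(config, write_perm_counts = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("colocalization run failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    genome <- .load_genome_index(config)
    g4_sets <- lapply(config$g4_sets, .load_g4_set)
    bps <- .collect_breakpoints(config, genome)
    results <- list(); tables <- list(); combo <- 0L
    for (ws in config$window_sizes) {
      windows <- make_windows(bps, ws, genome, dedupe = config$dedupe)
      tables[[as.character(ws)]] <- class_overlap_table(windows, g4_sets)
      for (set_name in names(g4_sets)) {
        combo <- combo + 1L
        results[[as.character(ws)]][[set_name]] <-
          perm_test(windows, g4_sets[[set_name]], genome,
                    n_perm = config$n_perm,
                    alternative = config$alternative,
                    seed = config$seed + combo)
      }
    }
    class_table <- do.call(rbind, c(tables, make.row.names = FALSE))

    report <- list(
      sample = config$sample_id,
      parameters = list(window_sizes = config$window_sizes,
                        sources = config$sources,
                        n_perm = config$n_perm,
                        alternative = config$alternative,
                        seed = config$seed,
                        dedupe = config$dedupe),
      results = lapply(results, function(by_set)
        lapply(by_set, .result_to_list)))
    report_path <- file.path(config$outdir, "overlap_report.json")
    written <- c(written, report_path)
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    table_path <- file.path(config$outdir, "class_overlap.tsv")
    written <- c(written, table_path)
    write.table(class_table, table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)

    if (write_perm_counts) {
      pc <- do.call(rbind, lapply(names(results), function(ws)
        do.call(rbind, lapply(names(results[[ws]]), function(sn)
          data.frame(window_size = ws, g4_set = sn,
                     perm = seq_len(results[[ws]][[sn]]$n_perm),
                     count = results[[ws]][[sn]]$perm_counts)))))
      pc_path <- file.path(config$outdir, "perm_counts.tsv")
      written <- c(written, pc_path)
      write.table(pc, pc_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }

    manifest <- list(
      package = "g4coloc",
      version = as.character(utils::packageVersion("g4coloc")),
      seed = config$seed,
      parameters = report$parameters,
      inputs = .input_manifest(config))
    manifest_path <- file.path(config$outdir, "run_manifest.json")
    written <- c(written, manifest_path)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    invisible(list(results = results, class_table = class_table,
                   files = written))
  }, error = on_fail)
}

#' Simulate one dataset and run the colocalization test on it
#'
#' One replicate of the calibration/power study: simulate a genome
#' with planted G4s and biased breakpoints ([simulate_dataset()]),
#' parse the emitted VCF/BEDPE/SEG with the breakpoint parsers, build
#' windows, and run [perm_test()] against the simulated G4 truth set.
#' With `pi = 0` the null holds and the returned p-value is a
#' calibration draw; with `pi > 0` it is a power draw.
#'
#' @inheritParams simulate_dataset
#' @param window_size Window width in bp (default 100, matching the
#'   `d_max` scale of the anchoring kernel).
#' @param n_perm Permutations (default 199).
#' @param keep_files Keep the simulated files on disk (default
#'   `FALSE`: the temporary dataset directory is removed).
#' @return The `overlap_result`, with the dataset attached as
#'   attribute `"dataset"` when `keep_files = TRUE`.
#' @export
simulate_and_test <- function(chrom_lengths = c(chr1 = 2e6), n_g4 = 50,
                              n_events = 50, pi = 0, d_max = 50,
                              window_size = 100, n_perm = 199, seed,
                              keep_files = FALSE, ...) {
  dir <- tempfile("simrep")
  ds <- simulate_dataset(chrom_lengths = chrom_lengths, n_g4 = n_g4,
                         n_events = n_events, pi = pi, d_max = d_max,
                         seed = seed, dir = dir, ...)
  f <- ds$sim$files
  parts <- list()
  if (!is.na(f$vcf))
    parts$small <- breakpoints_from_vcf(f$vcf, ds$sim$sample_id)
  if (!is.na(f$bedpe))
    parts$sv <- breakpoints_from_bedpe(f$bedpe, ds$sim$sample_id)
  if (!is.na(f$seg))
    parts$cnv <- breakpoints_from_segments(f$seg, ds$sim$sample_id,
                                           genome = ds$index)
  bps <- do.call(rbind, c(parts, make.row.names = FALSE))
  windows <- make_windows(bps, window_size, ds$index)
  res <- perm_test(windows, ds$g4s, ds$index, n_perm = n_perm,
                   seed = seed + 1L)
  if (keep_files) attr(res, "dataset") <- ds
  else unlink(dir, recursive = TRUE)
  res
}

#' Scan a FASTA file and write scored PQS intervals as BED
#'
#' @param fasta Input FASTA path.
#' @param out Output BED path.
#' @param params [scan_params()].
#' @param all_candidates Write the full pre-greedy candidate set.
#' @return The hit `GRanges`, invisibly.
#' @export
run_scan <- function(fasta, out, params = scan_params(),
                     all_candidates = FALSE) {
  hits <- scan_fasta(fasta, params, all_candidates = all_candidates)
  write_bed(hits, out)
  invisible(hits)
}

#' Simulate a dataset and write all its files
#'
#' @param outdir Output directory for FASTA, chrom.sizes, truth BEDs,
#'   variant files and the JSON truth ledger.
#' @inheritParams simulate_dataset
#' @param ... Passed to [simulate_dataset()].
#' @return The [simulate_dataset()] result, invisibly, with a `files`
#'   element listing everything written.
#' @export
run_simulate <- function(outdir, chrom_lengths = c(chr1 = 2e6),
                         n_g4 = 50, n_events = 50, pi = 0, d_max = 50,
                         seed, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(chrom_lengths = chrom_lengths, n_g4 = n_g4,
                         n_events = n_events, pi = pi, d_max = d_max,
                         seed = seed, dir = outdir, ...)
  fasta <- file.path(outdir, "genome.fa")
  writeXStringSet(ds$genome, fasta)
  sizes <- file.path(outdir, "genome.chrom.sizes")
  write_chrom_sizes(ds$index, sizes)
  planted_bed <- file.path(outdir, "planted_g4.bed")
  write_bed(ds$planted, planted_bed)
  truth_bed <- file.path(outdir, "truth_g4.bed")
  write_bed(ds$g4s, truth_bed)
  ledger <- file.path(outdir, "truth.json")
  jsonlite::write_json(
    list(pi = ds$sim$pi, d_max = ds$sim$d_max, seed = seed,
         class_mix = as.list(ds$sim$class_mix),
         events = ds$sim$events, breakpoints = ds$sim$breakpoints),
    ledger, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ds$files <- c(list(fasta = fasta, chrom_sizes = sizes,
                     planted_bed = planted_bed, truth_bed = truth_bed,
                     ledger = ledger), ds$sim$files)
  invisible(ds)
}

#' Profile G4 density over a region and write bedGraph tracks
#'
#' @param pqs_bed BED of scored PQS intervals (e.g. from [run_scan()]
#'   with `all_candidates = TRUE`) or a `GRanges`.
#' @param region Region string `"chrom:start-end"` (1-based inclusive)
#'   or `GRanges`.
#' @param out_prefix Output prefix; writes
#'   `<prefix>.count.bedGraph` and `<prefix>.max_score.bedGraph`.
#' @param bin_size Bin width (default 100).
#' @param genome Optional `genome_index` for bounds checking.
#' @return The `g4_density_track`, invisibly.
#' @export
run_profile <- function(pqs_bed, region, out_prefix, bin_size = 100L,
                        genome = NULL) {
  hits <- .load_g4_set(pqs_bed)
  track <- density_track(hits, region, bin_size = bin_size,
                         genome = genome)
  write_bedgraph(track, track$count,
                 paste0(out_prefix, ".count.bedGraph"),
                 track_name = "g4_count")
  write_bedgraph(track, track$max_score,
                 paste0(out_prefix, ".max_score.bedGraph"),
                 track_name = "g4_max_score")
  invisible(track)
}
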