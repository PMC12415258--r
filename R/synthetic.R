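# Default variant-class mixture for simulated tumors: small deletions
# form the largest single class, with the remaining mass spread over
# the other small-variant, SV and copy-number classes.
.DEFAULT_CLASS_MIX <- c(SNV = 0.15, insertion = 0.10, deletion = 0.25,
                        inversion = 0.10, translocation = 0.10,
                        tandem_duplication = 0.10,
                        CN_gain = 0.10, CN_loss = 0.10)

.VCF_CLASSES <- c("SNV", "insertion", "deletion")
.SV_CLASSES <- c("inversion", "translocation", "tandem_duplication")
.CNV_CLASSES <- c("CN_gain", "CN_loss")

#' Generate a random genome
#'
#' Draws i.i.d. nucleotides with `P(G) = P(C) = g_fraction` and the
#' remaining probability split evenly over A and T. Suppression is
#' strand-symmetric (C mirrors G) because PQS are scanned on both
#' strands: a C-rich sequence is G-rich on its complement. The default
#' fraction of 0.10 is deliberately G/C-suppressed so that planted G4
#' motifs dominate the spontaneous PQS background and scanner recall
#' is measurable.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp,
#'   `>= 1000`).
#' @param g_fraction Probability of G at each base, in `(0, 0.5]`
#'   (default 0.10).
#' @param seed Optional integer seed; the result is a pure function of
#'   (parameters, seed).
#' @return List with `genome` ([Biostrings::DNAStringSet]) and `index`
#'   (a `genome_index`).
#' @export
generate_genome <- function(chrom_lengths = c(chr1 = 2e6),
                            g_fraction = 0.10, seed = NULL) {
  if (any(chrom_lengths < 1000)) stop("chromosome lengths must be >= 1 kb")
  if (g_fraction <= 0 || g_fraction > 0.5)
    stop("g_fraction must be in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  at <- (1 - 2 * g_fraction) / 2
  alphabet <- charToRaw("ACGT")
  seqs <- vapply(chrom_lengths, function(len) {
    rawToChar(alphabet[sample.int(4L, len, replace = TRUE,
                                  prob = c(at, g_fraction, g_fraction, at))])
  }, "")
  genome <- DNAStringSet(seqs)
  names(genome) <- names(chrom_lengths)
  list(genome = genome, index = genome_index(chrom_lengths))
}

# one canonical PQS motif string: 4 G-tracts, 3 non-G loops
.random_motif <- function(tract_len, loop_len) {
  tr <- sample(tract_len, 4L, replace = TRUE)
  lp <- sample(loop_len, 3L, replace = TRUE)
  loops <- vapply(lp, function(k)
    paste(sample(c("A", "C", "T"), k, replace = TRUE), collapse = ""), "")
  list(seq = paste0(strrep("G", tr[1]), loops[1], strrep("G", tr[2]),
                    loops[2], strrep("G", tr[3]), loops[3],
                    strrep("G", tr[4])),
       tracts = tr, loops = lp)
}

#' Plant canonical PQS motifs into a genome
#'
#' Overwrites `n` non-overlapping sites (pairwise gaps `>= min_gap`)
#' with generated canonical G4 motifs -- four G-tracts of 3--5 Gs
#' separated by 1--7 nt non-G loops by default -- and returns the
#' planted truth set. One base on each side of a planted motif is set
#' to `T` so adjacent genomic Gs cannot merge into the planted tracts.
#' By default the function audits itself (the scanner must report a hit
#' overlapping every planted site) and augments the truth set with
#' spontaneously occurring PQS found by a post-plant scan of the full
#' genome, so the truth is the complete G4 interval set of the
#' simulated world.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param n Number of motifs to plant (`>= 0`).
#' @param tract_len,loop_len Integer vectors the per-motif tract and
#'   loop lengths are drawn from (defaults `3:5` and `1:7`).
#' @param min_gap Minimum gap between planted sites in bp (default 200).
#' @param params [scan_params()] used for the audit and the
#'   spontaneous-hit scan.
#' @param spontaneous Add scanner hits outside planted sites to the
#'   truth set (default `TRUE`).
#' @param audit Verify scanner recall over planted sites (default
#'   `TRUE`).
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts per motif before giving up.
#' @return List with `genome` (modified `DNAStringSet`), `planted`
#'   (`GRanges` of planted sites with `tracts`/`loops`/`score`
#'   metadata) and `truth` (`GRanges`, planted sites plus spontaneous
#'   scanner hits, metadata column `origin`).
#' @export
plant_pqs <- function(genome, n, tract_len = 3:5, loop_len = 1:7,
                      min_gap = 200L, params = scan_params(),
                      spontaneous = TRUE, audit = TRUE, seed = NULL,
                      max_tries = 1000L) {
  stopifnot(is(genome, "DNAStringSet"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  lens <- setNames(width(genome), names(genome))
  placed_chrom <- character(0); placed_start <- integer(0)
  placed_end <- integer(0)
  motifs <- vector("list", n)
  for (i in seq_len(n)) {
    motifs[[i]] <- .random_motif(tract_len, loop_len)
    w <- nchar(motifs[[i]]$seq)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- if (length(lens) == 1L) names(lens) else
        sample(names(lens), 1L, prob = lens)
      # 0-based start; keep one flank base on each side inside bounds
      pos0 <- floor(runif(1) * (lens[[chrom]] - w - 2)) + 1
      same <- placed_chrom == chrom
      if (!any(same & placed_start - min_gap < pos0 + w &
                 placed_end + min_gap > pos0)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("cannot place ", n, " motifs with min_gap ", min_gap,
           " (failed at motif ", i, ")")
    placed_chrom <- c(placed_chrom, chrom)
    placed_start <- c(placed_start, as.integer(pos0))
    placed_end <- c(placed_end, as.integer(pos0 + w))
  }
  # apply all replacements in one pass per chromosome; a planted site
  # [pos0, pos0+w) in 0-based coordinates is written at 1-based
  # pos0+1..pos0+w with one T flank on each side
  for (chrom in unique(placed_chrom)) {
    i <- which(placed_chrom == chrom)
    genome[[chrom]] <- Biostrings::replaceAt(
      genome[[chrom]],
      IRanges(placed_start[i], placed_end[i] + 1L),
      vapply(motifs[i], function(m) paste0("T", m$seq, "T"), ""))
  }
  planted <- if (n > 0) {
    gr <- bed_ranges(placed_chrom, placed_start, placed_end)
    mcols(gr)$name <- vapply(motifs, function(m)
      paste0("t", paste(m$tracts, collapse = ","), ";l",
             paste(m$loops, collapse = ",")), "")
    mcols(gr)$score <- vapply(motifs, function(m)
      score_pqs(m$tracts, m$loops), integer(1))
    gr
  } else GRanges()
  if (audit && n > 0) {
    for (i in seq_len(n)) {
      chrom <- placed_chrom[i]
      lo <- max(1L, placed_start[i] + 1L - params$max_width)
      hi <- min(lens[[chrom]], placed_end[i] + params$max_width)
      local <- as.character(subseq(genome[[chrom]], lo, hi))
      hits <- scan_pqs(local, params)
      site_s <- placed_start[i] - (lo - 1L)   # 0-based within local
      site_e <- placed_end[i] - (lo - 1L)
      if (!any(hits$start < site_e & hits$end > site_s))
        stop("audit failed: planted motif ", i, " not recovered by scanner")
    }
  }
  truth <- planted
  if (length(planted)) mcols(truth)$origin <- "planted"
  if (spontaneous) {
    hits <- scan_genome(genome, params)
    if (length(hits)) {
      # planted and spontaneous hits may occupy disjoint chromosomes
      extra <- hits[!suppressWarnings(
        overlapsAny(hits, planted, ignore.strand = TRUE))]
      if (length(extra)) {
        mcols(extra)$origin <- "spontaneous"
        # the two sets may live on disjoint chromosomes; harmless
        truth <- suppressWarnings(c(truth, extra))
      }
    }
  }
  truth <- truth[order(as.character(seqnames(truth)), start(truth))]
  list(genome = genome, planted = planted, truth = truth)
}

.sample_chrom <- function(lens, k) {
  if (length(lens) == 1L) rep(names(lens), k)
  else sample(names(lens), k, replace = TRUE, prob = lens)
}

#' Simulate breakpoints with tunable G4-proximity bias
#'
#' Each of `n` variant events is, with probability `pi`, anchored to a
#' uniformly chosen G4 and positioned uniformly within `d_max` bp of
#' that G4's midpoint (box kernel, clipped to the chromosome);
#' otherwise it is placed uniformly on the genome. `pi = 0` is the
#' null world of the calibration study; large `pi` with small `d_max`
#' is the enriched alternative. Event classes are drawn from
#' `class_mix` and the events are emitted simultaneously as VCF
#' (SNV/insertion/deletion), BEDPE (inversion/translocation/
#' tandem-duplication) and SEG (copy-number gain/loss), so every
#' breakpoint parser is exercised; the returned truth ledger records
#' exactly the breakpoints those parsers recover.
#'
#' Simulated VCF deletions are short (2--20 bp) so both deletion ends
#' fall near the same anchor; SV partner ends are 1--20 kb away
#' (translocation partners anywhere on the genome) and copy-number
#' segments span 5--50 kb. An event whose position must be clipped for
#' the record to fit on the chromosome is demoted to background if the
#' clip moved it outside the `d_max` band.
#'
#' @param genome A [Biostrings::DNAStringSet] (REF alleles for the VCF
#'   are read from it).
#' @param g4s `GRanges` of G4 truth intervals (required non-empty when
#'   `pi > 0`).
#' @param n Number of events (`>= 1`).
#' @param pi Probability an event is G4-anchored, in `[0, 1]`.
#' @param d_max Anchoring half-width in bp (default 50).
#' @param class_mix Named probability vector over `VARIANT_CLASSES`.
#' @param sample_id Sample name written into the files.
#' @param dir Output directory (created if needed); default a fresh
#'   temporary directory.
#' @param seed Optional integer seed.
#' @return A `synthetic_truth` list: `breakpoints` (data.frame
#'   matching the parser output columns plus `event`, `anchored`,
#'   `anchor`), `events` (per-event class/anchoring table), `files`
#'   (paths of the emitted `vcf`/`bedpe`/`seg`, `NA` when a source has
#'   no events), plus the simulation parameters.
#' @export
simulate_breakpoints <- function(genome, g4s, n, pi = 0, d_max = 50L,
                                 class_mix = .DEFAULT_CLASS_MIX,
                                 sample_id = "SIM", dir = tempfile("simbp"),
                                 seed = NULL) {
  stopifnot(is(genome, "DNAStringSet"), n >= 1, pi >= 0, pi <= 1)
  if (pi > 0 && length(g4s) == 0L)
    stop("pi > 0 requires a non-empty G4 truth set")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% VARIANT_CLASSES))
    stop("class_mix must be named with variant classes")
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lens <- setNames(width(genome), names(genome))

  cls <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
  anchored <- runif(n) < pi
  anchor <- rep(NA_integer_, n)
  chrom <- character(n); pos <- numeric(n)
  bg <- function() {
    ch <- .sample_chrom(lens, 1L)
    list(chrom = ch, pos = floor(runif(1) * lens[[ch]]))
  }
  if (any(anchored)) {
    mid0 <- floor((start(g4s) - 1 + end(g4s)) / 2)
    g_chrom <- as.character(seqnames(g4s))
  }
  for (i in seq_len(n)) {
    if (anchored[i]) {
      a <- sample.int(length(g4s), 1L)
      anchor[i] <- a
      chrom[i] <- g_chrom[a]
      pos[i] <- mid0[a] + sample.int(2L * d_max + 1L, 1L) - d_max - 1L
      pos[i] <- min(max(pos[i], 0), lens[[chrom[i]]] - 1)
    } else {
      b <- bg(); chrom[i] <- b$chrom; pos[i] <- b$pos
    }
  }

  base_at <- function(ch, p0) as.character(subseq(genome[[ch]], p0 + 1, p0 + 1))
  seq_at <- function(ch, p0, len)
    as.character(subseq(genome[[ch]], p0 + 1, p0 + len))
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

  clip_into <- function(i, lo, hi) {
    # keep event i's position inside [lo, hi]; demote anchoring if the
    # clip leaves the d_max band
    p <- min(max(pos[i], lo), hi)
    if (anchored[i] && abs(p - (mid0[anchor[i]])) > d_max) {
      anchored[i] <<- FALSE
      anchor[i] <<- NA_integer_
    }
    pos[i] <<- p
    p
  }

  bp_rows <- list()
  vcf_rows <- list(); bedpe_rows <- list(); seg_rows <- list()
  add_bp <- function(ev, ch, p0, cl, role, anch, anc)
    bp_rows[[length(bp_rows) + 1L]] <<- data.frame(
      event = ev, chrom = ch, pos = as.integer(p0), variant_class = cl,
      sample = sample_id, end_role = role, anchored = anch,
      anchor = anc, stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    ch <- chrom[i]; len <- lens[[ch]]
    if (cls[i] == "SNV") {
      p <- clip_into(i, 0, len - 1)
      ref <- base_at(ch, p)
      vcf_rows[[length(vcf_rows) + 1L]] <-
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", ch, p + 1, ref,
                other_base(ref))
      add_bp(i, ch, p, "SNV", "single", anchored[i], anchor[i])
    } else if (cls[i] == "insertion") {
      p <- clip_into(i, 1, len - 1)
      ref <- base_at(ch, p - 1)
      ins <- paste(sample(c("A", "C", "G", "T"),
                          sample.int(5L, 1L), replace = TRUE),
                   collapse = "")
      vcf_rows[[length(vcf_rows) + 1L]] <-
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", ch, p, ref,
                paste0(ref, ins))
      add_bp(i, ch, p, "insertion", "single", anchored[i], anchor[i])
    } else if (cls[i] == "deletion") {
      dlen <- sample(2:20, 1L)
      p <- clip_into(i, 1, len - dlen)
      ref <- paste0(base_at(ch, p - 1), seq_at(ch, p, dlen))
      vcf_rows[[length(vcf_rows) + 1L]] <-
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", ch, p, ref,
                base_at(ch, p - 1))
      add_bp(i, ch, p, "deletion", "start", anchored[i], anchor[i])
      add_bp(i, ch, p + dlen, "deletion", "end", FALSE, NA_integer_)
    } else if (cls[i] %in% .SV_CLASSES) {
      if (cls[i] == "translocation") {
        b <- bg(); ch2 <- b$chrom; p2 <- b$pos
        p <- clip_into(i, 0, len - 1)
      } else {
        size <- sample(1000:20000, 1L)
        size <- min(size, len - 2)
        p <- clip_into(i, 0, len - 1 - size)
        ch2 <- ch; p2 <- p + size
      }
      lab <- c(inversion = "INV", translocation = "TRA",
               tandem_duplication = "DUP")[[cls[i]]]
      bedpe_rows[[length(bedpe_rows) + 1L]] <-
        sprintf("%s\t%d\t%d\t%s\t%d\t%d\tsv%d\t.\t+\t-\t%s",
                ch, p, p + 1, ch2, p2, p2 + 1, i, lab)
      add_bp(i, ch, p, cls[i], "mate_A", anchored[i], anchor[i])
      add_bp(i, ch2, p2, cls[i], "mate_B", FALSE, NA_integer_)
    } else {                              # CN_gain / CN_loss
      slen <- sample(5000:50000, 1L)
      slen <- min(slen, len - 2)
      p <- clip_into(i, 1, len - 1 - slen)
      seg_rows[[length(seg_rows) + 1L]] <-
        sprintf("%s\t%d\t%d\t%s", ch, p, p + slen,
                if (cls[i] == "CN_gain") "gain" else "loss")
      add_bp(i, ch, p, cls[i], "start", anchored[i], anchor[i])
      add_bp(i, ch, p + slen, cls[i], "end", FALSE, NA_integer_)
    }
  }

  files <- list(vcf = NA_character_, bedpe = NA_character_,
                seg = NA_character_)
  if (length(vcf_rows)) {
    files$vcf <- file.path(dir, paste0(sample_id, ".vcf"))
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    writeLines(c(header, unlist(vcf_rows)), files$vcf)
  }
  if (length(bedpe_rows)) {
    files$bedpe <- file.path(dir, paste0(sample_id, ".bedpe"))
    writeLines(unlist(bedpe_rows), files$bedpe)
  }
  if (length(seg_rows)) {
    files$seg <- file.path(dir, paste0(sample_id, ".seg"))
    writeLines(unlist(seg_rows), files$seg)
  }

  breakpoints <- do.call(rbind, bp_rows)
  structure(list(
    breakpoints = breakpoints,
    events = data.frame(event = seq_len(n), variant_class = cls,
                        anchored = anchored, anchor = anchor,
                        chrom = chrom, stringsAsFactors = FALSE),
    files = files, pi = pi, d_max = as.integer(d_max),
    class_mix = class_mix, sample_id = sample_id, seed = seed),
    class = "synthetic_truth")
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper chaining [generate_genome()], [plant_pqs()] and
#' [simulate_breakpoints()]: one G-suppressed genome with planted G4
#' motifs, a G4 truth set, and variant files whose breakpoints carry a
#' `pi`/`d_max` G4-proximity bias.
#'
#' @param chrom_lengths Named chromosome lengths (default one 2 Mb
#'   chromosome).
#' @param n_g4 Number of planted G4 motifs.
#' @param n_events Number of variant events.
#' @param pi,d_max Enrichment parameters (see
#'   [simulate_breakpoints()]).
#' @param g_fraction Background G fraction (default 0.10).
#' @param seed Integer seed driving all three stages.
#' @param dir Output directory for the variant files.
#' @param scan [scan_params()] for planting audit/spontaneous scan.
#' @param ... Passed to [simulate_breakpoints()].
#' @return List with `genome`, `index`, `planted`, `g4s` (truth set),
#'   and `sim` (the `synthetic_truth`).
#' @export
simulate_dataset <- function(chrom_lengths = c(chr1 = 2e6), n_g4 = 50,
                             n_events = 50, pi = 0, d_max = 50,
                             g_fraction = 0.10, seed = NULL,
                             dir = tempfile("simds"),
                             scan = scan_params(), ...) {
  if (!is.null(seed)) set.seed(seed)
  gen <- generate_genome(chrom_lengths, g_fraction)
  pl <- plant_pqs(gen$genome, n_g4, params = scan)
  sim <- simulate_breakpoints(pl$genome, pl$truth, n = n_events, pi = pi,
                              d_max = d_max, dir = dir, ...)
  list(genome = pl$genome, index = gen$index, planted = pl$planted,
       g4s = pl$truth, sim = sim)
}
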