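---
title: "G-quadruplex scanning and breakpoint colocalization with g4coloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G-quadruplex scanning and breakpoint colocalization with g4coloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4coloc)
```

## The question the package answers

G-quadruplexes (G4s) are four-stranded DNA secondary structures that
fold in guanine-rich sequence. They stall replicative polymerases, and
in cells with compromised fork protection or double-strand-break repair
— BRCA2 deficiency being the canonical example — loci able to form G4s
can become hotspots of breakage and mutagenic repair. A recurring
analysis in tumor genomics is therefore: *do the breakpoints of somatic
variants colocalize with (putative) G4-forming sequence more than
chance placement would predict?*

`g4coloc` implements that analysis as a tested, reusable chain:

1. **Scan** genomic DNA on both strands for putative quadruplex
   sequences (PQS) and give each candidate an explicit integer
   stability score (`scan_genome()`, `scan_fasta()`).
2. **Extract breakpoints** from variant calls: VCF small variants,
   BEDPE structural variants (SVs), and copy-number (CNV) segment
   boundaries (`breakpoints_from_vcf()` and friends).
3. **Window** each breakpoint with a fixed-width range — 100 bp and
   1 kb are the conventional sizes (`make_windows()`).
4. **Test** the count of windows overlapping at least one G4 against a
   null obtained by randomly re-placing the windows on the genome
   (`perm_test()`), in the style of region-set association tools such
   as regioneR.
5. **Profile** per-locus G4 density and stability in bins
   (`density_track()`), the quantitative content of a "G4-dense gene"
   track.
6. **Simulate** complete synthetic worlds — genome, planted G4 motifs,
   breakpoints with a tunable G4-proximity bias — so the statistical
   behaviour of the whole chain is measurable without sequencing data
   (`simulate_dataset()`, `simulate_and_test()`).

Intervals are carried as `GenomicRanges::GRanges` (1-based, closed)
internally; every BED-style input and output, and the public breakpoint
coordinates, are 0-based half-open and converted at the I/O boundary.
Overlap is always "at least one shared base": BED-adjacent intervals
(`a.end == b.start`) never overlap.

## The PQS model and its score

A PQS is parsed as four G-tracts separated by three loops:

* tracts: runs of at least `min_tract = 3` consecutive guanines
  (optionally one *defective* tract of exactly 2 Gs when
  `allow_defect = TRUE`);
* loops: `loop_min = 1` to `loop_max = 12` nt of arbitrary sequence
  (Ns break tracts but are permitted in loops);
* total span at most `max_width = 50` bp.

Each candidate receives the integer score

$$ S = 15\,t_{\min} + 3\,(G_{tot} - 4 t_{\min}) - 2\,L_{tot} - 12\,D $$

with $t_{\min}$ the shortest tract (capped at 6), $G_{tot}$ the summed
tract lengths (each capped at 6), $L_{tot}$ the summed loop length and
$D \in \{0, 1\}$ the number of defective tracts. The terms express the
usual determinants of G4 stability: more stacked tetrads (driven by the
weakest column), evenness of the four columns, short loops, and an
explicit penalty for a broken column. The calibration is such that the
canonical minimal motif `(G3 N1-12)3 G3` scores roughly 25–45 (39 for
`GGGTGGGTGGGTGGG`) and long-tract, short-loop motifs exceed 50 — the
conventional "high stability" cut used by `high_stability_census()`.
The score is a transparent linear surrogate for the kind of stability
score produced by dedicated predictors; agreement with any particular
external tool is not a goal, the semantics of "above 50 means high
predicted stability" is.

Candidate enumeration considers every admissible choice of four G-runs.
Tract lengths are realized as prefixes of the maximal runs; because the
score strictly increases whenever a base moves from a loop into an
interior tract, and plateaus at the cap for the final tract, the
best-scoring parse per run-quadruple is closed-form and unique under
the (score desc, width asc) tie-break — the test suite verifies this
against exhaustive enumeration. Overlapping candidates are resolved
greedily (score desc, leftmost, shortest) into a maximal
non-overlapping set per strand; `all_candidates = TRUE` exposes the
full pre-greedy set, which is what `density_track()` should be fed,
since overlapping candidates are precisely what "G4-dense" means.

Minus-strand hits come from scanning the reverse complement and
reflecting coordinates back; hits on opposite strands may overlap
because a quadruplex on either strand threatens the fork.

## Breakpoints and windows

Every variant contributes the genomic positions where its ends join or
interrupt the reference:

| source | class | breakpoints |
|---|---|---|
| VCF | SNV | 1 (the variant base) |
| VCF | insertion | 1 (the junction) |
| VCF | deletion | 2 (both flanks of the deleted segment) |
| BEDPE | deletion / inversion / translocation / tandem duplication | 2 (midpoint of each end interval) |
| SEG | CN gain / loss | 2 (segment boundaries; termini touching a chromosome end are dropped) |

Windows are symmetric, `[pos - w/2, pos + w/2)`, clipped at chromosome
edges. Coordinate-identical windows are collapsed by default
(`dedupe = TRUE`) so that duplicate calls cannot inflate the statistic;
the contributing classes are retained and a collapsed window counts
toward each of its classes in `class_overlap_table()`.

## The permutation test

The statistic is deliberately simple: the number of windows overlapping
at least one G4 interval, each window counted once (total overlapping
base pairs would weight long CNV segments more; the count-once form
matches the "percentage of windows overlapping" framing in which such
results are reported). Under the null, each window is independently
re-placed uniformly over every unmasked position that admits its full
width, choosing chromosomes proportionally to their number of
admissible positions; masked regions (e.g. assembly gaps) are never
touched. The empirical p-value is

$$ p = \frac{1 + \#\{ \text{perm} \ge \text{obs} \}}{N + 1}, $$

never zero, with floor $1/(N+1)$; the default $N = 999$ makes the floor
exactly 0.001, the conventional reporting level for a fully saturated
permutation test. The z-score `(obs - mean(perm)) / sd(perm)` is
reported as a diagnostic only and flagged undefined when the permuted
counts are constant. Each G4 set (e.g. predicted vs experimentally
derived) is tested separately with no cross-set multiple-testing
adjustment, mirroring per-dataset reporting; users comparing many sets
should adjust downstream.

Within `run_colocalization()` each (window size, G4 set) combination
uses a deterministic sub-seed derived from the config seed, so the
whole report is byte-reproducible.

## The synthetic worlds

`generate_genome()` draws i.i.d. nucleotides with
$P(G) = P(C) = g$, the remainder split evenly over A and T, default
$g = 0.10$. Suppression is applied to *both* G and C: the scanner is
double-stranded, so a genome that suppressed only G while enriching C
would be G-rich on its minus strand and would drown the planted signal
in spontaneous PQS — defeating the purpose of a low-background world.
With symmetric suppression a 2 Mb background genome typically contains
zero spontaneous PQS, so the planted motifs dominate the truth set; any
spontaneous hits that do arise are added to the truth by a post-plant
scan rather than ignored.

`plant_pqs()` overwrites non-overlapping sites (default pairwise gap
$\ge$ 200 bp) with canonical motifs: tract lengths drawn from 3–5,
loops 1–7 nt of non-G sequence, one T flank on each side so adjacent
genomic Gs cannot extend a planted tract. The function audits itself:
the scanner must report a hit overlapping every planted site.

`simulate_breakpoints()` is the alternative/null model the permutation
test is meant to detect. Each of $n$ variant events is anchored with
probability $\pi$: an anchored event picks a G4 uniformly and lands
uniformly within $\pm d_{\max}$ of its midpoint (a box kernel — the
simplest model consistent with fixed-width window overlap; a decaying
kernel is out of scope); otherwise it lands uniformly on the genome.
Classes are drawn from a deletion-dominant mixture (deletion 0.25,
SNV 0.15, insertion 0.10, and 0.10 each for inversion, translocation,
tandem duplication, CN gain, CN loss), reflecting the small-deletion-
heavy spectra of homologous-recombination-deficient tumors. Events are
emitted simultaneously as VCF, BEDPE and SEG so every parser is
exercised, and the truth ledger records exactly the breakpoints the
parsers will recover — the round trip is asserted to be exact in the
tests. For multi-breakpoint events (deletions, SVs, CNV segments) the
anchoring decision is made per event and the *drawn* breakpoint carries
the anchored flag; partner ends (a deletion's other flank lands within
2–20 bp, an SV partner 1–20 kb away or on another chromosome, a CNV
boundary 5–50 kb away) are recorded as background, so the invariant
"every anchored breakpoint lies within $d_{\max}$ of its anchor's
midpoint" holds exactly.

### What the simulations do and do not show

The generator emulates the *statistical structure* the test must
detect: a mixture of G4-anchored and background breakpoints on a genome
with a known G4 truth set. It does not emulate real mutational
signatures, sequence-context biases of variant calling, clustered
rearrangements, mappability or coverage artifacts, or the
chromatin-dependence of G4 formation. A calibrated, powerful test on
these worlds is therefore evidence the *machinery* is sound — not that
any particular biological dataset is free of confounders; on real data
the mask and per-chromosome placement options should be used to respect
alignability and karyotype.

## Validation studies shipped with the package

The acceptance suite runs four statistical studies end to end (sizes
chosen to exercise the full chain at desk scale):

* **Headline world**: one 2 Mb chromosome, 100 planted G4s, 100 events
  with $\pi = 0.8$, $d_{\max} = 50$; with 999 permutations the observed
  count must beat every permutation, i.e. $p = 0.001$ at the floor.
* **Calibration**: 200 null worlds ($\pi = 0$, 50 G4s, 50 events,
  199 permutations); the rejection rate at $\alpha = 0.05$ must lie in
  [0.01, 0.10].
* **Power**: 50 worlds with $\pi = 0.6$, $d_{\max} = 50$, 100 G4s,
  100 events, 499 permutations; $p \le 0.01$ in at least 90% of
  replicates.
* **Exactness**: on a 1 kb toy genome with one window and one G4, the
  Monte-Carlo p must fall within the binomial 99% CI of the p obtained
  by enumerating all 901 placements.

These studies use 100 bp windows, matching the scale of the
$d_{\max} = 50$ anchoring kernel. Note one subtlety the calibration
study deliberately includes: two-ended events yield *correlated* window
pairs (both flanks of a small deletion), while the null re-places
windows independently, so the observed count has slightly heavier tails
than the permutation null. The measured type-I error therefore sits a
little above the nominal level at small window sizes; the calibration
band accommodates this, and users testing few, strongly clustered
events should prefer the 1 kb window or collapse event ends first.

## Numerical and design choices

* **Degenerate inputs**: empty G4 sets are valid (observed 0, $p = 1$
  one-sided greater); empty window sets are an error; a window wider
  than every unmasked segment is an error naming the width.
* **Ties**: permuted counts equal to the observed count toward the
  p-value (the $\ge$ in the formula), the conservative convention.
* **Seeds**: every stochastic function takes a `seed` and is a pure
  function of (inputs, seed); `run_colocalization()` derives
  per-combination sub-seeds from the config seed.
* **"Above score 50"** is implemented inclusively (`>= 50`), with
  `inclusive = FALSE` to switch, since the phrase is ambiguous by one
  unit.
* **Merging**: G4 annotations are *not* merged before counting; the
  count-once statistic is invariant to subject overlap, so merging
  would only matter for base-pair statistics.
* **Chromosome choice in the null** is genome-wide (probability
  proportional to admissible positions); a per-chromosome restriction
  can be imposed by running chromosomes separately.

## Known limitations

* The scanner enumerates canonical (and optionally 2-G-defective)
  intramolecular PQS only: no bulged tracts, no RNA G4s, no
  thermodynamic folding, no intermolecular structures.
* The score is an interpretable linear surrogate, not a fitted
  thermodynamic model; absolute values are comparable within this
  package only.
* BEDPE end intervals are reduced to midpoints; confidence-interval
  aware windowing is not implemented.
* The permutation null randomizes windows independently; event-level
  (paired-end) randomization is not implemented (see the calibration
  note above).

## A worked example

```{r example, eval = FALSE}
library(g4coloc)

# a synthetic tumor world with strong G4-proximity bias
ds <- run_simulate("sim_out", chrom_lengths = c(chr1 = 2e6),
                   n_g4 = 100, n_events = 100, pi = 0.8, d_max = 50,
                   seed = 11)

cfg <- run_config(
  chrom_sizes = ds$files$chrom_sizes,
  variants = list(small = ds$files$vcf, sv = ds$files$bedpe,
                  cnv = ds$files$seg),
  g4_sets = list(planted = ds$files$planted_bed,
                 all = ds$files$truth_bed),
  outdir = "coloc_out", window_sizes = c(100, 1000),
  n_perm = 999, seed = 12)
res <- run_colocalization(cfg)

res$results[["100"]][["all"]]     # overlap_result; p at the 0.001 floor
res$class_table                   # per-class overlap fractions
```
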