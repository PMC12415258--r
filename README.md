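# g4coloc

G-quadruplex scanning and breakpoint colocalization testing for tumor
genomes.

## The problem

G-quadruplexes (G4s) are four-stranded secondary structures that fold
in guanine-rich DNA and stall replication forks. In cells with
defective fork protection or break repair (e.g. BRCA2 deficiency),
G4-capable loci can become hotspots of breakage and mutagenic repair.
The recurring analytical question — *do the breakpoints of somatic
variants overlap putative G4-forming sequence more often than random
placement would predict?* — needs four ingredients: a G4 scanner with
a stability score, breakpoint extraction from heterogeneous variant
files, fixed-width breakpoint windows, and a permutation test against
a random-placement null. `g4coloc` provides all four, plus a synthetic
data generator so the statistical behaviour of the chain (type-I
error, power) is measurable without any sequencing data.

It is aimed at cancer-genomics and genome-stability researchers who
have variant calls (VCF small variants, BEDPE SVs, SEG copy-number
segments) and want a reproducible, seedable enrichment analysis in R.

## The method in brief

**Scanner.** A putative quadruplex sequence (PQS) is four G-tracts
(≥ 3 Gs; optionally one defective 2-G tract) separated by three loops
of 1–12 nt, spanning ≤ 50 bp, scanned on both strands. Each candidate
is scored

    S = 15·t_min + 3·(G_total − 4·t_min) − 2·L_total − 12·D

(t_min = shortest tract, capped at 6; G_total = summed tract lengths,
each capped at 6; L_total = summed loop lengths; D = defects). The
canonical motif `GGGTGGGTGGGTGGG` scores 39; scores ≥ 50 are the
conventional "high stability" class. Overlapping candidates are
resolved greedily (score desc, leftmost, shortest); the full candidate
set is available for density profiling.

**Windows.** Every variant contributes its breakpoint end(s): one for
SNVs and insertions, two for deletions (both flanks), two per SV
(BEDPE end-interval midpoints), two per copy-number segment (its
boundaries). Windows are `[pos − w/2, pos + w/2)`, typically w = 100
and 1000, clipped at chromosome edges, deduplicated by coordinate.

**Test.** The statistic is the number of windows overlapping ≥ 1 G4
interval (count-once). The null re-places every window independently
and uniformly over all unmasked positions admitting its width.
Empirical p = (1 + #{perm ≥ obs}) / (N + 1); with the default N = 999
the attainable floor is 0.001.

## Worked example

Simulate a tumor-like world with strong G4-proximity bias and analyse
it end to end:

```r
library(g4coloc)

ds <- run_simulate("sim_out", chrom_lengths = c(chr1 = 2e6),
                   n_g4 = 100, n_events = 100, pi = 0.8, d_max = 50,
                   seed = 11)

cfg <- run_config(
  chrom_sizes = ds$files$chrom_sizes,
  variants = list(small = ds$files$vcf, sv = ds$files$bedpe,
                  cnv = ds$files$seg),
  g4_sets  = list(g4 = ds$files$truth_bed),
  outdir = "coloc_out", window_sizes = c(100, 1000),
  n_perm = 999, seed = 12)
res <- run_colocalization(cfg)
res$results[["100"]][["g4"]]
#> Permutation overlap test (greater)
#>   windows: 178, overlapping G4s: 95 (53.4%)
#>   permutations: 999, perm mean: 1.52
#>   empirical p = 0.001, z = 76.20
```

178 deduplicated 100-bp windows arise from the 100 simulated events
(two-ended classes contribute two each); 95 of them (53%) overlap a G4
interval, while random placement yields on average ~1.5 overlapping
windows, so the observed count beats all 999 permutations and the
p-value sits at its floor of 0.001. `res$class_table` breaks the
overlap fraction down by variant class and window size, and
`coloc_out/` contains the JSON report, the class table TSV and a run
manifest with the seed and input checksums.

Single steps are available as plain functions (`scan_fasta()`,
`breakpoints_from_vcf()`, `make_windows()`, `perm_test()`,
`density_track()`), and `inst/cli/g4coloc.R` wraps them as shell
subcommands (`scan`, `windows`, `run`, `simulate`, `profile`).

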