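# het5c

Analysis toolkit for **chromosome conformation capture carbon copy (5C)**
experiments targeted at pericentromeric heterochromatin, where
heterochromatic genes are transcribed despite a repressive chromatin
environment. The package takes raw 5C read pairs all the way to
topologically associating domain (TAD) calls, border feature statistics
and expression integration, and ships a synthetic-data generator with
planted domain structure so every stage can be validated against known
ground truth.

## What it does

1. **Quantification** — reads paired FASTQ whose reads carry the
   universal-tail + primer + EcoRI-junction structure of 5C libraries;
   trims the common ends (keeping bases 21–79), applies the Phred filter
   (≥ 80% of bases at Q ≥ 25 in both mates), assigns each pair to exactly
   one forward × reverse primer combination (multi-mapping pairs are
   discarded), and normalizes counts to the total mapped pairs. Scores
   are binned (median, 10 kb default) into symmetric contact matrices
   with a distance-decay observed/expected transform: entries with
   `log2(obs/exp) > 0` are interactions enriched above the distance
   baseline.
2. **TAD calling** — the Directionality Index per 10 kb bin over a
   100 kb window,

   `DI = sign(B − A) · ((A − E)²/E + (B − E)²/E)`, `E = (A + B)/2`,

   where `A`/`B` sum the upstream/downstream contacts; a three-state
   discrete-emission hidden Markov model (Baum–Welch + Viterbi) segments
   the profile into upstream-bias / no-bias / downstream-bias states; a
   TAD runs from the first downstream-biased bin to the end of the next
   upstream-biased run. Boundaries from replicates are single-linkage
   clustered at 50 kb; clusters supported by ≥ 2 replicates become
   consensus boundaries.
3. **Border statistics** — interval permutation tests (length- and
   chromosome-preserving randomization within a declared universe; add-one
   p-value, Z-score), scaled meta-region profiles (borders → 30 kb / 10 kb
   bins, intra-TAD → 150 kb / 30 kb bins) and anchor × feature
   combination counts.
4. **Condition comparison & expression** — intra- vs inter-TAD
   classification of interactions, replicate pooling by mean, notched
   boxplot summaries (notch = median ± 1.58·IQR/√n) with a
   notch-non-overlap flag; FPKM categorization (no < 1, low 1–10,
   moderate 10–50, high > 50), gene→TAD assignment and per-TAD
   expression-category concordance; exact set algebra over DE gene lists.
5. **Synthetic data** — alternating T7/T3 primer sets, Poisson contact
   counts over a power-law distance decay with planted TADs, paired
   FASTQ emission (with decoy and low-quality knobs), feature tracks with
   tunable border fold-enrichment, and log-normal FPKM tables tied to TAD
   activity.

## Worked example

```r
library(het5c)

sim <- simulate_fivec_experiment(seed = 42)   # 1 Mb, 6 planted TADs,
                                              # 3 replicates, 200k pairs
res <- consensus_from_tables(sim$tables, sim$primers,
                             chrom_length = 1e6, seed = 42)
res$consensus$tads
#>       chrom  start     end replicate
#> 1 chr2L_het      0  170000        NA
#> 2 chr2L_het 170000  330000        NA
#> 3 chr2L_het 330000  560000        NA
#> 4 chr2L_het 560000  670000        NA
#> 5 chr2L_het 670000  840000        NA
#> 6 chr2L_het 840000 1000000        NA

boundary_recovery(sim$truth, res$consensus)
#> recovered 100% of planted boundaries, 0 spurious
attr(res$consensus, "report")$support_fraction
#> [1] 1

# border enrichment of a synthetic MAR-like track planted at fold 10
truth <- synthetic_truth(sim$model, feature_enrichment = c(MAR = 10))
trk <- generate_feature_tracks(truth, sim$genome, seed = 42)
b <- tad_boundaries(res$consensus)
borders <- data.frame(chrom = b$chrom,
                      start = pmax(0, b$position - 15000),
                      end = pmin(1e6, b$position + 15000))
permutation_overlap_test(trk$MAR, borders, n_permutations = 1000,
                         seed = 42)
#> <perm_test>  obs=101 null=30.81+/-4.95 Z=14.18 p=0.000999 (greater, 1000 perms)
```

All six planted domains are recovered with their boundaries placed
within one bin of the truth, every replicate boundary falls in a
supported 50 kb cluster, and the planted border enrichment is detected
at the smallest p-value 1000 permutations can report.

## Layout

- `R/` — implementation: synthetic data (`genome.R`, `primers.R`,
  `simulate.R`, `fastq.R`, `tracks.R`), quantification (`quant.R`,
  `matrix.R`, `interaction-table.R`), TAD calling (`di.R`, `hmm.R`,
  `tads.R`), border statistics (`overlap.R`), condition comparison and
  expression (`compare.R`, `expression.R`), I/O (`io.R`) and pipeline
  wrappers (`pipeline.R`).
- `vignettes/het5c-methods.Rmd` — the methods vignette: model,
  parameters, numerical choices, and what the synthetic validation does
  and does not establish.
- `tests/testthat/` — unit, property and acceptance tests with
  independent oracles in `helper-oracles.R`.
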