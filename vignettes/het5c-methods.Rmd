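---
title: "het5c: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{het5c: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pericentromeric heterochromatin houses genes that are actively
transcribed despite residing in repressive chromatin. Chromosome
conformation capture carbon copy (5C) interrogates the long-range DNA
contacts of such targeted regions: forward primers (T7 universal tail)
and reverse primers (T3 tail) anneal at adjacent restriction sites, and
only forward x reverse ligation junctions are amplified and sequenced.
The analytical questions this package answers are: where are the
topologically associating domains (TADs) in the targeted regions, which
genomic features mark their borders, how do inter- and intra-TAD
contacts shift when heterochromatin proteins are depleted, and how does
domain structure relate to the expression level of the genes inside.

Because real conclusions at this scale require deposited sequencing
data, the package is built around a synthetic-data generator with
*planted* structure: every pipeline stage is validated against a ground
truth it is supposed to recover.

## Quantification model

A 5C read pair carries `universal tail + own primer + EcoRI junction
(GAATTC) + mate primer`. The pipeline:

1. **Trim** to bases 21-79 (1-based): all reads share common ends (the
   universal tails 5', primer runoff 3'), so a fixed window is correct.
   The 59-base window cannot retain two full 30-mer primers, which
   drives the assignment design below. Trimming twice is an error (an
   idempotence guard, since the cut is positional, not adaptive).
2. **Phred filter**: keep a pair iff >= 80% of bases have Q >= 25 in
   *both* mates. Both bounds are inclusive ("at least"), the natural
   reading of a minimum-score/minimum-fraction filter; the boundary case
   (exactly 80% at exactly Q25) is covered by a unit test.
3. **Assignment**: each mate identifies its own primer by exact full
   substring match (0 mismatches — synthetic reads are error-free and
   the real-data path accepts pre-mapped pair lists instead) and, when
   the junction motif follows, the mate primer by its prefix (>= 15
   junction-spanning bases). A pair is credited when exactly one
   forward x reverse combination survives; two or more combinations is
   multi-mapping and discarded; zero is unmatched. One confident mate
   suffices, mirroring how a single mate aligning to a junction
   pseudo-reference identifies the pair. The bookkeeping identity
   `assigned + ambiguous + unmatched + quality_dropped + short_dropped =
   input pairs` is asserted in tests.
4. **Normalization**: `norm_score = raw / total_mapped x factor`. The
   factor is a per-dataset calibration constant supplied by the analyst
   (published 5C work used 11.62 and 8.65 for control and experiment
   libraries); its derivation is not re-implemented because it is not
   stated anywhere reproducible. Totals count assigned *pairs*, not
   mapped mates — the spec left this open; pairs are the unit the rest
   of the pipeline consumes.
5. **Binning**: cell (i, j) is the median of primer-pair scores whose
   anchor midpoints fall in the two bin windows; 10 kb bins, step =
   size by default (a 1 kb step gives the sliding-window heatmap
   variant). Empty cells stay absent (`NA`) — a missing observation is
   not a zero. The optional smoother replaces each observed cell by the
   median of observed cells within +/-10 kb on both axes; the original
   web tool's "smoothing by interactions, S = 10,000" is not publicly
   specified, so this +/-10 kb median smoother is an explicit,
   documented stand-in.
6. **Observed/expected**: expected score per distance stratum (width =
   one bin) is the *median* of observed scores at that separation; the
   output is `log2(obs/expected)` and an entry is a "valid" interaction
   iff it is strictly positive (strict, as printed in the source
   convention). The median is robust to the planted (or real) enriched
   cells inflating the baseline. Strata with non-positive expected
   values yield `NA` cells rather than infinities.

## TAD calling

**Directionality Index.** For each bin, `A` is the sum of interaction
scores to bins up to 100 kb upstream, `B` the downstream counterpart,
`E = (A + B)/2`, and

```
DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
```

This is a chi-squared-style statistic against the null of unbiased
contacts; it is strongly positive at domain starts (contacts point
downstream) and strongly negative at domain ends. `DI = 0` when
`A = B`, including the no-data case `A = B = 0`, which is flagged. The
printed source formula `(B - A/|B - A|)` is read as the sign term
`((B - A)/|B - A|)`: the literal reading collapses dimensionally and the
cited method defines a pure sign. Windows truncated at chromosome ends
use the available span. The window is specified in bp, so 5 kb-binned
chromosomes (as used for chromosome X designs) automatically get 20 bins
per side. The implementation is checked for *exact* equality against a
naive double-loop evaluation on random matrices, including antisymmetry
under matrix reflection.

**Segmentation.** DI values are discretized into K = 7 quantile levels
(profiles too degenerate for 3 distinct quantile edges fall back to
sign levels) and segmented with a 3-state hidden Markov model with
categorical emissions. Choices the source method leaves open, and what
this package does:

- *Emission family*: discrete categorical over quantile levels rather
  than Gaussian mixtures — EM over discretized levels is robust on the
  short profiles a targeted 5C design yields (on the order of 100 bins).
- *EM*: Baum-Welch with scaling, 5 seeded restarts (sticky 0.9-diagonal
  transition init; emissions initialized low/central/high so state
  identities start ordered), stop when the log-likelihood gain drops
  below 1e-6 or at 200 iterations (then the best-so-far fit is returned
  with a warning and `converged = FALSE`). Best restart by
  log-likelihood; ties break to the lowest restart index.
- *State labeling*: after Viterbi decoding, each state is labeled by the
  sign of the mean DI over the bins assigned to it, with a dead zone of
  0.1 x max|DI| around zero mapping to no-bias; unused states are
  no-bias. Labeling by emission-weighted DI rank was tried first and is
  fragile under label switching and state splitting (two states sharing
  one biased block); labeling by the realized path is robust, and two
  same-sign states simply share a label — their runs merge in the next
  step.

**Extraction.** Biased runs shorter than 2 bins are absorbed into
no-bias (suppressing one-bin flickers). A TAD starts at the first bin of
a downstream-bias run and ends at the last bin of the next upstream-bias
run; a downstream run never closed by an upstream run before the
chromosome end is an open domain — dropped and counted. Gaps between
consecutive TADs are the border intervals (borders are reported as
inter-TAD gaps; whether published border sizes refer to gaps or
boundary-bin runs is unstated, and gaps are the definition the rest of
the package consumes).

**Consensus.** All replicate boundary positions are single-linkage
clustered per chromosome with linkage distance 50 kb (equivalent to
cutting a single-linkage dendrogram at that height; the test suite
checks exact agreement with `hclust` + `cutree` on random
configurations). Clusters supported by >= 2 distinct replicates yield a
consensus boundary at the cluster median; the support rule is the
conservative majority reading of "pooled for a consensus definition"
(2 of 3 for triplicate designs). Consensus TADs are re-derived between
consecutive consensus boundaries wherever >= 2 replicates call a TAD
over the interval midpoint, and the fraction of replicate boundaries in
supported clusters is reported alongside.

## Border feature statistics

**Permutation test.** Each permutation redraws the query intervals
uniformly *within the declared universe*, preserving per-interval
lengths and chromosome assignment. For a targeted 5C design the universe
is the designed region set: randomizing pericentromeric queries
genome-wide would inflate Z trivially, so the universe is an explicit
config choice. The overlap unit is query intervals overlapped (>= 1 bp,
half-open), so merging feature intervals changes nothing. The p-value
uses the add-one estimator `p = (1 + #{perm >= obs})/(1 + n_perm)` and
is never 0; `Z = (obs - mean)/sd`, reported `NA` when the null has zero
spread. Benjamini-Hochberg adjustment across features is available but
opt-in (raw p is what border-enrichment analyses conventionally
report).

Two practical notes, verified by the acceptance suite:

- With few query intervals the overlap count is heavily tied and the
  add-one p-value is conservative — the measured type-I error falls
  *below* the binomial band around the nominal level. Calibration is
  therefore checked on a fixture large enough (150 query intervals) for
  the statistic to be approximately continuous.
- Testing a handful of wide border windows against a dense track
  saturates (the observed count equals its maximum under the null too).
  The power check of planted fold-10 border enrichment randomizes the
  *feature track* against fixed border windows — the same null, the
  direction with usable power, and the convention of the
  region-permutation tools this mirrors.

**Scaled profiles.** Borders are rescaled to a canonical 30 kb in three
10 kb bins, intra-TAD bodies to 150 kb in five 30 kb bins (the median
sizes of each region class); each real region is split into equal
fractions and the per-bin mean feature-interval count across regions is
reported. Profiles are invariant to region order.

**Anchor combinations.** Inter-chromosomal interaction anchors are
labeled with the exact subset of features they overlap; the per-subset
count table (the input of an UpSet-style plot) partitions the anchors.

## Condition comparison and expression

Interactions are classified by anchor-midpoint containment in the
consensus TADs: both anchors in one TAD = intra-TAD, two different TADs
on one chromosome = inter-TAD, anything touching a border gap or outside
= unassigned (tallied, excluded from summaries). Replicates pool by the
mean over replicates in which a pair is present. Summaries use
quartiles by linear interpolation between order statistics (R type 7 —
the plotting tool behind the published figures is unnamed, so the
convention is declared rather than guessed), notch bounds
`median +/- 1.58 IQR / sqrt(n)` (the standard 95% rule for notched
boxplots) and Tukey outlier thresholds. The "effect" flag is notch
non-overlap between two conditions; since that is a visual heuristic
rather than a formal test, a Wilcoxon rank-sum p-value is exposed
alongside rather than asserting any particular criterion.

FPKM categories: no < 1, low 1-10, moderate (10, 50], high > 50, mean
FPKM across replicates. The published category text is internally
inconsistent (Methods say "no expression = 0 FPKM", Results "< 1 FPKM";
the interval (50, 51) is unassigned); the Results thresholds are adopted
and the gap closed at > 50 = high so the four classes partition the
axis. Genes are assigned to the TAD of maximal overlap; genes not fully
contained in their TAD are border straddlers — excluded from
concordance but listed, since they are the documented exceptions to the
one-domain-one-expression-level pattern. Per-TAD concordance is the
modal-category fraction; genome-level concordance is its mean over TADs
with genes.

## The synthetic world

Defaults state the world once; tests never tune them:

- **Genome**: 1 chromosome x 1 Mb (a pericentromeric region is a few
  hundred kb to ~2 Mb), 100 primers at 10 kb spacing, alternating
  forward/reverse as in the alternating 5C design.
- **TADs**: six planted domains of 100-250 kb with 10-20 kb border gaps,
  alternating active/inactive — matching the reported Het TAD scale
  (90 kb-0.3 Mb domains, 10-40 kb borders).
- **Contacts**: expected pair count proportional to
  `distance^-1` (decay exponent 1, the canonical contact-decay slope),
  floored at one bin (10 kb) to avoid blowup at adjacent primers,
  times 5 inside a TAD vs 1 between (a strong but realistic insulation
  contrast); scaled to 200,000 pairs per replicate, 3 replicates,
  Poisson counts. The noise model is Poisson because the source gives
  none; a negative-binomial dispersion knob exists but defaults off.
  Only forward x reverse pairs carry signal, mirroring 5C chemistry.
- **Reads**: Phred+33, Q40 bases by default; decoys *replace* a stated
  fraction of signal pairs (so fraction 1.0 leaves nothing assignable),
  cycling unmatchable / chimeric-ambiguous / low-quality; a separate
  knob degrades a fraction of bases to Q2 in a fraction of signal reads
  to exercise the Phred filter.
- **Feature tracks**: 40 background intervals of 1 kb per Mb (a typical
  peak-track density), plus extra intervals within +/-15 kb of planted
  boundaries sized so border-window density is `fold` times background.
- **Expression**: genes tiled every 20 kb inside TADs; gene mean FPKM
  log-normal around 50 (active) or 0.3 (inactive) with sdlog 0.4
  (within-domain spread of "similar" expression levels); replicate
  noise sdlog 0.15, mean-preserving — consistent with the r > 0.96
  replicate correlations reported for the RNA-seq this emulates.

What a green synthetic run does **not** establish: behavior under real
mapping artifacts (repeats, multi-mapping at the sequence level),
restriction-fragment-accurate primer geometry, overdispersed or
batch-structured replicate noise, chromosome-scale heterogeneity
(e.g. designs where one arm yields too few contacts for the HMM — the
minimum-profile-length precondition encodes that failure mode but the
real threshold is data-dependent), or the correctness of any particular
published TAD map.

## Degenerate inputs and numerical corners

- Zero read depth: valid, all-zero tables flagged `zero_depth`.
- Empty matrices/profiles: empty DI profiles; segmentation requires at
  least `2 * window / bin_size` bins and errors otherwise.
- All-zero DI: everything no-bias, zero TADs.
- `perm_sd = 0`: Z reported as `NA`, p well-defined.
- Consensus tolerance below the bin size: warned (clusters will rarely
  merge).
- Quantile discretization collapsing (constant or two-valued DI): sign
  fallback.
- Identical seeds give byte-identical outputs for every generator;
  independent generator streams derive distinct 32-bit seeds from the
  master seed.

## Known limitations

- Exact-match assignment is correct for synthetic reads and for the
  pre-mapped-pairs entry point, but is not a read aligner; real FASTQ
  with sequencing errors should be mapped externally and supplied as
  pair lists.
- The expected-model and smoothing stand-ins are documented choices, not
  reconstructions of the original web tool's unpublished algorithms.
- Hi-C-style all-vs-all matrices, nested/hierarchical domains and
  inter-chromosomal "domains" are out of scope.
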