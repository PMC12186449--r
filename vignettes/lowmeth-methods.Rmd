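---
title: "Methods behind lowmeth: imputation, copy-number calling and feature selection for low-pass WGBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind lowmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lowmeth` processes low-pass whole-genome bisulfite sequencing (WGBS)
cohorts: it computes CpG beta values from read counts, imputes the missing
cells that low coverage inevitably produces, calls copy number from the
same coverage without any external reference, relates the results to
methylation-array data, and selects variance-ranked CpG feature sets. This
vignette explains each model, the parameters that matter, the numerical
choices, and what the bundled simulator can and cannot tell you about real
data.

## Coordinates, strand collapsing and beta values

Internally every locus is a 0-based forward-strand cytosine position;
1-based cytosine-report input is converted at the parsing boundary, which
keeps all interval arithmetic BED-compatible. A CpG is palindromic:
bisulfite reads report its two cytosines separately on the two strands, so
the reverse-strand record at position p+1 is summed into the forward record
at p. Arrays report one value per CpG, and downstream modules assume one
record per site.

The beta value is β = m/t with t the total read count. The default minimum
depth for calling a beta is 1 — any covered CpG yields a value — because
the pipeline's philosophy is to impute low-confidence cells rather than
discard them; the stricter 10× cut applies only to the selection of
imputation *training* examples, where the target must be trustworthy.

## Missing-value imputation

One gradient-boosted regression-tree model is fitted per sample
(squared-error objective; models are deliberately not shared across
samples, since per-sample coverage and bias differ). Each CpG is described
by five numbers derived from the four-ingredient feature design:

* `dist_up`, `beta_up` — distance (bp) to and beta of the nearest
  non-missing CpG upstream on the same chromosome;
* `dist_down`, `beta_down` — the same downstream;
* `beta_other_mean` — the mean beta of all *other* samples at the locus.

The neighbour features exploit the short-range spatial autocorrelation of
CpG methylation; the cross-sample mean exploits its strong between-sample
stability. The stated "distance to neighbouring CpG" idea is implemented
as two directional features rather than one nearest-neighbour distance —
the flanks are not interchangeable, and the tree model can always ignore
one of them. When a neighbour does not exist (chromosome ends, or a wholly
uncovered flank) the distance is set to a sentinel of 10^6 bp — far beyond
any informative range, so trees isolate it with a single split — and the
neighbour beta falls back to `beta_other_mean`. When no other sample
covers the locus the cross-sample mean falls back to the target sample's
chromosome-wide mean beta and the cell is flagged low-confidence.

Training samples up to 1,000,000 non-missing CpGs with depth ≥ 10 without
replacement, then splits 80/10/10 into train/validation/test. The split
exists because an error estimated on training data would be meaningless:
boosting early-stops on the validation partition (patience 20 rounds, up
to 500 rounds, maximum tree depth 6, learning rate 0.1 — conventional
boosted-tree defaults, all configurable) and the reported RMSE comes from
the untouched test partition. The quoted RMSE is therefore a held-out
error. All boosting runs single-threaded with a fixed seed, so results are
bit-reproducible. Predictions are clipped to [0, 1]; observed cells are
never overwritten; cells on chromosomes where the sample has no observed
CpG at all are left missing rather than guessed.

Note the held-out RMSE measures prediction of *observed* betas, which at
10× depth carry binomial sampling noise of roughly 0.06–0.14 sd; an RMSE
near 0.1 on such data is close to the irreducible floor, not model error.

## Reference-free copy-number calling

Low-pass coverage supports copy-number inference at coarse resolution; the
bin width of 50,000 bp is the tuned default, large enough that a 10×
genome gives thousands of fragments per bin (relative Poisson noise ~2%).
The steps:

1. **Binning** — fragments are assigned to bins by midpoint, so each
   fragment is counted exactly once regardless of bin straddling.
2. **Filtering** — a bin is dropped when > 50% of its length overlaps the
   blacklist (centromeres, telomeres, poor-mappability regions), or when
   its count falls below 1. The 50% rule is this package's definition;
   accumulated overlap across multiple blacklist intervals counts.
3. **Normalisation** — log2(count / median autosomal non-dropped count),
   optional loess GC correction when GC content is supplied, then
   re-centring of the autosomal median log2 to 0. The sample is its own
   reference — no panel of normals — which assumes most of the genome is
   copy-neutral; a genome that is mostly aneuploid would shift the
   baseline. Sex chromosomes are excluded from the median so XY samples do
   not bias it.
4. **Outlier screen** — bins deviating from a 51-bin rolling median by
   more than 100 rolling MADs of the residuals are dropped. Factor 100 is
   deliberately permissive: it removes only technical spikes, never
   genuine focal events (a copy-8 amplification sits ~2 log2 units up,
   far below 100 MADs of a typical noisy track, but such events span
   enough bins to shift the local median rather than appear as isolated
   residuals).
5. **Segmentation** — circular binary segmentation: within each
   chromosome, the arc maximising the two-sample t statistic between arc
   and complement is found exhaustively (O(n²) per scan, trivial at ≤ a
   few thousand bins per chromosome) and split when its p-value under the
   analytic t distribution (df = n − 2) falls below α = 1e-15. Analytic
   p-values, rather than a permutation null, make such an extreme
   threshold attainable and the procedure deterministic; the threshold
   itself is stringent on purpose — at 50 kb resolution only unambiguous
   transitions should create breakpoints. Zero-variance (noiseless)
   splits are treated as t = ∞, with mean differences below numerical
   rounding treated as zero so constant tracks never fragment. Ties in
   the t statistic resolve to the first (lowest-index) arc.
6. **Classification** — segment means map to absolute states: gain ≥ 0.3,
   amplification ≥ 0.7, loss ≤ −0.4, deletion ≤ −1.1. These cut-offs were
   calibrated against anchors visible in pure tumours: monosomy at log2 ≈
   −1.0 and single-copy gain at ≈ +0.585. Boundaries are inclusive toward
   the non-neutral call (a mean of exactly 0.3 is a gain); the alternative
   ±0.2 preset mirrors exome-pipeline conventions. Note the thresholds
   presume high tumour purity: admixture compresses log2 ratios toward 0.
7. **Arm calls and concordance** — an arm takes the non-neutral state
   covering the largest classified length, provided it exceeds 50% of that
   length, else neutral; arms without classified bins are `no-data`. A
   segment is concordant with a reference set when a single same-state
   segment overlaps > 50% of its length. The denominator is the *query*
   segment's length (one-directional); a `reciprocal` flag additionally
   requires the same fraction of the reference segment. One-directional is
   the default because sensitivity questions ("was this event also seen on
   the other platform?") are asymmetric.

## Cross-platform matching and feature selection

Array probes span ~50 bp around their target CpG, so a WGBS CpG and a
probe coordinate within 25 bp of each other are treated as the same locus.
Each probe takes its nearest CpG within tolerance; equidistant ties break
to the lower genomic coordinate, a determinism choice with no biological
content. One coordinate per probe is used (probes are points, not
intervals, in this matcher). Per-sample Pearson correlations use only
cells non-missing on both platforms, and samples with fewer than 3 usable
pairs or zero variance are flagged undefined instead of silently dropped.

Variable-CpG selection ranks complete loci by cross-sample sd (n − 1
denominator) and keeps the top 10,000 by default. Annotation uses the
standard island-relative distances — shore within 2 kb of an island, shelf
within the next 2 kb — because the category names imply them; shores and
shelves of islands closer than twice those distances merge into single
regions. Open-sea CpGs share the gap interval between consecutive shelf
boundaries, so "same annotation" is well defined everywhere. Each region
keeps its highest-sd CpG as representative (ties to the lower
coordinate). Island-relative intervals are the only grouping key; genic
annotations, when supplied, are carried as labels but do not merge
regions.

## The simulator: what it does and does not emulate

`simulate_methylomes()` draws regional methylation levels from a 50/50
mixture of Beta(0.5, 8) and Beta(8, 0.5) — strongly bimodal, > 60% of mass
within 0.1 of the extremes, matching the empirical shape of CpG
methylation — in blocks of 1 kb (roughly the scale at which neighbouring
CpGs share state at ~1 CpG / 100 bp density, and the mechanism that makes
the imputer's neighbour features informative). A configurable fraction of
blocks (default 5%) is group-differential, drawing one level per molecular
group, which plants the clustered differential CpGs that make top-variable
loci collapse into few unique regions. Locus- and cell-level Gaussian
jitter (sd 0.02 / 0.03) keeps within-group variation non-zero. Read counts
are Poisson(λ · copy/2) totals with binomial methylated counts; fragment
tracks place midpoints uniformly at rate proportional to copy/2; the
array counterpart subsamples loci (default 25%), adds truncated Gaussian
noise (sd 0.03) and applies a fixed logistic squeeze mapping [0, 1] into
≈ (0.12, 0.88) to mimic array intensity compression.

The simulator deliberately omits bisulfite conversion failure, mapping and
GC bias, probe-specific array artefacts, FFPE degradation, tumour purity
and subclonality. Passing tests therefore demonstrate that the algorithms
are implemented correctly and behave as designed under their stated
assumptions — spatially autocorrelated bimodal methylation, near-uniform
coverage, pure tumours — not that real cohorts will reach the same error
rates. In particular, real low-pass missingness is spatially structured
(mappability, GC), while the recovery experiments mask completely at
random; and simulated coverage has no wave artefacts, so segmentation here
is easier than on real libraries.

## Validation scale and reproducibility

The test suite exercises cohort-scale behaviour at sizes chosen to keep a
full run fast on a laptop: imputation recovery on 8 samples × 60,000 CpGs
(17% masked), arm-level CNV sensitivity on 20 simulated tumours over a
10-chromosome, 3 Mb/chromosome toy genome, and breakpoint localisation
over 100 seeded replicates. The acceptance script scales the imputation
cohort to 20 samples × 200,000 CpGs. All randomness flows from explicit
seeds through `withr::with_seed()`, so every reported number is
bit-reproducible; regenerating a cohort from the same config is
bit-identical.

## Known limitations

* Copy-state thresholds assume high tumour purity; no purity/ploidy
  deconvolution is attempted, and allele-specific copy number is out of
  scope.
* The CBS implementation prunes nothing after splitting; adjacent segments
  with statistically indistinguishable means can persist when α is
  relaxed far above the default.
* `beta_other_mean` makes single-sample cohorts unimputable by design;
  the error message says so rather than degrading to a weaker model.
* Array probes are matched as points; probes whose target CpG sits at the
  far end of their 50 bp footprint may fall outside the 25 bp tolerance.
* The imputer's sentinel distance (10^6 bp) is a convention, not a
  physical scale; models trained with it should not be applied to feature
  tables built with a different sentinel.
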