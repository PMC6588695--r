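---
title: "Methods: differential and evolutionary analysis of brain LC-MS metabolome peak tables"
author: "metacortex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential and evolutionary analysis of brain LC-MS metabolome peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of the package: the
models, their assumptions, the tunable parameters and their defaults, the
synthetic-data generator used throughout the test suite, and the numerical
design decisions taken where the problem left genuine latitude. It states
no empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

# Data model

A `PeakExperiment` extends `SummarizedExperiment`: a peaks × samples
intensity matrix (linear scale unless its `log2` flag is set), per-peak
*m/z* (Da), ionization mode and optional retention time in `rowData`, and
per-sample covariates — species, diagnostic group, age in years (negative
for prenatal), sex, postmortem delay (PMD, hours), RNA integrity number,
injection order, batch — in `colData`. `group` is defined only for human
samples. Positive- and negative-mode runs are merged by concatenating the
peak axes over a shared sample set; ids get `pos:`/`neg:` prefixes so they
can never collide, and the operation preserves every intensity value.

# Putative annotation

Observed *m/z* values are matched to theoretical adduct masses
`mass + delta` for seven singly charged forms (positive: [M+H], [M+NH4],
[M+Na]; negative: [M−H], [M+FA−H], [M−H2O−H], [M+Na−2H]); the deltas are
monoisotopic, stored to six decimals in one constant table
(`adductTable()`). A match requires `|ppm| <= tolerance` with
`ppm = (obs − theo)/theo × 1e6`; the default tolerance is 10 ppm and the
comparison is deliberately inclusive, so boundary hits are matches. The
candidate search is an interval query over a mass-sorted index, with an
exact ppm test at the window edges so floating-point rounding cannot
change a boundary decision; the test suite proves it record-for-record
identical to an exhaustive scan. All in-tolerance (compound, adduct)
pairs are reported — annotation at 10 ppm is putative by nature, and
downstream gene linking deliberately consumes every candidate rather than
a guessed "best" one. Multiply charged ions and isotope-pattern scoring
are out of scope.

# Injection-order drift correction

Long LC-MS runs drift: sensitivity changes smoothly with injection order
for a subset of metabolites. Per metabolite, intensities are
log2-transformed and standardized (mean 0, SD 1); a support vector
regression with an RBF kernel (`svr_c = 1`, `svr_epsilon = 0.1`) of
standardized intensity on injection order estimates the order-effect
curve, one shared hyperparameter set for all metabolites. Because drift
is a run-scale phenomenon, the default kernel width ties the length scale
to the run: `gamma = 1/range(order)^2`. Curves are clustered with k-means
(`k = 10`, fixed seed).

Deciding which clusters are drift-affected replaces a manual visual check,
and a naive automated rule is biased: k-means groups noise curves of
similar shape, so a cluster-mean curve evaluated on the same data the
cluster was selected from retains substantial amplitude and near-monotone
rank correlation even for pure noise. The package therefore splits the
samples by injection-order-rank parity: curves are fitted and clustered on
the odd-rank half, and each cluster is judged on its members' raw mean
profile over the held-out even-rank half, where the profile of a null
cluster of *m* members shrinks as 1/sqrt(m). A cluster is flagged when
that held-out profile has |Spearman rho| ≥ 0.3 against order **and** a
smoothed peak-to-trough amplitude ≥ 0.5 SD; both thresholds are
configurable. Flagged-cluster members are corrected by subtracting the
cluster-average standardized profile computed on all samples — subtracting
the average of epsilon-insensitive SVR fits instead would undershoot the
drift by the tube width plus regularization shrinkage — then intensities
are returned to the linear magnitude scale. With `action = "discard"`
flagged members are dropped instead. Consequences verified in the test
suite: a driftless table is a fixed point (no flags, output equals input),
planted 2-SD linear drift is flagged and removed (median residual
|Spearman rho| below 0.1), a second pass flags nothing, and zero-variance
metabolites pass through unchanged with a warning.

# PMD filter

Metabolites that degrade or accumulate after death confound group
comparisons. The filter uses one species (default macaque) with many
short-PMD reference animals (PMD ≤ 20 min) and a few prolonged-PMD probes
(5–6 h). Per metabolite, a natural cubic regression spline with
`spline_df = 4` of log2 intensity on age is fitted to the references; each
probe is compared to a prediction-style interval,
`prediction ± z(0.95) × sqrt(s²(1 + leverage))` — a prediction rather than
a confidence interval because an individual new sample, not a mean, is
being judged. Any probe strictly outside excludes the metabolite; a probe
exactly on a bound is retained, and probes outside the reference age range
are skipped rather than extrapolated. With two probes and 95% intervals
the expected false-exclusion rate among unaffected metabolites is about
1 − 0.95² ≈ 10%, a deliberate stringency trade-off; the per-probe bounds
are returned in the `details` table so exclusions can be audited.

# Upper-quartile normalization

Within each ionization mode, each sample's intensities are divided by the
75th percentile of its nonzero intensities and multiplied by the geometric
mean of the per-sample quartiles, restoring the original magnitude scale.
After normalization the per-sample upper quartiles within a mode are equal
to machine precision. The restoration constant necessarily depends on all
samples, so rescaling one sample changes the output by a single global
factor (the geometric mean shifts by the n-th root) while every
between-sample ratio is exactly invariant — the strongest invariance any
quartile-dependent restoration can provide.

# Differential calling: two-reference age-ANCOVA

Metabolite levels follow strong, nonlinear age trajectories, so the group
comparison is a nested-model F-test on top of a polynomial age trend. Per
peak:

1. The polynomial degree (0 to `max_degree = 3`) is chosen by adjusted R²
   on the *reference group only*, with age centered and scaled before
   powers for conditioning. Ties within `1e-8` go to the smaller degree;
   the degree is capped at what the data can support, with a warning.
   Adjusted R² is a mild penalty: it admits a spurious term with
   probability roughly P(F > 1) ≈ 1/3, so under pure noise degree 0 is
   the modal but not near-certain choice — the criterion orders models, it
   does not perform hypothesis-test-strength selection, and the test suite
   asserts exactly that behavior.
2. The null model (that polynomial, fit to all samples) is compared to the
   full model with an additive group-offset term:
   `F = (RSS0 − RSS1) / (RSS1 / (n − k − 2))`, p from F(1, n − k − 2).
   The group term is an intercept offset only — no group × age
   interaction — so the test asks whether one group runs uniformly above
   or below the shared trajectory.
3. The procedure runs twice, once per reference group; BH adjustment is
   applied separately within each run across all peaks, and a peak is
   significant only if both adjusted values pass `alpha = 0.05`. The
   two-reference design makes the call robust to which group's samples
   drive the trend estimate.

The effect direction is the sign of the case-group coefficient in the
control-reference fit. Degenerate responses (zero residual variance) are
resolved explicitly: if the null model also fits perfectly there is no
evidence for an effect (p = 1); if only the full model does, the offset
explains everything (p = 0). Age is the only covariate; sex, RIN and PMD
enter the design through matching and filtering, not the model.

Calibration is part of the acceptance suite: across 2000 null simulations
at n = 72 the type-I error at nominal 0.05 must fall in [0.03, 0.07], and
power at a 1-SD offset must exceed 0.8.

# Temporal modules

Significant peaks are clustered on standardized log2 intensities across
all human samples with distance 1 − Pearson correlation, complete linkage,
tree cut at `n_modules = 4`. Peaks are sorted by id before clustering so
the partition cannot depend on input order; zero-variance peaks are
dropped with a warning. Module summaries are cubic-smoothing-spline
trajectories of the per-sample module mean, per group, on a 50-point age
grid — display smoothing only, with no downstream role.

# Pathway enrichment and expression shifts

Peaks map to compounds (all putative matches), compounds to directly
linked enzymes, genes to pathways. The background is the gene set linked
to *all* detected peaks, the selection the subset linked to the peaks of
interest; each pathway with at least one background gene gets an
upper-tail hypergeometric p for the selection/pathway overlap drawn from
the background, BH-adjusted across pathways. Overlap between two pathway
sets is tested one-sided with Fisher's exact test over the union of tested
pathways as universe — the minimal well-defined choice. For expression
shifts, each peak's proportion of linked genes with |log2 fold change| >
0.2 is computed, and the proportion distributions of two peak categories
are compared with a two-sample KS test. Mapping tables are static inputs
with a documented schema; no live database queries, and database-version-
dependent pathway counts are treated as properties, never as fixed
expected values.

# Stability selection

Diagnosis is predicted from metabolite intensities with L1-regularized
logistic regression at a fixed penalty, C = 100 in sklearn convention,
mapped to the glmnet lasso penalty `lambda = 1/(C · n_train)` and reached
through a short warm-start path. Each of `n_subsamples = 500` seeded
stratified 75/25 train/test splits standardizes features on the training
fold (applied unchanged to the test fold — the source of the
scaling-invariance guarantee), fits, records the nonzero-coefficient set
and evaluates the test ROC AUC via the Mann–Whitney statistic, where a
constant score yields 0.5 by construction. Inclusion probability is the
fraction of splits with a nonzero coefficient; predictors are ranked by
inclusion probability, then mean |coefficient|, then peak id — a fully
deterministic chain — and the top `top_k = 200` form the predictor set.
Non-convergence is counted and reported, never silently dropped.

# Lineage-specificity calls

Cross-species comparisons use human-equivalent ages: nonhuman ages are
multiplied by per-species factors. The factors belong to the
configuration; the defaults (human 1, chimpanzee 61/42, macaque 61/21)
simply align the three species' observed lifespans onto the human range
and should be replaced by calibrated developmental-alignment factors when
available. Human samples default to controls only, so disease effects
cannot masquerade as lineage effects; macaque PMD probes are excluded
whenever PMD is recorded.

*Stringent*: for each species pair the two-reference ANCOVA runs with
species as the group factor, BH within pair across peaks, both reference
runs must pass. Human-specific requires human/chimpanzee and human/macaque
significant and chimpanzee/macaque not; chimpanzee-specific is the mirror
image. *Relaxed*: per peak, intensities are z-scored across all included
samples pooled (one common transform, hence affine invariance); with
species means m_H, m_C, m_M, human-specific requires
|m_H − m_M| > |m_C − m_M| with sign(m_H − m_M) = sign(m_C − m_M), and the
mirror rule for chimpanzee. Swapping the human and chimpanzee labels swaps
the two call types exactly; both symmetries are asserted in the test
suite. The two criteria answer different questions and need not nest: a
real but small shared-direction shift in the sister lineage can make the
pairwise ANCOVA significant (failing the stringent exclusivity clause)
while strengthening the relaxed sign condition.

Module-level summaries draw `subsample_n = 30` animals per species,
`n_module_subsamples = 1000` times, recompute relaxed calls per draw, and
record the human:chimpanzee call-count ratio genome-wide and per module.
Zero denominators become +Inf and are summarized by median and quartiles,
which stay finite while fewer than a quarter of draws are degenerate; the
degenerate fraction is reported alongside. Concordance with an external
fold-change table is Pearson correlation plus a one-sided Fisher test on
the sign-quadrant table.

# The synthetic cohort generator

`generateCohort()` emulates the statistical structure the pipeline is
built for, not raw spectra. Defaults are the study conditions: 40 human
controls (0–61 y), 32 ASD cases (2–60 y), 40 chimpanzees (0–42 y), 40
short-PMD macaques (−0.27 to 21 y) plus 2 prolonged-PMD probe animals
(PMD 5–6 h, everyone else under 20 min); 500 peaks, 60% positive mode.
Ages are uniform within each range — the real cohorts oversample young
ages, which matters for display but not for the offset-model power the
tests measure. On the log2 scale each peak gets a baseline
(N(20, 2²)), a smooth age trend, planted effects, and homoscedastic
Gaussian residuals (`noise_sd = 1`), then is exponentiated with the
intensity magnitudes and multiplicative noise of real peak tables.

Planted structure, all fractions disjoint by construction:

- **ASD effects** (10% of peaks, 1.0 residual-SD offsets): four module
  archetypes shared within module. The shapes are tetrahedral-simplex
  combinations of the first three orthonormalized Legendre polynomials in
  scaled age, giving smooth distinct trajectories with pairwise
  correlation exactly −1/3. That geometry is what makes
  correlation-distance clustering well-posed: any two modules are
  strictly anti-correlated, while any smooth null trajectory correlates
  at least +1/3 with some archetype, so stray false-positive peaks attach
  to a module before two modules can merge under complete linkage.
  Modules 1–2 are elevated in ASD, 3–4 reduced; module 3's offset
  declines linearly from 1.5× at birth to 0.5× at age 60 (mean 1), an
  early-childhood emphasis that preserves the additive-offset power the
  differential test is calibrated against.
- **Drift** (10% of peaks): a linear 2-SD span across the injection run.
- **PMD sensitivity** (4%): a 10-SD shift confined to the probe animals.
- **Lineage shifts** (45% human, 15% chimpanzee — 3:1 — at 2 SD): the
  shifted lineage moves fully, the sister lineage moves 0.2× in the same
  direction. The partial shift models gradual shared change with
  lineage-specific acceleration and is what makes the relaxed criterion's
  sign-concordance clause informative: with a pure one-lineage shift the
  sister lineage's deviation sign would be a coin flip and the relaxed
  rule could recover at most half the planted peaks. The 0.45/0.15
  fractions were chosen a priori so that, given the relaxed criterion's
  known 1/4–1/4 null call rates, the genome-wide human:chimpanzee ratio
  lands near the planted 3:1 regime rather than being diluted toward 1.

`generateReferenceTables()` supplies a ~60-compound library (masses
computed from molecular formulas with monoisotopic atomic masses — the
glutathione, purine, pyrimidine, TCA and amino-acid chemistry a brain
polar-metabolite study would annotate), a toy pathway annotation with one
pathway per compound class, and a gene-level log2 fold-change table in
which genes linked to affected peaks carry inflated values. Affected
peaks draw compounds from the four module classes (module 3 from the
glutathione class), unaffected peaks from the remaining classes, keeping
the affected-linked and unaffected-linked gene sets disjoint so the
planted enrichment and expression-shift contrasts are well defined.
Everything is deterministic given the seed.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: missing values and detection limits,
heteroscedastic or heavy-tailed noise, retention-time drift, correlated
peak families from shared compounds (adducts/fragments of one metabolite),
batch structure beyond injection order, and non-uniform age sampling.

# Problem sizes and runtime

The test suite and acceptance script run the full pipeline on the default
500-peak cohort, 2000 null ANCOVA simulations, 500 classifier subsamples
and 1000 lineage subsamplings; oracle-equivalence checks enumerate all
hypergeometric configurations up to a background of 12 genes and all 70
label assignments of the tiny KS instance. These sizes were chosen so the
statistical claims are measured at meaningful resolution while the whole
suite completes in a few minutes on one CPU.

# Known limitations

- Annotation is putative: at 10 ppm, distinct compounds with close masses
  (structural isomers share masses exactly) are indistinguishable, and all
  candidates propagate to gene linking by design.
- The drift flag thresholds, though held-out-evaluated, are heuristic
  surrogates for expert review; pathological drift shapes with zero rank
  correlation and small amplitude would pass unflagged.
- The ANCOVA models an additive group offset; group × age interactions are
  detectable only insofar as they project onto an offset.
- The PMD filter's two-probe design has ~10% false-exclusion rate by
  construction; it trades peaks for confidence in the survivors.
- Age-scaling factors for the stringent cross-species ANCOVA are
  lifespan-alignment defaults, not calibrated developmental mappings.
- The relaxed lineage criterion calls roughly half of truly null peaks at
  random (1/4 to each lineage); it is a ranking and ratio device, not a
  per-peak significance statement.
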