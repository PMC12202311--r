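---
title: "Consensus stability selection for two-class metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus stability selection for two-class metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboselect)
```

## Overview

`metaboselect` implements a biomarker-discovery pipeline for two-class
untargeted metabolomics, built around one idea: a metabolite is a credible
group marker only if it is selected in *every* repetition of the analysis,
across imputation draws, selector seeds, and held-out sample subsets. The
motivating design is a slaughter cohort of pigs — castrated males vs intact
gilts, plasma sampled on many collection days, body weight as a continuous
confounder, a 2:1 class imbalance — but every stage is generic for a
samples × metabolites abundance matrix with group, weight and batch-day
metadata.

This vignette explains the model and procedure, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## Data cleaning

Per metabolite, a value is masked as missing when it deviates from the
metabolite's median by strictly more than 5 interquartile ranges; quartiles
use linear interpolation between order statistics (`quantile()` type 7, the
common default — no convention is canonical, so one is fixed and used
everywhere). The strict inequality means a constant metabolite (IQR 0) is
never masked, which protects near-constant metabolites from being
destroyed. Metabolites with fewer than four observed values are skipped
with a warning because their quartiles are unstable.

Filtering then cascades in a fixed order: xenobiotic-class metabolites are
dropped first (they reflect exposure, not physiology), then metabolites
with a missing fraction strictly above 25%, then samples with a missing
fraction strictly above 30% computed over the *surviving* metabolites.
"More than" is read literally: exactly 25% (or 30%) survives. The cascade
order matters — a metabolite removed for missingness no longer counts
against its samples — and applying the filter twice changes nothing.

## Imputation

Missing values are imputed by chained equations with predictive mean
matching (PMM). For each target metabolite the `n_predictors = 10` most
absolutely-correlated metabolites are chosen once, on the incomplete input
matrix, using pairwise-complete Pearson correlations; a candidate needs at
least `min_predictor_overlap = 10` shared observations, which guards
against spurious |r| = 1 from tiny overlaps. Absolute correlation is used
because a strongly negative predictor is exactly as informative as a
positive one.

Each imputation initializes missing cells with random draws from the
observed values, then runs `n_chain_iterations = 5` sweeps. In each sweep
the observed target values are regressed on the predictors, the
coefficients are perturbed with a normal draw using the least-squares
covariance (a standard proper-PMM variant; plain "predictive mean
matching" does not pin this down further), predicted means are formed for
observed and missing rows, and each missing cell copies the observed value
of one of the `donor_pool_size = 5` rows with nearest predicted mean,
chosen uniformly. Every imputed value is therefore an actually observed
value of the same metabolite — asserted exhaustively in the tests. The
default grid of 5 imputations under each of 5 seeds yields 25 completed
datasets; Rubin-style pooling is deliberately absent, because each
completed dataset is analyzed separately downstream.

## Confounder removal

Each metabolite is independently regressed on an intercept, body weight,
and J − 1 reference-coded collection-day dummies (reference level:
lexicographically smallest day label — the coefficients are nuisance, so
the choice only needs to be fixed), and the residuals replace the data in
all selection and testing steps. A constant covariate column is dropped
rather than producing a rank-deficient fit; remaining collinearity is an
error naming the columns. For the correlation network's population-level
correlations the model additionally contains a group indicator, so the
group difference itself does not masquerade as a metabolite–metabolite
correlation. Mixed or litter effects are out of scope: the model is fixed
effects only.

## Shadow-feature selection

The selector is a from-scratch implementation of the Boruta scheme. Each
iteration: every currently undecided feature's column is permuted to make
a "shadow" feature; a random forest (impurity importance, 300 trees by
default, class weights inversely proportional to class frequency to
protect the 2:1 imbalance) is fitted on [not-yet-rejected real features |
shadows]; an undecided feature scores a *hit* if its importance strictly
exceeds the maximum shadow importance. Hits accumulate, and after each
iteration a two-sided binomial test with success probability 0.5,
Bonferroni-corrected over the currently undecided pool, confirms features
in the upper tail and rejects them in the lower tail at `alpha = 0.01`.
The run stops at `max_iter = 1000` or when the pool empties; leftovers are
*tentative* and never count as selected — only "confirmed" enters the
consensus.

Two implementation choices are worth recording. First, the number of
shadows equals the number of undecided features each iteration and shadows
are re-permuted every iteration (the classical scheme); the two-step
correction used by some newer implementations is not replicated. Second,
shadow permutations and forest seeds are drawn from per-(iteration,
feature) streams derived from the run seed, so results do not depend on
column order, and two runs with the same seed but different `max_iter`
agree on all common iterations — that makes "shrinking `max_iter` never
adds confirmed features" a structural property, which the tests assert.

With the correction disabled, a feature that hits every iteration is first
confirmable at iteration 8: the two-sided tail is 2·0.5⁸ ≈ 0.0078 < 0.01,
while 7 iterations give 0.0156. This binomial-tail arithmetic is frozen
into the tests as an oracle.

## The consensus grid

The default `grid_plan()` reproduces the study geometry: 5 imputation
seeds × 5 imputations = 25 completed datasets, each residualized and
analyzed with 5 selector seeds — 125 full-data runs. The **selection set**
is the intersection of the 125 confirmed sets; 124 of 125 is not enough.
Each completed dataset is then partitioned once into 10 group-stratified
folds (stratification protects the imbalance; the partition is drawn per
dataset, not per selector seed), and each fold's retained nine-tenths is
residualized afresh and analyzed with the 5 selector seeds — 1,250
additional runs. The **core set** is the subset of the selection set
confirmed in all of them, so core ⊆ selection holds by construction, and a
per-metabolite confirmation rate over the CV runs is reported.

When sPLS-DA replaces the shadow selector (`selector = "splsda"`),
confirmation additionally requires the loading sign to be identical across
runs: a metabolite selected everywhere but with flipping sign is dropped.

## Scoring

Scores are computed per completed dataset and reported as mean ± SD across
datasets. Mean-decrease-Gini importances come from one balanced forest on
the scored set and are normalized to sum to 1 — on a 40-metabolite set
exchangeable noise gives ≈ 0.025 each, which sets the scale of the
reported values. The per-metabolite AUC is the rank statistic with ties
counted one half, folded as max(a, 1 − a) so it measures discriminative
strength regardless of which group is higher. Mann–Whitney tests use base
R's `wilcox.test` (exact for small tie-free samples, tie- and
continuity-corrected normal approximation otherwise) with a Bonferroni
divisor equal to the number of scored metabolites. AUC and tests run on
residuals, consistent with "residuals are used in data analysis"; the
relative difference Δ% = (x̄_A − x̄_B)/x̄_A·100 instead uses the imputed raw
abundances, because residual means are ≈ 0 and would make the ratio
degenerate. The out-of-bag error of the balanced forest summarizes joint
classification performance without a held-out set.

## Network and over-representation

Pearson correlations among selected metabolites are computed three ways —
population-level on group-adjusted residuals, and within each group on
weight+day residuals — and the coefficient with the largest |r| is kept
per pair, with an edge when |r| ≥ 0.5 (inclusive, "≥"). Node statistics
use unweighted hop counts: average shortest path to the other nodes of the
node's component, and betweenness normalized by (n−1)(n−2)/2 within each
component of size n; all statistics of singleton nodes are reported
unavailable ("–" in tables). By default the correlations come from the
first imputed dataset; a Fisher-z average across all datasets is a
documented option (`correlation_triplet` on each member and `atanh`-mean)
left to the user, since the within-dataset choice is what the run
geometry fixes.

Over-representation uses the one-sided hypergeometric upper tail per
metabolite set, Benjamini–Hochberg across sets, and keeps a set when
FDR < 0.05 *and* at least 2 input metabolites overlap it. The universe is
the post-QC metabolites that map into the library via their HMDB ids — the
closest reproducible reading of web-tool behaviour, exposed as an
argument. A multi-valued HMDB cell maps its metabolite to a set if *any*
id is a member, counted once. No pathway content is bundled (licensing and
version drift); the GMT file is user input.

## The synthetic generator

`generate_dataset()` draws log-normal abundances: per metabolite and
sample, `log y = mu_m + log_sd·(z + d_m·A) + b_m (w − w̄) + c_m[day]`,
where `z` is a unit-variance latent with single-factor within-block
correlation, `d_m` the planted standardized shift (sign random, magnitude
`sqrt(2)·qnorm(auc)` for a target AUC drawn from `target_auc_range`), `A`
the group-A indicator, and `b`, `c` weight and day effects. Because the
shift acts on the unit-variance latent and the log is monotone, the
large-sample AUC equals `pnorm(|d|/sqrt(2))` exactly — the calibration the
tests verify empirically at n = 2×5,000 within ±0.02. With the default
`log_sd = 0.3`, target AUCs of 0.54–0.70 correspond to relative
differences |Δ%| of roughly 4–20, matching the scale of real panels.

Defaults mirror the motivating cohort: 228 vs 466 samples, 600
metabolites, weight 155 ± 5 kg, 23 collection days. Missingness is a
mixture of completely-at-random and censoring-like (rank-weighted toward
low abundances, `censor_fraction = 0.5` of the missing mass), because
LC-MS missingness is abundance-dependent. Outliers multiply a random cell
by at least 8, inflated if needed so the 5×IQR rule provably flags it.
Every sub-step (covariates, effects, latent, confounders, outliers,
missingness, annotation) uses its own RNG stream derived from the single
seed, so the dataset is bit-for-bit reproducible and sub-steps are
individually stable.

What the generator does **not** emulate: chromatographic or ionization
effects, plate-to-plate drift, vendor QC normalization, heavy-tailed or
multimodal abundance distributions, and any real biological pathway
structure (annotations are arbitrary labels). Passing tests therefore
demonstrate statistical correctness of the pipeline under a plausible
generative model, not performance on any particular real cohort. The
marginal log-normal form itself is a modeling choice, not an empirical
claim.

## Numerical choices and degenerate inputs

- Quartiles: type 7 everywhere; thresholds (5×IQR, 25%, 30%) strict.
- Predictor regressions drop collinear columns with a warning; a target
  with no admissible predictors falls back to random observed-value
  draws, logged.
- A day level with a single sample produces a warning (its residual is
  forced to 0); a single-class fold is an error.
- Zero-variance features: auto-rejected by the selector (warning),
  importance 0 in scoring, error in predictor selection when the target
  itself is constant.
- Ties in |r| rankings break by lexical metabolite id; the sPLS loading
  sign is fixed by making the largest-|loading| feature positive.
- All randomness flows from one master seed through labelled streams
  (`derive_seeds`): polynomial string hash of the label, offset added to
  the seed modulo 2³¹ − 1, one `sample.int` draw. Stages are thereby
  independently reproducible and keep every derived seed below 2³¹.

## Problem sizes used in the validation suite

The tests exercise the full default run geometry (25 imputed datasets,
125 + 1,250 selector runs) on a deliberately small cohort (40 samples, 10
metabolites, 20-tree forests, 20 iterations), and parameter recovery on
150 + 150 samples × 60 metabolites with 8 metabolites planted at AUC
0.75–0.85 under a reduced 2×2×2 grid with 5 folds — sizes at which the
whole suite runs in minutes while still separating planted signal from
noise decisively. At these conditions the consensus recovers the planted
set essentially perfectly (recall 1.0, precision ≥ 0.9 over five generator
seeds in the acceptance script's own re-run); the numbers your machine
produces are written by `scripts/acceptance.R`, not quoted from anywhere.

## Known limitations

- The imputation regressions assume approximate linearity among
  correlated metabolites on the abundance scale; heavily skewed panels
  may prefer a log transform before the pipeline.
- Forest size and tree depth are not tuned inside the cross-validation
  (deliberately — the CV measures selection stability, not generalization
  of a tuned classifier).
- The intersection consensus is conservative by design: one failed run
  vetoes a metabolite, so small selector instabilities at weak effect
  sizes reduce recall before they ever reduce precision.
- Betweenness and shortest paths treat the network as unweighted; |r| is
  an edge attribute, not a distance.
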