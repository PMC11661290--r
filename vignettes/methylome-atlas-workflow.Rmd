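---
title: "Methylome atlas models for acute leukemia: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome atlas models for acute leukemia: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Acute leukemia subtypes leave strong, stable imprints on genome-wide DNA
methylation, and aggregate methylation state carries prognostic information
beyond cytogenetic risk groups. `methatlas` implements a complete analysis
chain for array-style methylation data (β-values, the fraction methylated per
CpG probe) of leukemia cohorts:

1. **QC and harmonization** of multi-cohort β matrices,
2. a **manifold atlas** compressing hundreds of thousands of probes into 2
   coordinates (visualization) or 5 coordinates (classification),
3. **gradient-boosted classifiers** on the 5-D coordinates for disease subtype
   and for death within five years,
4. a **stepwise CpG hazard signature**: per-probe Cox proportional-hazards
   association scan → suggestive screen → stability-selected L1-penalized Cox
   → compact linear M-value score dichotomized at its training median,
5. **survival evaluation** (Kaplan–Meier, log-rank, Cox hazard-ratio reports,
   five-year ROC), and
6. a **nanopore bridge** that converts modkit-style bedMethyl 5mCG calls into
   the atlas feature space and produces a gated per-sample diagnostic and
   prognostic report.

Everything runs end to end on synthetic cohorts with planted structure, so the
full workflow is testable without any data download.

```{r}
library(methatlas)
config <- discovery_config(seed = 1)
disc <- run_discovery(config)
str(disc$evaluation)
```

## The synthetic generator and what it emulates

`generate_cohort()` draws β-values from a **logit-normal cluster mixture**:
each probe has a baseline logit-mean (N(0, 1.5²), giving the familiar bimodal
β distribution), each subtype adds Gaussian centroid offsets over an
informative probe subset, scaled so the expected centroid–centroid distance is
`cluster_separation`, and samples scatter around their centroid with
`sigma_logit = 0.5`. A logit-normal (rather than beta-mixture) model keeps the
downstream M-value mathematics linear: M-values are exactly the latent logits
up to the factor `1/log(2)`, so the Cox association stage is correctly
specified under the generative model.

Parameter defaults and their rationale (all overridable):

* `sigma_logit = 0.5` — a within-subtype β-value SD near 0.1 at intermediate
  methylation, the magnitude typical of within-group probe variability on
  450K/EPIC arrays.
* `baseline_hazard = 0.01` events/month — about 45% mortality by 60 months at
  a null linear predictor, in the range of pediatric AML trial cohorts.
* `censoring_rate = 0.1` — interpreted as the fraction *lost to follow-up
  before the horizon*; uniform censoring on `[0, horizon]` is applied to a
  random subject subset whose size is calibrated by bisection (±0.02), with
  administrative censoring at `horizon_months = 60` applied on top. This keeps
  the parameter meaningful even when administrative censoring dominates.
* Survival signal: `n_prognostic_cpgs = 10` probes with alternating-sign log
  hazard ratios of `±0.7` per M-value unit, acting through
  `eta = Σ b_j (M_j − E[M_j])`, plus per-subtype hazard offsets
  (`cluster_log_hr = 0.5` SD) — prognosis in acute leukemia is to a large
  degree a function of diagnostic subtype, and without this component the
  atlas coordinates (which encode subtype) would carry no survival
  information at all. Cluster-informative, prognostic, and QC-flagged probe
  subsets are disjoint, so filters never delete planted signal and the
  per-probe association scan sees clean nulls apart from the
  subtype-mediated hazard.
* The clinical risk group is built from noisy tertiles of `eta`
  (noise SD = 1.5 × SD(eta)). It is deliberately an *imperfect proxy* of the
  epigenomic signal — as cytogenetic risk grouping is in practice — so that
  risk-group-adjusted association scans are exercised without the adjustment
  absorbing the entire per-probe effect.
* MRD1 (minimal residual disease after first induction, positive at ≥0.1%
  leukemic cells) is Bernoulli with a logistic link in `eta`.

What the generator does **not** emulate: probe-specific measurement error
profiles, spatially correlated probes, karyotype/fusion structure, cell-type
composition shifts, 5hmC, and read-level noise. Passing tests therefore
demonstrate the correctness and statistical calibration of the pipeline under
its own modeling assumptions, not clinical performance on real arrays.

`generate_cohort(config, template = previous)` re-draws samples from a
previous cohort's generative model (same probe roles, centroids, and
coefficients), which is how independent validation cohorts are made.

## QC and harmonization

`qc_pipeline()` applies, in order: manifest-flag filters (sex-linked,
non-CpG, masked probes), detection-p-value sample exclusion, high-missingness
probe removal (strictly more than 5% missing), caller-supplied non-target
sample removal, PCA outlier exclusion, batch-mean imputation, and
empirical-Bayes batch adjustment. Two rules are under-determined by
convention and are exposed as parameters with field-standard defaults: a
sample fails when more than 5% of its probes have detection p > 0.05, and a
sample is a PCA outlier when its score on either of the first two principal
axes lies more than 6 robust SDs (1.4826 × MAD) from the axis median — robust
scaling avoids masking by the outliers themselves.

Batch adjustment wraps the parametric ComBat location/scale model from the
`sva` package, batch-only by default (a covariate-protecting mode exists).
Two in-package post-steps: each probe is re-centered to its pre-adjustment
pooled mean (the empirical-Bayes restore step moves pooled means by ~1e-4,
and downstream stages assume the pooled scale is untouched), and output is
clipped to [0, 1]. Single-batch input returns unchanged; zero-variance probes
pass through untouched.

## The atlas embedding

`fit_embedding()` implements pairwise-controlled manifold approximation:
inputs wider than 100 probes are first compressed to 100 principal
components; near pairs (10 per sample, chosen by locally scaled distances),
mid-near pairs (ratio 0.5), and random far pairs (ratio 2) are built; and
coordinates are optimized by Adam through the algorithm's published
three-phase weight schedule (100/100/250 iterations), from a PCA
initialization scaled by 0.01. All hyperparameters sit at the algorithm's
published defaults; the seed is stored in the model. β-values (not M-values)
are embedded by default, matching the atlas construction convention; pass
M-values explicitly if preferred.

2-D and 5-D fits are independent fits (no shared initialization); each is
individually reproducible under its seed.

Out-of-sample projection (`project_samples()`) places a new sample at the
inverse-distance-weighted average of its 10 nearest training samples'
coordinates in the (PCA-reduced) input space. This is recorded in the model
as `transform_method = "knn_weighted_average"`. It is exact for training
samples, deterministic, and cheap; its known limitation is that it cannot
extrapolate outside the convex hull of the training embedding, which is the
desired behavior for an atlas with fixed cluster geography.

## Classifiers on atlas coordinates

`train_subtype()` and `train_risk()` fit gradient-boosted, leaf-wise-grown
decision-tree ensembles (via `xgboost` with `grow_policy = "lossguide"`) on
the 5-D coordinates. Tuning is stratified 5-fold cross-validation over a
small grid — learning rate {0.05, 0.1}, leaves {7, 15, 31}, L1 ∈ {0, 0.1, 1},
L2 ∈ {0, 0.1, 1} — with up to 200 trees and early stopping (20 rounds) on the
held-out fold; class weights are inversely proportional to class frequency.
The subtype model is selected by pooled out-of-fold macro-F1, the risk model
by out-of-fold AUC. The *reported* cross-validation metrics (and per-class
concordance) come from a fresh outer CV pass at the selected configuration —
reporting the tuning pass's own out-of-fold metric would inherit the
optimism of picking the best of 54 grid points, visibly so under
label-permutation nulls. Per-class "concordance" is operationalized as held-out
recall per class. Classes smaller than the fold count merge into an `other`
stratum with a warning; ties in predicted probability resolve to the first
class in the declared class order.

The five-year mortality target is binary: events before 60 months are
"dead", follow-up reaching 60 months without an event is "alive", and samples
censored earlier are excluded from classifier training (their count is
recorded) — anything else would assign a label that the data cannot support.
They remain in all survival analyses, which handle censoring properly.

## The CpG hazard signature

`cox_ewas()` fits one Cox model per probe (Efron ties), covariates = probe
M-value + risk-group indicators, follow-up administratively censored at 60
months, and reports the Wald statistics of the probe coefficient. Probes with
zero variance are skipped; non-converging fits keep `NA` p-values with a
count. `select_suggestive()` keeps probes with p strictly below 1e-5.

`stability_select()` then repeats, per iteration: re-randomize an
event-stratified 10-fold assignment; choose the L1 penalty minimizing mean
cross-validated partial-likelihood deviance over a fixed 50-point grid
log-spaced four decades down from the smallest all-zero penalty; and record
the non-zero set of a penalized fit at that penalty. **Design note:** the
recorded fit runs on a random half of the samples (Meinshausen–Bühlmann
subsampling) rather than on the full data. With a full-data recorded fit the
non-zero set at a given penalty is deterministic, selection frequencies
collapse to {0, 1}, and the ≥95% frequency rule loses its false-positive
control (we measured 19 consistently selected null probes out of 190 on a
500 × 200 experiment; with subsampling: 0, while 9/10 planted effects of
|log HR| 0.4–0.8 still exceeded 95%). Penalty *selection* remains full-data
cross-validation re-randomized each iteration. `resample = "none"` restores
the literal full-data variant, `"bootstrap"` resamples n with replacement.
The subsample fit truncates the penalty path at the chosen value: the
saturated small-penalty tail is numerically unstable on subsampled survival
data and is never selected anyway.

`fit_signature()` refits an unpenalized joint Cox model on the selected
probes (a ridge fit with penalty 1e-3 is the fallback for collinear sets, and
`penalized = TRUE` forces it); the refit is preferred for interpretability of
the reported coefficients. The score is `Σ b_i · M_i`; the cutoff is the
median training score; `score_and_group()` labels `high` strictly above the
cutoff (ties → `low`).

## Survival evaluation

`km_estimate()` (product-limit with Greenwood variance on the log scale),
`logrank_test()` (unweighted, chi-square reference), `cox_fit()`
(partial-likelihood Newton–Raphson with Efron ties, Wald intervals,
separation flagged at |coef| > 20), and `auc_5y()` (rank-based AUC against
the determinate dead-by-60-months outcome — binary-at-horizon, mirroring the
risk classifier's target, not a time-dependent AUC). Efron tie handling, the
field default, is used throughout.

## Nanopore bridge

`parse_bedmethyl()` reads modkit-dialect BED9+ rows, keeps 5mCG ("m") calls,
and counts skipped 5hmC rows — the models are 5mCG-based, so
hydroxymethylation is excluded from β estimates by default.
`collapse_and_map()` pools the two strand records of each CpG (manifest `pos`
is the 1-based + strand cytosine; + strand rows start at `pos − 1`, − strand
rows at `pos`) by **summing counts** — coverage-weighted and exact — and
marks a probe missing unless pooled coverage strictly exceeds 5 (filtering
after pooling; a per-strand mode exists). Missing features are filled with
discovery-cohort probe means; the imputed fraction is carried into the
report. `report_sample()` projects, classifies, and applies the prognostic
models only when the top subtype is in the gate set with confidence strictly
above 0.5.

## Reproducibility, problem sizes, and numerical choices

* Every stochastic stage takes an explicit seed; `discovery_config(seed)`
  derives per-stage seeds from one master seed, and two runs of
  `run_discovery()` under the same config produce byte-identical artifacts
  (hash manifest included).
* M-value clipping ε = 1e-6 keeps M finite at β ∈ {0, 1}; β→M→β inverts
  exactly inside the clipping bounds.
* The packaged synthetic workflow runs at desk scale by design: 600 samples ×
  2,000 probes for discovery runs, 100 stability iterations by default
  (`stability_iters`), 400-sample validation draws. These sizes make the
  statistical properties measurable in minutes; production cohorts should
  raise the iteration count (the reference design uses 1,000) and may raise
  the suggestive threshold's stringency with cohort size.
* Boosted-model training is single-threaded for bit-reproducibility.

## Known limitations

* The embedding optimizes the published loss but is a from-scratch
  implementation; coordinates will not numerically match other
  implementations (cluster geometry, not coordinates, is the contract).
* Out-of-sample projection interpolates among training samples only.
* The generator's independence assumptions (probes independent within
  cluster, MCAR missingness) are favorable to the pipeline; violations on
  real data (correlated probes, informative missingness) are not modeled.
* EFS is generated generically (a proportional competing cause at 1.5× the
  baseline hazard); trial-specific event definitions are out of scope.
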