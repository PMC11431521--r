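---
title: "Plasma GAGome and cfDNA diagnostic scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma GAGome and cfDNA diagnostic scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients investigated for suspected lung cancer include a substantial
fraction who turn out to have benign lung disease. Liquid-biopsy assays
based on cell-free DNA (cfDNA) are specific but insensitive, especially
in early-stage disease, because many tumors shed little DNA into plasma.
Free glycosaminoglycans (GAGs) — the protein-free fraction of chondroitin
sulfate (CS), heparan sulfate (HS) and hyaluronic acid (HA) circulating
in plasma — carry an orthogonal, systemic cancer signal. This package
implements the statistical pipeline for developing and evaluating a
plasma *GAGome score*, a *cfDNA score*, and their sequential combination
for discriminating lung cancer from benign lung disease.

```{r setup}
library(gagdx)
```

## The GAGome and its feature expansion

The measured GAGome is the vector of absolute concentrations (µg/mL) of
17 disaccharides: eight CS sulfation forms (0S, 2S, 6S, 4S, 2S6S, 2S4S,
4S6S, TriS), eight HS forms (0S, 2S, 6S, NS, NS6S, NS2S, 2S6S, TriS) and
unsulfated HA. `expand_features()` derives 22 additional features, for a
complete GAGome of 39 features per sample:

* **totals** — total CS and total HS, the sum of the class's
  disaccharide concentrations (µg/mL);
* **mass fractions** — each CS/HS disaccharide as a percentage of its
  class total (µg/µg%), 16 features;
* **charges** — per class, the sulfo-count-weighted sum of the mass
  fractions divided by 100. With weights 0–3 (count of sulfo groups per
  disaccharide), the charge is a dimensionless average sulfation level
  in [0, 3];
* **ratios** — 4S CS/0S CS and 6S CS/0S CS.

The charge is computed over *mass fractions*, not absolute
concentrations: this makes it a compositional summary, dimensionless and
invariant to the overall concentration scale, consistent with its
conventional "[-]" unit notation. Features whose denominator is zero
(fractions and charge of an all-zero class, ratios with a zero 0S CS)
are marked *unavailable* (`NA`), never `NaN`, so downstream filters
behave deterministically. Measured values below the detection limit
enter derived-feature arithmetic as reported; the detectability rule
below filters *features*, not individual values.

## Detectability and feature selection

A disaccharide is considered detectable in plasma when its **median**
concentration across all samples is **strictly above 0.1 µg/mL**
(`detectable_features()`; even sample counts use the midpoint of the two
central order statistics). In free-GAG plasma data only 0S CS and 4S CS
typically clear this limit.

`select_analysis_features()` maps a detectable set to the analyzable
features. A derived feature is retained when the measured disaccharides
it genuinely depends on are all quantifiable:

* a mass fraction needs its numerator disaccharide detectable;
* a ratio needs both disaccharides detectable;
* a class total needs at least one detectable member (undetectable
  members contribute negligible mass);
* a class charge needs *every sulfated* member detectable, because each
  sulfated fraction enters with weight ≥ 1 — a charge built mostly from
  unquantifiable components would be noise.

With the detectable set {0S CS, 4S CS} this yields six analysis
features: the two concentrations, their two fractions, 4S CS/0S CS and
total CS. With all 17 detectable it yields all 39.

## The Bayesian equivalence screen

Each analysis feature is standardized (mean 0, SD 1, denominator
`n − 1`) and modelled as Gaussian with the case indicator as predictor,
optionally adjusted for experimental batch (binary) and sample age
(months) — `fit_linear_group_model()`. All coefficients and the
intercept carry a Student-t prior with 7 degrees of freedom, location 0
and scale 2; the residual SD has a half-t(3, 0, 2) prior, a standard
weakly-informative choice for a scale parameter of a standardized
response.

A feature is **credibly associated** with case–control status when

1. the 95% posterior interval of the group coefficient excludes zero,
2. at most 10% of the in-interval posterior mass lies in the region of
   practical equivalence (ROPE) [−0.1, 0.1] on the standardized-mean
   scale, and
3. the MCMC convergence gates pass.

Interval flavor: the package uses the **equal-tailed** quantile interval
by default, with endpoints taken as order statistics of the pooled
post-warmup draws — this makes the interval exactly reproducible and
directly testable against sorting, and it is invariant to permutation of
the draws. A highest-density interval is available via
`rope_spec(interval_type = "hdi")`; for the near-symmetric posteriors of
these models the two differ negligibly. The ROPE overlap is draw-based:
the fraction of draws inside the interval that also fall in the ROPE,
matching common ROPE tooling.

### Sampling and convergence gates

Models are sampled with JAGS through **rjags**, seeded per chain so
every fit is exactly reproducible. The default configuration is four
chains of 10,000 iterations with 5,000 warmup (the first 1,000 warmup
iterations are used for sampler adaptation, the remainder as burn-in),
retaining 20,000 draws. Design columns are mean-centered before
sampling; this reparameterizes only the intercept while leaving every
coefficient unchanged, and removes the intercept–slope correlation that
otherwise cripples mixing. The JAGS `glm` module is loaded when
available for its block samplers.

Every fit computes per-parameter **split R-hat** (chains halved, so
within-chain drift registers as between-chain disagreement) and a
multi-chain autocorrelation-based **effective sample size** (Geyer
initial monotone positive-sequence truncation). The gates are
R-hat < 1.01 and ESS > 1000 for every parameter; a fit that fails them
is flagged and can never be declared credible. Degenerate point-mass
draws are treated as converged (R-hat 1), so exact constants — useful in
tests — pass through. Chains stuck at different constants give R-hat
`Inf` and fail.

## The scoring models

The **GAGome score** is a Bayesian logistic regression of case status on
the absolute 0S CS concentration and the 4S CS mass fraction — the two
features that carry the cancer signal (0S CS up, 4S CS fraction down in
cases). The **cfDNA score** regresses case status on log cfDNA
concentration and the number of cfDNA variants. Both use the same
t(7, 0, 2) priors; the heavy-tailed prior keeps coefficients finite even
under complete separation. The score is the **posterior-mean linear
predictor** — the log-odds of lung cancer — which is monotone equivalent
to the posterior predictive probability for all ROC purposes.

GAGome predictors are **batch-normalized** before fitting
(`batch_normalize()`): centered within each experimental batch, then
scaled by the pooled post-centering SD. This removes additive batch
shifts exactly (adding a constant per batch leaves the output unchanged)
without estimating a batch coefficient inside the score.
`fit_logistic_score()` additionally centers and scales each predictor
and stores the constants in the model, so prediction on new data applies
the *training* normalization rather than recomputing it.

## Evaluation

* **AUC** (`roc_auc()`) is the Mann-Whitney probability — concordant
  case–control pairs, ties counted 1/2 — computed via midranks.
* **Thresholds** (`threshold_at_specificity()`): positivity is "score
  strictly above the cut-off"; the calibrated cut-off is the smallest
  control score value whose specificity meets the floor, which maximizes
  sensitivity subject to it. "Minimum X% specificity" is a floor, not a
  target.
* **Bootstrap** (`bootstrap_metrics()`): 5,000 stratified replicates
  (cases and controls resampled separately, preserving group sizes and
  prevalence), recalibrating the threshold inside each replicate;
  percentile 95% CIs. Stratification guarantees both classes in every
  replicate.
* **Combined test** (`combined_test()`): the sequential pathway budgets
  the overall false-positive allowance by calibrating the cfDNA cut-off
  at minimum 100% specificity and the GAGome cut-off at minimum 95%;
  a sample is combined-positive when either sub-test is positive, and a
  cfDNA-negative / GAGome-positive sample is flagged *reclassified
  positive*. Samples whose cfDNA was insufficient or missing are
  cfDNA-negative by definition, so the GAGome score is their only route
  to a positive call. On the calibration controls the combined false
  positives are bounded by the sum of the two budgets, hence combined
  specificity ≥ 95% there.
* **Stage strata**: sensitivity is reported for stage I, pooled II–III,
  and IV.
* **Independence check** (`feature_cfdna_correlation()`): Spearman rank
  correlation between score features and cfDNA measures — rank-based
  because concentrations are strongly right-skewed.
* **Cohort statistics** (`cohort_characteristics()`): Pearson χ² without
  continuity correction for categorical variables (missing excluded) and
  two-sample t-tests for continuous ones. The unequal-variance (Welch)
  form is the default — it reproduces the published age comparison —
  with the pooled-variance form available.

Thresholds are calibrated by resubstitution on the same cohort that is
evaluated, as is common in early biomarker studies; the reported
sensitivities are therefore optimistic. This is a property of the study
design the package reproduces, documented rather than "corrected".

## The synthetic cohort generator

No public data accompany the clinical study, so `simulate_cohort()`
generates cohorts with the same statistical skeleton, for method
validation and end-to-end testing:

* **sizes**: 85 cases (stages I/II/III/IV = 9/6/18/52) and 28 controls;
  age, sex and smoking drawn to match the published per-group marginals;
* **GAGome**: lognormal concentrations. Control medians are calibrated
  so only 0S CS (1.4 µg/mL) and 4S CS (2.2 µg/mL) exceed the 0.1 µg/mL
  detectability limit, with the other 15 disaccharides at trace level —
  4S CS is set as the dominant free plasma CS species. Cases shift
  0S CS up and 4S CS down by 0.6 log-scale SDs by default, a moderate
  effect producing single-feature AUCs near 0.65, stage-independent;
* **technical structure**: two batches (additive 0.15 log-scale shift,
  assignment independent of case status) and a small negative sample-age
  drift (−0.003/month over 6–48 months), both acting on log
  concentration — exactly the nuisance structure the adjusted screen
  removes;
* **cfDNA**: lognormal concentration (control median 6 ng/mL) with a
  case shift growing with stage (0.1/0.45/0.75/1.1 log units), and
  negative-binomial variant counts (control mean 0.3; case means
  0.6/1.8/3/5 by stage, dispersion 1.2) — reflecting that cfDNA signal
  is strongly stage-dependent while the GAGome signal is not;
* **availability masks**: 81 samples with cfDNA concentration, 74 of
  them with variant counts, 7 insufficient — assigned at random;
* **independence**: GAGome and cfDNA values are drawn from separate
  RNG substreams with no shared latent variables, so the two scores are
  genuinely orthogonal conditional on stage. Each component (covariates,
  GAGome, cfDNA, availability) has its own substream derived from the
  seed, so adding a component never perturbs another's draws, and a
  fixed seed reproduces a cohort bit-identically.

What the generator does **not** emulate: mass-spectrometric noise
(ion suppression, drift, censoring artifacts), correlations among the
trace disaccharides, histology subtypes, and any real biological
coupling between GAG metabolism and tumor DNA shedding. Passing tests on
synthetic cohorts therefore validate the *statistical machinery* —
calibration, operating characteristics, accounting — not the clinical
performance of the scores on real plasma.

## Numerical choices and degenerate inputs

* Quantiles of posterior draws are order statistics (type-1 inverse
  CDF); medians in the detectability rule use the standard midpoint
  convention.
* The detectability comparison is strict (`>` the limit), so a median
  exactly at 0.1 µg/mL is *not* detectable.
* Constant features are rejected at standardization with the feature
  named; single-class label vectors are rejected by every fit and
  evaluation function.
* `threshold_at_specificity()` returns `-Inf` only when the floor is 0;
  a 100% floor is always attainable at the maximum control score.
* Zero-variance posterior draws yield R-hat 1 and ESS equal to the draw
  count.
* All randomness (simulation, MCMC, bootstrap) is controlled by integer
  seeds; derived sub-seeds stay below 2^31.

## Simulation sizes used in the test suite

The package's operating-characteristic tests run at reduced but honest
sizes chosen to keep the suite fast while the convergence gates still
pass: two chains of 2,000–3,000 iterations (≥ 3,200 retained draws;
observed ESS comfortably above the 1,000 gate), 200 replicates for the
ROPE false-positive rate and power and for interval coverage, 300
replicates for the null-AUC check, and bootstrap sizes of 200–500 for
determinism and coverage checks. The acceptance script runs the full
study configuration (4 × 10,000 iterations, 5,000 bootstraps).

## Limitations

* The GAGome score's predictors are fixed by configuration
  (`score_features`), defaulting to the two cancer-associated features;
  the equivalence screen is reported alongside rather than feeding the
  score automatically, so a fully data-driven feature-to-score pipeline
  is a deliberate extension point.
* cfDNA AUC is computed on the subset with complete cfDNA data; the
  insufficient-cfDNA samples enter only the combined-test calls (as
  cfDNA-negative), mirroring the study's handling.
* No multiplicity correction is applied across the six screened
  features, and no cross-validation or external validation is performed
  — the evaluation design reproduces the original single-cohort
  resubstitution analysis.
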