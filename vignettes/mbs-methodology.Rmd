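---
title: "Count-based molecular prognostic scores: methodology and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-based molecular prognostic scores: methodology and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbscore)
```

## The method

`mbscore` implements a family of prognostic scores built from dichotomized
gene expression in survival cohorts, of the kind used to stratify
myelodysplastic-syndrome (MDS) patients from CD34+ cell transcriptomes. The
construction has four steps:

1. **Dichotomization.** Each candidate gene's expression $x_g$ is split at an
   optimal cutpoint $c_g$. Candidates are the midpoints between consecutive
   sorted unique values whose induced split leaves at least
   `min_group_frac` (default 10%) of patients on each side. The default
   criterion is the Youden index of the induced indicator against the event
   label, $J(c) = |\mathrm{TPR}(c) - \mathrm{FPR}(c)|$; Harrell's C of the
   indicator against the censored outcome is a selectable alternative. The
   risk direction is the side of the cutpoint whose univariate hazard ratio
   exceeds one; "low expression" always means *at or below* the cutpoint,
   so scores are exactly reproducible from a stored model file.
2. **Two-stage screening.** Stage 1 fits a univariate Cox proportional-
   hazards model per dichotomized gene. Genes with $p \le \alpha$
   (two-sided, $\alpha = 0.05$) are carried, one at a time, into stage 2: a
   Cox model adjusting for age (years, continuous), gender, and IPSS-R
   coded low (very-low + low) versus non-low. The binary IPSS-R coding
   avoids sparse-level separation in per-gene fits; the five-level version
   remains available in the data model. A gene is selected when its
   adjusted $p \le \alpha$; the boundary is inclusive, so a multivariate
   p-value printed as exactly 0.05 passes.
3. **Score assembly.** The score is the count of risk factors: one point
   for each selected gene whose risk condition holds. Tiers are frozen at
   0 = favourable, 1 = intermediate, $\ge 2$ = adverse. The published
   reference panel has five components (high ANPEP, high PKM, low ACLY,
   low PANK1, low SLC25A5); `mbs_model()` reconstructs it directly from a
   component table when screening is not wanted.
4. **Internal validation.** (a) Tier-wise Kaplan-Meier survival at 24 and
   36 months with BCa bootstrap intervals over $R = 1000$ unstratified
   resamples of the whole cohort; (b) a bootstrapped comparison of the
   score's AUC against a baseline clinical score (IPSS-R categories coded
   1-5) over $R = 10000$ resamples,
   $\Delta\mathrm{AUC} = \mathrm{AUC}_{\mathrm{MBS}} -
   \mathrm{AUC}_{\mathrm{baseline}}$; (c) a final multivariable Cox model
   of the tier indicators plus confounders, ranking covariates by Wald
   $\chi^2$.

## Statistical machinery and conventions

* **Cox fits** use Efron tie handling by default (months-scale survival
  times are often tied in real tables; Efron is the more accurate
  correction, and Efron and Breslow agree exactly when no event times are
  tied). Convergence tolerance is $10^{-12}$ so the partial-likelihood
  score vanishes at the reported coefficients to high precision. Hazard
  ratio intervals are Wald, $\exp(\hat\beta \pm z_{0.975}\,SE)$, matching
  the symmetric-on-log-scale intervals such studies print.
* **Monotone likelihoods** (e.g. a reference tier without deaths) are
  flagged per coefficient, never silently returned; the final
  multivariable model reports a finite-side 95% profile-likelihood bound
  for flagged coefficients, obtained by scanning the coefficient with the
  other terms refit at each value.
* **AUC for overall survival** is operationalized as the binary AUC
  against the observed event indicator, computed with DeLong's algorithm;
  this is the convention the C-statistic tables of such studies require.
  Patients censored before the horizon keep their observed label, a known
  limitation; Harrell's C over comparable pairs is exposed as
  `harrell_c()` for a censoring-aware alternative.
* **Survival-at-horizon intervals** use the log(-log) transform so bounds
  stay inside $[0, 1]$, consistent with the asymmetric intervals printed
  in validation tables.
* **BCa intervals.** The bias term is $z_0 = \Phi^{-1}(\#\{\hat\theta^*_r
  < \hat\theta\}/R)$ and the acceleration $a$ comes from a leave-one-out
  jackknife of the original cohort,
  $a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})$ with
  $d_i = \bar\theta_{(\cdot)} - \hat\theta_{(i)}$. Removing one patient
  only perturbs that patient's own tier curve, which keeps the jackknife
  linear in $n$. When every replicate equals the original estimate (a tier
  with no deaths anywhere) the interval degenerates to a point, giving the
  100% (100-100%) pattern expected for an event-free tier; when $z_0 = 0$
  and $a = 0$ the construction reduces exactly to the percentile interval.
  A replicate lacking a tier entirely is recorded as missing for that
  tier's cells and counted; horizons beyond a replicate's follow-up use the
  last available estimate (step-function convention), also counted.
* **Cross-tier bootstrap test.** The per-horizon Kruskal-Wallis test over
  the tier-wise replicate distributions is reported as such studies report
  it, but the replicates are resamples of one cohort, not independent
  samples, so the p-value is descriptive, not inferential.
* **Delta-AUC p-value** is the symmetric bootstrap tail probability
  $2\min(P(\Delta^* \le 0), P(\Delta^* \ge 0))$, floored at $1/R$.
* **Tier percentages** are rounded to integers with the excess absorbed by
  the largest tier so they total 100; with counts 28/60/71 of 159 this
  yields the 18/38/44 partition such studies print (plain rounding would
  give 18/38/45, summing to 101).
* **Reproducibility.** Every resampling routine takes an explicit seed and
  uses a fixed per-replicate sub-seed schedule, so results depend only on
  `(seed, R)`. The pipeline derives per-stage seeds from one top-level
  seed via `derive_seed()`.

## The synthetic-cohort generator

The generator emulates the statistical structure the pipeline assumes — it
is the package's test bed, not a microarray simulator.

* **Expression** is Gaussian per gene with unit variance on the log scale
  (default mean 7, a typical log2 intensity). The pipeline only uses
  thresholds and ranks, so heavier tails would not change any downstream
  behaviour.
* **Survival** follows proportional hazards with an exponential baseline:
  $h_i = \lambda_0 \exp(\sum_g \beta_g z_{ig} + \beta_{\mathrm{age}}
  (\mathrm{age}_i - 67) + \beta_{\mathrm{male}} + \gamma_{\mathrm{IPSSR}})$,
  where $z_{ig}$ indicates expression on the risk side of the gene's
  *population* quantile — so ground-truth cutpoints are configuration
  constants, available for recovery studies. A Weibull shape is not
  needed: the exponential is the simplest model satisfying the
  proportional-hazards assumption, which is all the pipeline uses.
* **Defaults as study conditions.** Five prognostic genes (the reference
  panel, directions as published) with $|\log \mathrm{HR}| = 0.8$ and
  risk-side prevalence 25% ($q = 0.75$ for high-risk, $0.25$ for
  low-risk): a five-component count at prevalence 0.25 implies a
  Binomial(5, 0.25) tier split of roughly 24/40/36%, close to the
  published 18/38/44 partition. The baseline hazard is 0.005/month
  (reference-patient median OS $\approx$ 139 months; with risk factors and
  confounders acting, cohort medians land in the 30-70 month range typical
  of MDS cohorts). Censoring is exponential at 0.01/month capped at a
  120-month administrative horizon, giving roughly 55-65% observed
  deaths. Age is Normal(67, 10) truncated to [19, 87] with a log-HR of
  0.03/year; gender is male with probability 102/159 and no hazard effect;
  IPSS-R categories follow the published cohort frequencies
  (27/53/44/23/12 of 159) with monotone log-HR effects
  (0, 0.25, 0.6, 1.0, 1.4).
* **What it does not emulate**: probe-level noise, batch effects,
  expression-confounder correlation (genes are independent of IPSS-R, age
  and gender), non-proportional hazards, and informative censoring.
  Passing recovery tests therefore demonstrates the pipeline's behaviour
  under its own assumptions, not robustness to their violation. In real
  cohorts prognostic expression typically *does* correlate with disease
  stage, which is why adjusted screens there prune more genes than the
  independence simulation suggests.

## The cutpoint-optimization multiplicity problem

Choosing each gene's cutpoint by maximizing an outcome-dependent criterion
and then testing the same dichotomized gene on the same data is a
maximally-selected-statistic procedure: the stage-1 test's effective type-I
error is far above its nominal $\alpha$ (a well-documented property of
optimal-cutpoint prognostic studies). The package implements the procedure
as the method defines it and makes the consequence measurable: the
acceptance suite's pipeline-recovery experiment counts, across seeded
simulations, how often the screen returns exactly the true panel with at
most one false positive. Under the study conditions the power side
(recovering all five true genes) holds, while the false-positive side does
not — null genes pass the optimized-cutpoint screen far more often than
$\alpha$ suggests, and the adjustment stage removes few of them because the
simulated confounders are independent of expression. Users who need a
calibrated screen should pre-specify cutpoints (e.g. medians or
population quantiles), for which the suite verifies the nominal level, or
apply a maximally-selected-statistic correction, which is out of scope
here. The number of univariate hits such screens report on real data (15
of 37 candidates) is consistent with this inflation.

## Problem sizes used by the test suite

The suite exercises: oracle equivalence on 50-200 random instances of
$n \le 60$; Cox recovery and calibration at $n = 2000$; pipeline recovery
over 50 seeded cohorts of $n = 500$ with 37 genes; delta-AUC coverage over
200 simulations at $n = 300$ with $R = 1000$; null calibration of the
log-rank test over 1000 replicates and of the screening stage over 30
null cohorts (>1000 gene-level tests). These sizes were chosen so each
property is measured with useful Monte-Carlo precision while the whole
suite stays comfortably runnable on one CPU.

## Known limitations

* The binary-event AUC ignores censoring times; `harrell_c()` is the
  censoring-aware alternative.
* Complete-case handling of missing confounders assumes missingness
  unrelated to outcome.
* The frozen {0, 1, $\ge 2$} tier rule presumes a multi-component model; a
  single-component model cannot reach the adverse tier (a warning is
  emitted).
* The bootstrap cross-tier p-value is descriptive (see above).
* No external-cohort validation machinery: the package validates scores
  internally only.
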