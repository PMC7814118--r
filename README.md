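# mbscore

Count-based molecular prognostic scores for survival cohorts: construction,
patient stratification, and internal validation.

## The problem

Risk stratification in myelodysplastic syndromes (MDS) rests on clinical
scores such as the Revised International Prognostic Scoring System (IPSS-R).
Gene-expression information from the disease-initiating CD34+ compartment
can refine it: dichotomize each candidate gene at an optimal expression
cutpoint, keep the genes that independently predict overall survival after
adjusting for clinical confounders, and count each patient's "molecular risk
factors". The resulting molecular-based score (MBS) — reference panel: high
*ANPEP*, high *PKM*, low *ACLY*, low *PANK1*, low *SLC25A5*, each one
point — stratifies patients into favourable (score 0), intermediate (1) and
adverse (≥ 2) tiers.

`mbscore` is for biostatisticians and computational biologists who want this
class of score as a tested, reproducible pipeline: every stage is a plain R
function, every resampling step is seeded, and a synthetic-cohort generator
with known ground truth makes the whole pipeline testable without any data
download.

## The method in brief

* **Cutpoints**: exhaustive scan over midpoints of sorted unique expression
  values (each side ≥ 10% of patients), maximizing the Youden index
  J(c) = |TPR(c) − FPR(c)| of the induced indicator against the event label
  (Harrell's C selectable); risk direction from the indicator's univariate
  hazard ratio.
* **Screening**: per gene, univariate Cox on the dichotomized indicator,
  then — for univariate hits only — one Cox model per gene adjusting for
  age, gender and IPSS-R (low vs non-low); selected when both two-sided
  p ≤ 0.05.
* **Score**: number of risk conditions met; tiers {0, 1, ≥ 2}.
* **Validation**: tier-wise Kaplan–Meier survival at 24/36 months with BCa
  bootstrap intervals (R = 1000, bias term from the replicate distribution,
  acceleration from a leave-one-out jackknife); bootstrapped
  ΔAUC = AUC_MBS − AUC_IPSS-R (R = 10000, percentile CI, symmetric tail
  p-value); final multivariable Cox model of tier indicators plus
  confounders ranked by Wald χ².

See `vignettes/mbs-methodology.Rmd` for assumptions, conventions and design
notes — including why outcome-optimized cutpoints inflate the screening
stage's effective type-I error.

## Worked example

Simulate a cohort with the statistical structure of a CD34+ MDS expression
study (159 patients, 37 candidate genes, five true prognostic genes), score
patients with the reference five-gene panel at its ground-truth cutpoints,
and validate the score:

```r
library(mbscore)

sim <- simulate_cohort(simulation_config(n_patients = 159,
                                         seed = derive_seed(7, "cohort")))
cohort <- sim$cohort
model <- mbs_model(sim$truth$prognostic[, c("gene", "cutpoint", "direction")])

assignment <- score_patients(model, cohort)
tier_percentages(table(assignment$tier))
#>   favourable intermediate      adverse
#>           26           40           34

bootstrap_km(cohort, assignment, R = 1000,
             seed = derive_seed(7, "bootstrap-km"))
#> <mbs_bootstrap> R = 1000, n = 159, seed = 1281906
#>          tier horizon original boot_mean           ci n_missing
#>    favourable      24    83.1%     83.1% (67.7-93.4%)         0
#>  intermediate      24    68.9%     69.0% (54.7-79.6%)         0
#>       adverse      24    23.8%     23.8% (13.0-39.1%)         0
#>    favourable      36    73.5%     73.7% (56.7-86.8%)         0
#>  intermediate      36    60.8%     60.9% (48.0-74.3%)         0
#>       adverse      36    11.9%     12.0%  (3.3-24.1%)         0

ipssr_num <- match(cohort$clinical$ipssr, ipssr_levels())
compare_auc_bootstrap(cohort$clinical$os_event, assignment$score, ipssr_num,
                      R = 10000, seed = derive_seed(7, "delta-auc"))
#> <mbs_auc_comparison> AUC A = 0.672, AUC B = 0.529, delta = 0.143
#>   (95% CI 0.010-0.273), P = 0.0344 (R = 10000)
```

Reading the output: the three tiers split the cohort roughly 26/40/34% and
their bootstrap 3-year overall survival is ordered 74% / 61% / 12%; the
count score's AUC for death (0.672) beats the IPSS-R categories (0.529) by
ΔAUC = 0.143, with a bootstrap CI excluding zero (P = 0.034).

To fit a score from data instead of using a known panel, run the screening
path (`optimal_cutpoint()` per gene → `screen_genes()` → `build_mbs()` →
`score_patients()`), or let `run_all(run_config(...))` sequence everything
and write the tables (cutpoints, Table-2-style screening, scores, tier
survival, bootstrap validation, AUC comparison, multivariable model) plus a
seed-and-hash manifest into an output directory. A thin command-line front
end with `simulate` / `cutpoints` / `screen` / `build` / `score` /
`validate` / `run-all` subcommands is installed at `inst/cli/mbs.R`.

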