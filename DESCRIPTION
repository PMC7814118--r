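Package: mbscore
Title: Molecular-Based Prognostic Scoring from Dichotomized Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and internal validation of count-based molecular
    prognostic scores from normalized gene-expression and right-censored
    survival data. Implements optimal-cutpoint dichotomization of candidate
    genes, two-stage Cox proportional-hazards screening against clinical
    confounders (age, gender, IPSS-R), assembly of a molecular-based score
    (MBS) with favourable / intermediate / adverse risk tiers, and the
    resampling machinery used to validate such scores internally: BCa
    bootstrap intervals for tier-wise Kaplan-Meier survival at fixed horizons
    and a bootstrapped delta-AUC comparison against a baseline clinical score.
    A synthetic-cohort generator emulates the statistical structure of a
    CD34+ myelodysplastic-syndrome expression cohort so that every pipeline
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    pROC,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
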