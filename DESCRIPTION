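Package: pembropsm
Title: Partitioned-Survival Cost-Effectiveness Model of First-Line
    Pembrolizumab Plus Chemotherapy in Advanced Oesophageal Squamous
    Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressive disease, death)
    partitioned-survival cohort model for the cost-effectiveness of
    pembrolizumab plus cisplatin/5-fluorouracil versus chemotherapy alone
    as first-line treatment of advanced oesophageal squamous cell
    carcinoma with PD-L1 CPS >= 10, from the Chinese payer perspective.
    Provides parametric survival laws (log-logistic and five comparator
    families) with maximum-likelihood fitting to right-censored data and
    AIC/BIC model selection, a synthetic Kaplan-Meier generator for
    end-to-end testing of the fitting stage, per-cycle drug, adverse-event
    and follow-up costing with treatment-cycle caps, discounted QALY and
    life-year accrual with optional half-cycle correction, base-case
    incremental cost-effectiveness ratios, one-way (tornado) and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and price and treatment-duration threshold
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    ggplot2,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
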