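Package: lycodose
Title: Bayesian Model-Averaging CRM Dose Finding with Docetaxel
    Pharmacokinetics and Correlative Biomarker Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for conducting and evaluating a phase I dose-finding
    study of daily oral lycopene combined with 3-weekly docetaxel in
    metastatic prostate cancer. Implements the Bayesian model-averaging
    continual reassessment method (BMA-CRM) with deterministic quadrature
    posteriors, per-patient escalation replay, trial simulation and
    operating characteristics; non-compartmental pharmacokinetic analysis
    (Cmax, trapezoidal AUC, terminal slope, extrapolated AUC) with paired
    geometric-mean-ratio estimation; the trial's correlative statistics
    (baseline fold change, ligand-dependent IGF-1R phosphorylation ratio,
    exact Wilcoxon signed-rank, one-sided paired t, PSA response); and
    seeded synthetic-data generators so every stage is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
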