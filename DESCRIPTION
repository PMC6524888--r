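Package: vtecea
Title: Lifetime Markov Cohort Cost-Effectiveness Model of Extended
    Anticoagulation for Venous Thromboembolism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A state-transition (Markov) cohort model of extended oral
    anticoagulant treatment versus no extended treatment after venous
    thromboembolism (VTE). Patients move among twelve health states
    (recurrent deep venous thrombosis or pulmonary embolism, VTE-related
    death, major and clinically relevant nonmajor bleeding, intracranial
    bleed, chronic thromboembolic pulmonary hypertension, treatment
    discontinuation, background death and event-free on/off treatment) in
    three-month cycles over a lifetime horizon. The package provides the
    probability/rate conversion calculus (period-basis rescaling, hazard
    ratios, age adjustment of bleeding risks, piecewise-constant hazards
    from cumulative-incidence curves), discounted cost and QALY accounting
    from societal or payer perspective, incremental cost-effectiveness
    ratios, probabilistic and univariate sensitivity analysis with
    cost-effectiveness acceptability curves, scenario analyses, a trial
    validation harness, a censored interval-risk estimator, and synthetic
    fixtures (Gompertz-Makeham life table and a patient-level
    microsimulation oracle) so the full analysis runs without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
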