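Package: wardforge
Title: Reconfigurable Processing Pipelines for Smart-Ward Patient Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A constructor kernel for smart-ward patient assessment: declarative
    processing patterns (threshold logic, trend analysis, signal features,
    machine-learning inference) are assembled into validated directed-acyclic
    pipelines that turn heterogeneous vital-sign streams into complex
    indicators. Indicators are evaluated against per-patient dynamic baselines
    (rolling or exponentially weighted mean and standard deviation) rather than
    fixed population thresholds. The package ships a Monte-Carlo virtual-patient
    simulator with paroxysmal sympathetic hyperactivity episodes, motion
    artifacts, missingness and physiological noise; scoring-table calculators
    for standard clinical scales; a compact reference recurrent (LSTM)
    classifier; and a benchmarking harness comparing manual, automated and
    complex-feature assessment policies with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
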