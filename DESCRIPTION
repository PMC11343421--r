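Package: hfcea
Title: Markov Cohort Cost-Utility Model for Add-On SGLT2 Inhibition in
    Heart Failure with Ejection Fraction Above 40 Percent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition engine for cost-utility analysis
    of empagliflozin added to standard of care in heart failure with preserved
    or mildly reduced ejection fraction, from the Malaysian healthcare payer
    perspective. Health states are Kansas City Cardiomyopathy Questionnaire
    clinical summary score quartiles; the engine supports parametric survival
    extrapolation over six families, life-table blending of background non-CV
    mortality, treatment discontinuation, transient events (heart-failure
    hospitalisation, adverse events), half-cycle correction, discounting,
    deterministic and probabilistic sensitivity analysis, cost-effectiveness
    acceptability curves, and phenotype-weighted pooling of results. A
    synthetic-parameter generator calibrated to published event-rate targets
    makes every component testable without trial-level inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
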