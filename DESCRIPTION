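Package: aecrisk
Title: Adverse-Event Incidence Estimation Under Competing Risks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to describe the occurrence of adverse events (AEs) over time
    in single-arm trials where a non-fatal efficacy event (e.g. relapse)
    competes with the AE. Implements the standard crude estimators (crude
    proportion, epidemiological rate, overall Kaplan-Meier, cause-specific
    hazard, Aalen-Johansen crude incidence, Nelson-Aalen cumulative hazard,
    naive Kaplan-Meier incidence) together with potential-incidence estimators
    that relax the independence assumption between the latent AE and relapse
    times through covariate adjustment: stratified or Cox-model weighted
    average survival, and inverse probability of censoring weighting (IPCW).
    Includes the closed-form potential quantities of the covariate-conditional
    exponential generative model, a simulator for that model, and a
    replication engine that quantifies estimator bias over Monte Carlo
    replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    graphics,
    stats,
    utils
Suggests:
    cmprsk,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
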