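Package: searchddm
Title: Drift-Diffusion Modeling of Memory-Guided Visual Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of dual-color visual
    working-memory guided search experiments. Provides a factorial trial
    generator with constrained memory-hue sampling, a discrete-time
    two-boundary drift-diffusion simulator with restart-on-timeout and a
    bounded-attempts failure mode, Multiple-Item-Template (MIT) and
    Single-Item-Template (SIT) drift-rate schedules, rank-ordered
    residual-sum-of-squares model fitting with common random numbers,
    inverse-Gaussian response-time distribution analysis, default (JZS)
    Bayes-factor paired t-tests, and a seeded end-to-end pipeline from
    trial generation to model comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
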