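Package: bayesstab
Title: Hierarchical Bayesian Modelling of Biopharmaceutical Stability Data
Version: 0.1.0
Authors@R:
    person("Stability", "Modelling Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling potency stability of multivalent
    biologic drug products stored at several temperatures. Provides a
    long-format data container with validated CSV input/output, a
    synthetic-cohort generator emulating multivalent vaccine stability
    studies, a fully conjugate Gibbs sampler for a three-layer
    (batch / molecular type / container) hierarchical Bayesian linear
    degradation model, posterior predictive and credible intervals,
    shelf-life estimation against a lower specification limit, per-batch
    linear and mixed-effects comparator models, and a simulation harness
    measuring empirical interval coverage and mean squared error under
    varying training-set sizes and time windows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
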