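Package: hdtvpp
Title: Value-Plus-Perseveration Modelling of the Hungry Donkey Task with
    Intake and Weight-Status Path Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying decision-making processes in children's
    choice behaviour on the Hungry Donkey Task (a child-friendly Iowa
    Gambling Task) and their downstream relations to laboratory energy
    intake and weight status.  Implements the task's four-door payoff
    environment, the Value-Plus-Perseveration (VPP) reinforcement-learning
    model (simulation, sequence likelihood, per-subject maximum a
    posteriori fitting, and parameter-recovery experiments), classical
    behavioural metrics (netscore, win-stay, lose-shift), nonparametric
    association statistics with Benjamini-Hochberg adjustment, synthetic
    cohort generation calibrated to published parameter distributions, and
    recursive path models with product-of-coefficients indirect effects,
    moderation probing, bootstrap uncertainty, and covariance-based fit
    indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
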