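Package: envchoice
Title: Choice Between Reward Environments: Task Simulation, Decision Models, and Neural Pattern Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying decisions between "environments" (bundles of
    twenty probabilistic items) and single items. Generates the two-stage
    choice task, simulates agents with known parameters, fits and compares a
    zoo of decision-value models (a convolutional network over item
    probability distributions, a dense network for item choice, simplified
    moment-input networks, an autoencoder, a logistic decision-value GLM,
    mean-variance-skewness, power-law, and cumulative prospect theory
    models) by 20-fold cross-validated likelihood, decomposes the network's
    decision value into per-detector partial values, and provides
    representational similarity analysis with permutation inference plus ROI
    beta time-course, leave-one-subject-out peak, PPI, and JZS Bayes factor
    procedures exercised on synthetic BOLD-like data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
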