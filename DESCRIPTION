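Package: fermpc
Title: Soft-Sensor Identification and Metaheuristic Model Predictive Control
    for Fed-Batch Fermentation
Version: 0.1.0
Authors@R:
    person("fermpc", "maintainers", email = "fermpc@example.org",
           role = c("aut", "cre"))
Description: Tools for inferential sensing and non-linear model predictive
    control (NMPC) of product concentration in fed-batch l-Lysine
    fermentation.  Implements least-squares support vector machine (LSSVM)
    regression with a radial basis function kernel, trained by a single
    dense Karush-Kuhn-Tucker linear solve; Grey-Wolf Optimization (GWO) and
    a global-best Particle Swarm Optimization (PSO) baseline for
    bound-constrained minimization; a GWO-tuned soft-sensor identification
    pipeline with batch-wise cross-validation; a receding-horizon NMPC with
    additive output-feedback bias correction; and a synthetic fed-batch
    plant simulator (Monod-logistic growth with Luedeking-Piret product
    formation) that emulates a 72-hour batch protocol sampled every 15
    minutes, for desk-scale identification and closed-loop experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
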