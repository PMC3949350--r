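Package: behaviorcp
Title: Choice Probability Analysis of Ongoing Behavior in Duration Categorization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies how much ongoing body movement predicts perceptual
    reports in rodent duration-categorization (temporal bisection style)
    tasks. Provides a synthetic-session generator with a drifting latent
    choice bias coupled to head trajectories, a video head-tracking stage
    (background subtraction, blob segmentation, principal-axis head tip,
    port-axis projection), per-session logistic psychometrics, pairwise
    trajectory-reproducibility analysis, instantaneous choice probability
    (rectified auROC with a shuffle null), trajectory-level choice
    probability via choice-variance-weighted Gaussian mixture likelihoods
    and Bayes inversion with equal-count binning, and a four-model
    trial-history logistic GLM comparison with stepwise BIC refinement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    zoo,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
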