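Package: ddtraj
Title: Adjusting-Amount Delay Discounting and Neural Ensemble Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the within-session adjusting-amount
    delay discounting task and of peri-choice neural ensemble activity.
    Provides a softmax agent simulator of the task (adjusting immediate
    amount, forced-trial rule, session termination), discounting and
    strategy metrics (indifference points, hyperbolic discount-rate
    fitting, normalized area under the curve, extra-sum-of-squares curve
    comparison, consecutive-choice run-length distributions with gamma
    fits, rank-transformed latency contrasts), segmentation of choice
    sequences into runs with Change / Fail-to-Change outcomes, peri-event
    spike binning, smoothing and z-scoring with per-timepoint
    FDR-corrected tests, principal-component state-space trajectories
    with diagonal Euclidean distance analysis between the third and
    fourth trials of runs, and seeded synthetic behavioral and spike data
    generators so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
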