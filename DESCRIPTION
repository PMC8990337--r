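Package: popmodes
Title: Activity-Mode Decomposition and Latency Analysis for Trial-Aligned Spike Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing neural population dynamics in delayed-response
    tasks: decomposition of trial-aligned spiking activity into behaviourally
    interpretable modes (delay and response coding directions, go-cue,
    ramping and stimulation directions) via difference vectors and
    Gram-Schmidt orthogonalization; two-step Poisson latency detection for
    single neurons, threshold-crossing latencies for population projections
    and brain areas; hierarchical (animal/session/trial) bootstrap inference;
    ROC decoding of single-trial projections; movement-onset detection from
    high-speed kinematic traces; and an inhomogeneous-Poisson trial simulator
    with planted ground truth for end-to-end recovery testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
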