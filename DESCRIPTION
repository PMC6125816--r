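Package: stopnet
Title: Stop-Signal Task Activity, Connectivity, and Behavioral Prediction on Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for stop-signal/no-go (SNG)
    task fMRI studies of inhibitory control across the adult life span.
    Generates synthetic cohorts with known ground truth (race-model
    behavior with staircase-tracked stop-signal delays, head-motion traces,
    and BOLD-like multi-subject data carrying spatial components with
    evoked responses and condition-dependent coupling), estimates
    stop-signal reaction times by the block-based integration method,
    extracts group components by temporal-concatenation ICA with
    minimum-description-length order selection and stability clustering,
    quantifies component responsivity and both context-independent and
    context-dependent (correlational psychophysiological interaction)
    connectivity, and predicts individual stopping latency with
    shrinkage-regularized regression inside a permutation-based k-fold
    cross-validation framework, including age-moderation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
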