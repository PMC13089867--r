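Package: affordrsa
Title: Simulation and Representational Similarity Analysis of Action
    Affordances in Conceptual Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a number-line state-action task
    in which four states afford different signed numerical operations.
    Provides the repeating state-action graph and trial-schedule generators
    with serial counterbalancing and inter-stimulus-interval constraints;
    hypothesis dissimilarity matrices (shared-affordance, action-magnitude,
    link-distance, reaction-time and gaze models); a synthetic-participant
    generator producing BOLD runs, binocular gaze streams and probe-trial
    behaviour with known ground truth; first-level GLM beta extraction;
    cross-validated Mahalanobis (crossnobis) distance estimation with
    shrinkage noise covariance, reliability-based voxel selection and noise
    ceilings; tie-corrected Spearman and recursive partial rank correlation
    with Fisher-z group inference; and a gaze-lateralization pipeline with
    blink scrubbing, condition median timecourses and cluster-based
    sign-flip permutation testing. All user-facing functions take and
    return tidy data structures.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
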