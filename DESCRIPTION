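Package: illusim
Title: Simulation and Inference for Staircase Measurement of Face Size Illusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-alternative forced-choice psychophysical experiments
    that measure the point of subjective equality (PSE) with interleaved
    1-up/1-down staircases, and analyses the resulting PSE tables with the
    full inferential chain used in face-illusion research: two-way
    fully-within-subject ANOVA with Greenhouse-Geisser, Huynh-Feldt and
    Lecoutre-corrected sphericity epsilons, partial eta squared, and default
    g-prior Bayes factors for main effects and the interaction. Includes a
    configurable observer population model (lapse-mixed cumulative-Gaussian
    psychometric functions with subject-level random effects), experiment
    presets shaped like yaw- and pitch-rotation eyeshadow-illusion studies,
    and parameter-recovery tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
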