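Package: gazevis
Title: Gaze-Direction Visibility Experiments: Stimuli, Schedules, Simulation
    and Mixed-Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative psychophysics of eye-gaze perception.
    Renders parametric human-like and chimpanzee-like eye stimuli with
    iris/sclera/eyeball region masks, applies contrast-polarity reversal
    (CIELAB lightness inversion with chromaticity preserved) and joint
    size-and-brightness degradation levels simulating distancing and shading,
    and measures region-of-interest colorimetry (CIELAB means, iris-sclera
    delta-E, eye-shape metrics). Generates constraint-satisfying pseudorandom
    trial schedules for a three-direction keypress task and a three-item
    visual-search task, with adaptive level increments and training-stage
    criteria. Simulates trial-level correct/incorrect responses from a
    generative logistic observer with crossed random effects, and analyses
    them with binomial generalized linear mixed models: likelihood-ratio
    tests, interaction pruning, Bonferroni-corrected simple effects,
    dispersion checks and nonparametric bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    png,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
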