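Package: proscribe
Title: Proscriptive Population-Code Model of Depth-Cue Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates robust integration of binocular-disparity and texture
    cues to surface slant with a population-code model in which incongruent
    ("what not") combination units are read out with suppressive weights.
    Provides the maximum-likelihood cue-combination baseline, a simplified
    divisive-normalization comparator, in-silico suppression and
    stimulation (tDCS-style) perturbation experiments, a mutual-inhibition
    and adaptation extension for perceptual rivalry, psychometric-function
    fitting and two-interval forced-choice observer simulation, robust
    correlation and outlier-screening utilities, and a synthetic-cohort
    generator for end-to-end parameter-recovery studies.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
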