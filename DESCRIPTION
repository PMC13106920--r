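Package: songrhythm
Title: Rhythmic Ontogeny Analysis of Phrase-Structured Animal Song
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for categorical-rhythm analysis of annotated animal song,
    built around the inter-onset-interval ratio statistic r_k = t_k/(t_k +
    t_k+1). Reads Praat TextGrid note annotations or flat onset tables,
    computes inter-onset intervals with a meter-perception cap, classifies
    ratios into on- and off-integer ranges around the small-integer ratios
    1:2, 1:1 and 2:1, tests peak significance with offset Poisson mixed
    models and Tukey-adjusted contrasts, quantifies width-weighted rhythmic
    regularity with beta mixed models, locates kernel-density peaks of
    interval and ratio distributions, and renders density and ternary
    figures. Includes a phrase-structured synthetic song generator with
    age- and sex-class presets so the full pipeline is testable without
    field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmmTMB,
    emmeans,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
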