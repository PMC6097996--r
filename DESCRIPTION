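Package: beatcat
Title: Computerised Adaptive Testing for Beat Alignment Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An item-response-theory engine for adaptive beat alignment
    testing. Items are two-alternative forced-choice trials in which a
    listener judges which of two versions of a musical excerpt carries a
    beep track aligned with the beat; the lure's beeps are displaced by a
    fixed fraction of a beat. The package generates item banks
    automatically from structural stimulus features, predicts item
    difficulty from an explanatory item response model, runs adaptive
    test sessions with Bayes modal interim scoring and weighted
    likelihood final scoring, calibrates the constrained
    three-parameter-logistic and explanatory models on new response data
    by marginal maximum likelihood, provides item-fit and dimensionality
    diagnostics (Yen's Q1, two- and three-way margins, modified parallel
    analysis), derives consensus beat annotations from tapping
    recordings, renders beep-track stimuli, and simulates virtual-cohort
    experiments to estimate standard-error and test-retest reliability
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
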