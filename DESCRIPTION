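Package: emoroc
Title: Metacognition of Emotional Valence and Arousal from Type-2 ROC Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures metacognitive sensitivity for the valence and arousal
    dimensions of emotional experience from trial-level rating data.
    Continuous 0-100 emotion ratings are scored correct or incorrect against
    four normative standards (the participant's own estimate of what others
    feel, affective-database norms, and sample averages of both) using a
    participant-based interval rule of mean plus or minus 0.675 times the
    standard deviation of the rating-norm differences; confidence ratings are
    then swept over a fixed criterion grid to build type-2 ROC curves and
    compute AUROC2. For two-alternative forced-choice designs the package
    computes d-prime, maximum-likelihood meta-d-prime and the M-ratio.
    Test-retest reliability is assessed with ICC(3,1), Bland-Altman limits of
    agreement, correlations and paired comparisons, and an exact
    bivariate-normal power utility for correlations is included. A generative
    simulator with controllable first-order and metacognitive noise makes the
    full pipeline testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
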