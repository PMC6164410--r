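Package: phytovolt
Title: Classification of Chemical Stimuli from Plant Electrical Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies chemical stimuli (NaCl, H2SO4, ozone) from whole-duration
    plant electrical-signal recordings. Whole-series curve-fit coefficients
    (polynomial, Gaussian, Fourier, exponential models) serve as feature vectors;
    five discriminant classifiers (LDA, QDA, their diagonal naive-Bayes variants,
    and a Mahalanobis-distance rule) are implemented from first principles and
    evaluated by leave-one-out cross-validation with confusion-matrix measures.
    A one-versus-one decision tree combines the best per-pair feature-classifier
    combinations into a three-class predictor, and a seeded simulator generates
    class-conditional post-stimulus signals so the full pipeline is testable
    without proprietary recordings.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
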