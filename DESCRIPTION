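Package: arirt
Title: Auto-Regressive Item Response Theory Models for Binary Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits two-parameter logistic (2PL) item response models extended
    with auto-regressive lag effects, in which the response to an item is
    predicted by the responses to the preceding item(s) in administration
    order, over and beyond the latent trait. Supports fixed, item-specific
    (variable), and sparse lag structures of any order, full-information
    marginal maximum-likelihood estimation with Gauss-Hermite quadrature,
    expected a posteriori (EAP) person scoring with posterior standard
    deviations, conditional item response and information functions,
    likelihood-ratio and Wald tests, information criteria, item-parameter
    comparison summaries with BCa bootstrap intervals, and a Monte-Carlo
    simulation harness for type-I error, power, and parameter recovery.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
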