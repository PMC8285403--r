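Package: cardiomr
Title: Two-Sample Mendelian Randomization for Cardioembolic Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-sample Mendelian randomization
    from GWAS summary statistics: instrument selection (genome-wide significance
    filter, greedy LD pruning, proxy substitution), allele harmonization with
    palindromic-variant policies, causal estimation (inverse-variance weighted,
    MR-Egger, weighted and simple median with parametric-bootstrap standard
    errors), leave-one-out and pleiotropy sensitivity analyses, instrument
    strength and power diagnostics, and multiple-testing classification of
    associations. Ships a synthetic summary-statistics generator with known
    ground truth (configurable pleiotropy, LD blocks, palindromic and
    strand-swapped encodings) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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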