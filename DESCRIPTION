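Package: raschval
Title: Rating-Scale Rasch Validation of Short Likert Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-step Rasch validation pipeline for short polytomous
    Likert-scale questionnaires such as safety-climate screening tools.
    Fits the Andrich rating-scale model by joint maximum likelihood,
    then screens rating-scale category functioning, local independence,
    item and person goodness-of-fit (infit/outfit mean squares with
    iterative removal of misfitting items), unidimensionality via
    principal component analysis of standardized residuals, person
    separation and reliability, and Mantel chi-square differential item
    functioning across respondent background factors. Includes a
    benchmarking mean-value index, Wright-map targeting summaries,
    category probability curves, and a synthetic-data generator with
    controlled model violations for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
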