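Package: mosaicabc
Title: Inferring Meiotic and Mitotic Error Rates in Human Embryos from
    PGT-A Biopsy Data by Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates chromosomally mosaic blastocyst-stage embryos under
    meiotic and mitotic error rates, takes spatially contiguous in-silico
    trophectoderm biopsies, and infers the joint posterior of the two error
    rates from published preimplantation genetic testing for aneuploidy
    (PGT-A) biopsy-class proportions using adaptive population Monte Carlo
    approximate Bayesian computation. Posterior-predictive tools
    characterise whole-embryo karyotype composition, biopsy-to-embryo
    correspondence, and two-biopsy concordance, and sensitivity analyses
    quantify robustness to mosaic-biopsy misclassification across multiple
    published datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
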