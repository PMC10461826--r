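Package: gpstest
Title: Detect Shared Genetic Architecture from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonparametric detection of shared genetic architecture between
    two traits from genome-wide association study (GWAS) summary-statistic
    p-values. Implements the genome-wide pairwise-association signal sharing
    (GPS) test with a permutation-calibrated generalised extreme value null
    distribution (GPS-GEV) alongside the legacy transformed-exponential null
    (GPS-Exp), three interchangeable fast bivariate empirical-CDF backends,
    Hoeffding's test of bivariate independence as a comparator, an estimator
    of the effect-estimate correlation induced by case/control sample overlap
    between studies, and a synthetic paired-GWAS generator for type-1-error
    and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    goftest,
    jsonlite,
    optparse
Config/testthat/edition: 3
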