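Package: pedvar
Title: Variance-Component Analysis of Extended Twin-Family Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the extended twin-pedigree analysis of quantitative
    traits such as the Type D (distressed) personality proxy and its
    negative-affectivity and social-inhibition subscales.  Builds additive
    (2*kinship), dominance (fraternity) and shared-household relationship
    matrices from pedigree tables with monozygotic-twin groups; fits
    univariate and bivariate A/D/H/E variance-component models by maximum
    likelihood with age and sex as fixed effects; estimates familial Pearson
    and tetrachoric correlations with bootstrap confidence intervals; scores
    the 12-item ASEBA-based Type D proxy with the published imputation and
    survey-selection rules; and simulates NTR-like extended families with a
    known genetic architecture for validation studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    mvtnorm,
    numDeriv,
    jsonlite,
    yaml,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
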