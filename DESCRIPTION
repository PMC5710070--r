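Package: rrfi
Title: Random-Regression Models for Residual Feed Intake and Feed-Efficiency Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic analysis of feed efficiency in growing pigs with random-regression
    animal models that decompose feed intake into animal-specific use of feed for
    maintenance (metabolic weight), growth and backfat deposition, plus an unspecific
    residual-feed-intake intercept. Provides pedigree relationship matrices and their
    sparse inverses, weekly phenotype preparation from daily intake and measurement
    events (Legendre trajectory imputation, within-cell standardization, filtering),
    eight nested model specifications, a Gibbs sampler and EM-REML for variance
    components with DIC model comparison and posterior summaries (HPD, ESS), derived
    genetic parameters (heritabilities, slope variance ratios, conditional heritability
    along a covariate), a stochastic breeding-program simulator for comparing selection
    indexes on feed-efficiency components, and a synthetic-data generator with known
    true parameters for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
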