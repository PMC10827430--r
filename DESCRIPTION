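Package: profwise
Title: Profile-Wise Likelihood Analysis for Mechanistic Models with
    Measurement Error Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous maximum-likelihood estimation of mechanistic-model
    and measurement-error parameters for ODE and PDE models under additive
    Gaussian, multiplicative lognormal, and Poisson error models.  Provides
    univariate profile likelihoods for practical-identifiability analysis,
    chi-square-calibrated confidence intervals, profile-wise confidence sets
    for model solutions and for noisy data realizations (MLE-based and
    Bonferroni-corrected), a full-likelihood grid region as a gold-standard
    baseline, and Monte-Carlo machinery to evaluate curvewise and pointwise
    coverage of all of these sets under repeated sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    lhs,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
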