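Package: maternmanifold
Title: Matern Gaussian Processes on Compact Manifolds via Spectral Expansions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian processes with Matern and squared-exponential
    covariograms on the circle and the 2-sphere, built from spectral
    expansions in the eigenfunctions of the Laplace-Beltrami operator.
    Provides spectral densities with numerically certified normalizing
    constants, pointwise covariogram evaluation (truncated series with
    tail acceleration, plus the closed form for the exponential kernel on
    the circle), truncation-error bounds with positive-definiteness
    certification, equivalence decisions for pairs of Gaussian measures
    together with their microergodic parameters, exact field simulation,
    profile maximum-likelihood estimation of the variance under a
    misspecified decay parameter, best linear unbiased prediction under
    model misspecification, and reproducible experiment drivers for
    consistency, asymptotic-normality, prediction-optimality and
    truncation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
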