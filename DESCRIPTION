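Package: plband
Title: Profile Likelihood Pointwise Confidence Bands for Nonlinear
    Dose-Response Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes profile-likelihood-based pointwise confidence
    intervals for the expected response over an entire 4-parameter
    logistic dose-response curve fitted to grouped binomial data, as
    used in dose-finding trials. The curve is reparameterized so the
    expected response at each grid dose becomes a model parameter, and
    its likelihood-ratio confidence limits are found by bisection with
    a dose-ordered calculation that propagates monotone brackets and
    warm starts, falling back to a coarse-then-fine outward search when
    the expected response is near the probability boundary. Delta-method
    Wald and stratified nonparametric percentile bootstrap intervals are
    provided as comparators, together with a coverage simulation study
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    MASS
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
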