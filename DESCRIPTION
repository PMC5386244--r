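Package: polydens
Title: Polynomial Probability Density Estimation by the Method of Moments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates an N-th degree polynomial approximation to a known or
    unknown probability density from its first N+1 raw moments by solving the
    associated Hankel (Hilbert, on the unit interval) linear system, with
    positivity checking, normalization and Kolmogorov-Smirnov goodness of fit.
    Includes Gram-Charlier type A and Edgeworth series for comparison, exact
    piecewise-polynomial convolution of compactly supported polynomial
    densities, an exact big-integer Hilbert inverse and rational fallback
    solver for the ill-conditioned moment systems, and an application to the
    Smoluchowski coagulation equation in which a particle size distribution is
    reconstructed from closed-form truncated moments with power-law removal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    generics,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
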