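Package: abxdyn
Title: Dynamics of Antibacterial Drug Discovery and Resistance Emergence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the historical dynamics of antibacterial drug classes:
    a censoring-aware exponential model of the time from discovery of a
    class to first detection of clinical resistance (its clinical
    "half-life"), a coupon-collector model of class discovery in which
    draws from a finite pool of k classes arrive at a constant rate n
    after a lag phase, and the derived curve of classes whose resistance
    has not yet been detected, U(t) = D(t) - R(t).  Fits are Poisson
    maximum likelihood on yearly count data or closed-form censored
    exponential maximum likelihood, with percentile-bootstrap confidence
    intervals.  Includes a seeded generative simulator of class timelines
    so every fitting stage can be exercised and validated by parameter
    recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    survival,
    yaml
Config/testthat/edition: 3
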