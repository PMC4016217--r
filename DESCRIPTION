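Package: habvalue
Title: Time-Averaged Reproductive Output of Breeding Habitats for Itinerant Colonial Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for valuing breeding habitats of itinerant colonial breeders
    from site-by-year presence-absence surveys, colony sizes and per-colony
    reproductive success. Computes per-substrate occupancy, cessation-of-use
    and colonization rates with exact binomial confidence intervals, fits
    binomial and Gaussian mixed models with variance-partition effect sizes,
    fits censored Weibull accelerated-failure-time models of colony longevity
    by explicit maximum likelihood, and combines colony size, reproductive
    success and occupancy into a time-averaged chick-production index per
    habitat substrate with propagated standard deviations. Includes a
    two-state Markov metapopulation simulator for end-to-end validation and
    parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
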