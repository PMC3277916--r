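Package: permtail
Title: Tail-Based Estimation of Small Permutation-Test P-Values
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates permutation-test P-values from a limited number of
    permutation values. When fewer than ten permutation values exceed the
    observed test statistic, the empirical estimator is unreliable (its floor
    is 1/N), so the upper tail of the permutation distribution is modelled as
    a generalized Pareto distribution fitted to threshold exceedances by
    probability weighted moments, maximum likelihood or the method of moments,
    gated by an Anderson-Darling goodness-of-fit test. Includes bootstrap
    percentile confidence intervals, heuristic convergence diagnostics, an
    optimal order-preserving power transform, readers and writers for
    column-per-event permutation-value tables, synthetic null generators with
    closed-form tail probabilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
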