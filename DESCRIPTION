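Package: popchaos
Title: Nonlinear Dynamics and Resilience Analysis for Stressed
    Age-Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to detect reduced resilience in age-structured
    populations under sustained (press) chemical disturbance. Provides an
    individual-based, food-limited simulator of a Daphnia-like population
    exposed to a reproduction-inhibiting toxicant, nonlinear time-series
    characterisation of the resulting daily abundance series (time-delay
    embedding, recurrence plots, Poincare sections, maximal Lyapunov
    exponents via the Kantz stretching-curve algorithm with an independent
    Benettin tangent-map oracle), and paired Wilcoxon signed-rank inference
    over Monte-Carlo ensembles of Lyapunov exponents to locate the lowest
    disturbance level that significantly alters population dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
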