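Package: sprteffort
Title: Speed, Effort and Accuracy Trade-Offs in Sequential Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the three-way trade-off between decision
    speed, effort per-unit-time and accuracy in binary sequential
    decision-making. Implements a sequential probability ratio test whose
    evidence stream is corrupted by effort-dependent perceptual error, a
    hyperbolic effort-cost model, exact absorption oracles (gambler's-ruin
    closed form and dynamic programming) for the induced bounded random
    walk, fitness-landscape evaluation over a discrete grid of threshold
    and effort parameters, and comparisons between decision-makers that
    can and cannot modulate their effort level as the cost of time
    changes. All simulation results are reproducible from a single seed
    and can be exported as tab-delimited tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
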