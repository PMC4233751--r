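Package: clonedist
Title: Time-Independent Clone Size and Mutant Count Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact, size-indexed (time-independent) distributions for clonal
    dynamics in proliferating cell populations. Models the progenitor versus
    differentiated cell composition of a clone as an embedded Markov jump
    chain whose law is governed by weighted Motzkin lattice paths, giving the
    distribution of proliferating cells at a given clone size, gambler's-ruin
    probabilities of full differentiation, and a ratio estimator of the
    division-fate probabilities from observed counts of small fully
    differentiated clones. For growing colonies it provides exact
    Luria-Delbruck-type mutant count distributions indexed by colony size
    (neutral and with mutant selection), together with the mutation frequency
    spectrum, clone counts, clone sizes and mutations-per-clone of the
    subclonal structure, plus stochastic simulators used as oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
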