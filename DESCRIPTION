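Package: maxerlb
Title: Max Erlang Binomial Lifetime Distributions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Density, distribution function, quantile function, moments and
    random generation for the Max Erlang Binomial (MaxErlB) lifetime
    distribution: the maximum of a zero-truncated-binomial number of
    independent Erlang lifetimes, a parallel-system model in which the number
    of working components is random.  Includes the general max-compound
    construction over zero-truncated power-series count families, a seeded
    rejection-based simulator, a Pearson chi-square concordance test against a
    fully specified MaxErlB model, an EM algorithm (with the latent component
    count as the missing datum) for estimating the Erlang rate and the
    binomial success probability, a direct numerical maximum-likelihood
    cross-check, and a bundled bladder-cancer remission-time dataset of 128
    patients.  Fitted objects support broom-style tidy() and glance() and
    ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
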