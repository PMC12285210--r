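Package: sadfit
Title: Compound Abundance Distribution Models and Diversity Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits compound species abundance distribution models to integer
    count inventories and extrapolates species richness from the fitted zero
    class. Implements the compound exponential-geometric series (CEGS) model
    (latent Weibull-type abundances sampled by a geometric process) and the
    Poisson log normal (PLN) model (latent log normal rates sampled by a
    Poisson process), each with a probability mass function evaluated by
    numerical quadrature, a random sampler, and a zero-truncated maximum
    likelihood fit. Also provides the classical diversity and evenness
    statistics (Shannon, Simpson, Hill numbers, Pielou's J, Berger-Parker
    dominance, Fisher's alpha, logged Hill ratios), robustness diagnostics
    (dominant-species removal, bootstrap resampling, reciprocal-sum pair
    matching, latitudinal summaries), and Monte-Carlo sampling experiments
    that quantify how strongly diversity indices vary under repeated sampling
    from a fixed community.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
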