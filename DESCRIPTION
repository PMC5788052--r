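Package: retropop
Title: Population-Coding Analysis of Retrospective Cueing in Visual Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing continuous-report (delayed estimation) visual
    working memory experiments with retrospective cues. Implements a stochastic
    population-coding model of recall (von Mises tuning curves, Poisson spiking,
    maximum a posteriori decoding) together with the classical von Mises +
    uniform mixture model, both with swap-error and guessing extensions;
    per-participant maximum-likelihood fitting (Nelder-Mead with dispersed
    restarts), AIC model comparison, chance-corrected non-target response
    histograms, non-parametric group statistics with bootstrap standard errors,
    and a synthetic-experiment generator for parameter-recovery studies.
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
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
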