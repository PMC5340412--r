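Package: gutregimes
Title: Autoregressive and Non-Autoregressive Regimes in Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes dense microbial community time series (OTU count
    tables sampled over days) into an autoregressive regime, modeled by
    sparse vector autoregression with Granger-causal networks, and a
    non-autoregressive residual regime, screened for phylogenetic structure
    by distance-binned residual correlations. Includes rarefaction and
    diversity summaries, monotone cubic (PCHIP) gap filling,
    first-differencing, ADF/KPSS stationarity screening, Dirichlet
    multinomial mixture community-state clustering with Laplace model
    selection and temporal-subsampling state-decay curves, conditionally
    rare taxa detection via the bimodality coefficient, and a synthetic
    data generator with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    ape,
    vegan,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    e1071
Config/testthat/edition: 3
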