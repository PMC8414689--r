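Package: zinq
Title: Zero-Inflated Quantile Rank-Score Tests for Microbiome Differential Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Taxon-level association testing between microbial abundance and a
    clinical variable of interest using a two-part quantile regression model.
    The presence/absence of a taxon is tested by logistic regression and the
    conditional quantiles of its non-zero normalized abundance by zero-adjusted
    quantile rank-score tests; the marginal p-values are combined by a MinP
    resampling procedure or a weighted Cauchy combination test. Includes the
    common microbiome normalizations (rarefaction, total sum scaling,
    cumulative sum scaling, centered log-ratio), zero-inflated two-part and
    Dirichlet-multinomial synthetic data generators, and a simulation harness
    for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
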