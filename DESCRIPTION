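Package: plastexpr
Title: Mixed-Model Analysis of Expression Plasticity in Field-Grown Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-transcript linear mixed-model analysis of gene expression
    plasticity for repeated-measures RNA-Seq designs in natural environments.
    Provides detection filtering and median-of-ratios library-size
    normalization of count matrices, REML variance-component decomposition
    across genotype and environment factors, nested-model differential
    expression with Kenward-Roger F-tests gated by a marginal R-squared
    effect-size rule, construction of environmental regressors (detrended
    temperature, signed photoperiod deviation, soil water) with a
    variance-inflation collinearity check, GO-term overrepresentation with
    best-hit-group resampling, and Cohen's-kappa clustering of enriched GO
    categories. Includes a synthetic-study generator with recorded ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    ape
Suggests:
    testthat (>= 3.0.0),
    pbkrtest,
    DESeq2,
    withr,
    jsonlite
Config/testthat/edition: 3
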