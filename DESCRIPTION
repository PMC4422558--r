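Package: crpgrowth
Title: Growth-Rate Composition for Co-Utilized Carbon Substrates under
    cAMP-Crp Catabolite Repression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models steady-state exponential growth of Escherichia coli on
    mixtures of co-utilized carbon substrates under the global cAMP-Crp
    negative feedback on carbon-catabolic gene expression. Implements the
    linear catabolic expression response (the "C-line"), the carbon-flux
    growth relation and its single-parameter growth-rate composition
    formula, tools to estimate the carbon-limited speed limit (lambda_C)
    from expression or growth data with bootstrap confidence intervals, an
    exact rank-based two-sample test for comparing prediction deviations
    between substrate groups, and a synthetic-data generator for
    parameter-recovery studies. Ships the published single- and
    mixed-substrate growth-rate table as a built-in dataset and reproduces
    its validation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
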