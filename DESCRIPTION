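Package: ltcpairs
Title: Observational Co-Occurrence and Genetic Correlation of Long-Term Condition Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing observational co-occurrence and
    genetic correlation across pairs of long-term conditions. Implements
    eligibility gating of conditions (chronicity, prevalence, heritability),
    per-pair logistic co-occurrence models with inverse-variance fixed-effects
    meta-analysis and Benjamini-Hochberg correction, univariate and cross-trait
    LD-score regression with block-jackknife standard errors, source-selection
    rules for combining GWAS summary statistics, tercile-anchored concordance
    classification of pairs, and single-causal-variant Bayesian colocalisation
    with approximate Bayes factors. Ships a synthetic-data module that
    generates GWAS summary statistics, LD-score panels, person-level cohorts
    and colocalisation loci with known ground truth, so every stage is
    testable without access to restricted health or genetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
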