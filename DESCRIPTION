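Package: epiScape
Title: Epistasis Across Environmental Gradients in Two-Locus Fitness Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates competitive fitness of two-locus bacterial genotypes from
    flow-cytometry competition assays across an antibiotic-by-temperature
    environment grid, quantifies gene-by-gene interaction (epistasis) with five
    summary statistics (pairwise epistasis, the gamma correlation of mutational
    effects, simple and reciprocal sign epistasis with a parametric-bootstrap
    detection rule, the roughness-to-slope ratio, and diminishing-returns
    regressions), propagates measurement uncertainty with a parametric
    bootstrap, tests how epistasis changes along environmental gradients, and
    fits a nested linear-model suite for genotype-by-environment effects. A
    synthetic-data generator reproduces the full study design so the pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
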