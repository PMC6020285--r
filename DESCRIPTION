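Package: shhconcord
Title: Cross-Experiment Concordance Analysis of Shh-Regulated Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies Sonic hedgehog (Shh)-regulated genes by comparative
    transcriptomics across two independent expression experiments: per-gene
    differential expression with Benjamini-Hochberg FDR control, asymmetric
    significance gating, direction-concordance intersection of an in vitro
    pathway-activation arm with an in vivo pathway-inhibition arm, fold-change
    rank-sum prioritization of concordant genes, and hypergeometric
    over-representation of user-supplied gene categories. Includes a synthetic
    paired-experiment generator with known regulation truth for power and
    calibration studies, and the bench-validation arithmetic used alongside
    such screens (2^-ddCt relative quantification with Holm-Sidak-corrected
    t-tests, mesenchyme/ectoderm percent-expression partitioning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
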