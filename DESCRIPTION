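Package: jofa
Title: Joint Multi-Omic Factor Analysis with Supervised Factor Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates mRNA, miRNA and protein expression matrices into a single
    joint matrix and analyses it with the factor model X = FL + e, where molecules
    are observations and samples are variables. Provides the full workflow:
    cross-platform probe filtering, probe collapsing by correlation clustering,
    max/IQR expression filtering, mean-baseline or z-score standardization, a
    factor-model family capped by the Kaiser criterion, linear-discriminant
    selection of models and factors with chi-square significance, extraction of
    cross-layer key molecules by factor score, an alternative hierarchical
    clustering + SAM comparison pipeline with permutation FDR, EASE-score gene-set
    enrichment, and a synthetic multi-omic generator with planted ground truth.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
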