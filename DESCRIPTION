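Package: clonepotency
Title: Quantitative Clonal Potency Analysis of Hematopoietic Progenitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of single-cell clonal assays of human
    hematopoietic progenitors. Takes per-clone terminal lineage yields
    (granulocyte, monocyte, lymphocyte and three dendritic-cell subsets)
    and computes lineage-bias statistics (commitment degree, equipotency
    ratio, bias ratio), geometric-mean size-factor normalization across
    donors and lineages, perplexity-calibrated Gaussian affinities with an
    exact-gradient t-SNE embedding, lineage-track backbones and
    nearest-track assignment, complete-linkage clustering with optimal
    leaf ordering, granddaughter bias-inheritance classification, and
    correlations between transcription-factor dosage compartments and
    clonal lineage composition. Includes a seeded synthetic-data generator
    emulating the heavy-tailed, bias-structured clone tables such assays
    produce.
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
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
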