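Package: coexpair
Title: Comparative Co-Expression Analysis of Single-Cell and Bulk Tumor
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares gene co-expression networks built from single-cell and
    bulk RNA-seq profiles of the same tumor type. Gene pairs are classified as
    shared, single-cell-specific or bulk-specific using positive- and
    no-correlation cutoffs derived from shuffled-expression permutation nulls;
    each class is then characterized against protein-protein interactions,
    protein complexes, ontology similarity, promoter chromatin accessibility
    and chromatin contacts, and the class networks are mined for gene
    subnetworks whose expression stratifies patient survival. Ships a
    synthetic-data generator with planted co-expression structure, coupled
    annotations and survival outcomes so the whole pipeline can be exercised
    and calibrated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
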