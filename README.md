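# coexpair

Comparative co-expression analysis of single-cell and bulk tumor expression
profiles.

Co-expression — two genes rising and falling together across samples — is a
workhorse signal for predicting protein interactions, annotating gene
function and stratifying tumors. Almost all of it has historically been
measured in *bulk* tissue, where every profile averages millions of cells.
Single-cell RNA-seq measures the same quantity across *cells within* a
tumor, and the two views disagree profoundly: most strongly co-expressed
gene pairs at one level show no correlation at the other. `coexpair` is a
pipeline for making that comparison rigorously and for characterizing what
each kind of co-expression means, aimed at computational biologists with
paired single-cell / bulk expression data (or none at all — the package
ships a generator of fully synthetic datasets with known ground truth).

## The method

For a gene pair with expression vectors *x*, *y* over *n* samples (cells or
tumors), co-expression is the Pearson coefficient

&nbsp;&nbsp;&nbsp;&nbsp;*R* = Σᵢ(xᵢ−x̄)(yᵢ−ȳ) ⁄ √(Σᵢ(xᵢ−x̄)² · Σᵢ(yᵢ−ȳ)²)

computed after filtering (bulk genes with mean < 100 RPKM; single-cell
genes zero in over two-thirds of cells are excluded), log₂(RPKM+1)
transformation, per-gene centering and quantile normalization. Because the
single-cell and bulk correlation distributions differ, cutoffs are derived
separately per level from a *shuffled-expression null*: each gene's values
are permuted across samples (1,000 replicates), all-pairs correlations are
pooled, and

* the **positive cutoff** is the null's upper 10⁻⁶ quantile,
* the **no-correlation interval** covers 0.3 of null mass on each side of
  the null median.

Each pair then receives a pattern (`+`, `0`, `−`, or `intermediate`) per
level and a class: `+` at both levels is **shared**; `+` at one level with
an affirmative `0` at the other is **single-cell-specific** or
**bulk-specific**; everything else is `other`. The classes are
characterized against protein–protein interactions, protein complexes and
ontology similarity (with 1,000 random sets of 1,000 gene pairs as
controls), against promoter DNase-hypersensitivity correlation across 125
cell types, chromatin contacts (gene body ± 5 kb), and chromosome/
topological-domain co-location. Finally the three class networks are
decomposed into greedy-modularity subnetworks; each subnetwork (and every
combination of up to three screened ones) partitions patients into two
groups by hierarchical clustering (1 − *R*, complete linkage), is scored by
the log-rank test with Benjamini–Hochberg FDR and silhouette width, and the
winning signature is validated on a second expression platform after
reference-sample normalization, using a nearest-shrunken-centroid
classifier.

## Worked example

```r
library(coexpair)

cfg  <- sim_config(seed = 1)                  # 300 genes, 200 cells, 120 tumors
sim  <- simulate_dataset(cfg)                 # expression + annotations + clinical
proc <- preprocess_pipeline(sim$sc, sim$bulk)
corr <- correlate_levels(proc$sc, proc$bulk)
th   <- derive_thresholds(build_null(proc$sc,   n_reps = 200, seed = 2),
                          build_null(proc$bulk, n_reps = 200, seed = 3),
                          tail_method = "normal")
tibble::as_tibble(th)
#>   level       pos_cutoff neg_cutoff   no_lo  no_hi tail_method n_pooled
#> 1 single_cell      0.337     -0.337 -0.0605 0.0594 normal       8970000
#> 2 bulk             0.436     -0.436 -0.0775 0.0776 normal       8970000
```

The cutoffs say: at 200 cells a correlation must exceed 0.34 (0.44 at 120
tumors) to clear the 10⁻⁶ null tail, and only |R| ≲ 0.06–0.08 counts as
affirmative no-correlation. Classifying all 44,850 pairs:

```r
classes <- classify_pairs(corr, th)
table(classes$class)
#> bulk_specific    other  sc_specific   shared
#>            24    44737           31       58

ppi_enrichment(classes[classes$class == "shared", ],
               sim$annotations$ppi, proc$sc$gene, seed = 4)
#> <coex_enrichment: observed 0.1207 vs control 0.00368 (1000 x 1000 sets)
#>   = 32.80-fold, t-test p = 0>
```

Shared pairs are ~33-fold enriched for protein interactions over random
gene pairs — the generator planted a 27-odds coupling, recovered here
within sampling error on 58 pairs. The survival search then finds the
planted six-gene prognostic module:

```r
nets     <- lapply(c(shared = "shared", sc_specific = "sc_specific",
                     bulk_specific = "bulk_specific"),
                   \(cl) build_class_network(classes, cl))
subnets  <- purrr::imap_dfr(nets, \(g, cl) detect_subnetworks(g, class = cl))
bulk_log <- log2_plus_one(sim$bulk)
screened <- screen_subnetworks(subnets, bulk_log, sim$cohort$training)
sig      <- combine_and_search(screened, bulk_log, sim$cohort$training)
glance(sig)
#>   unit_id      n_genes statistic            p           q silhouette
#> 1 shared_sub02       6      29.5 0.0000000551 0.000000221      0.778
```

A log-rank p of 5.5×10⁻⁸ with silhouette 0.78 means the six genes split
the 120 training patients into two well-separated groups with sharply
different survival; `run_pipeline(run_config(sim = cfg))` chains all of the
above (plus the regulatory stage and cross-platform validation) and writes
a machine-readable `report.json`. `autoplot()` methods draw the classified
correlation plane and Kaplan–Meier curves; `tidy()`/`glance()` return the
result tables.

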