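#' All-pairs Pearson correlation
#'
#' Computes the Pearson correlation coefficient for every unordered gene pair
#' across samples. Zero-variance genes yield `NA` correlations (flagged
#' undefined, excluded from downstream ranking and classification). A warning
#' is raised when the matrix is not quantile-normalized.
#'
#' @param m a `coex_expr` with at least 3 samples.
#' @return tibble with columns `gene_a`, `gene_b` (gene_a < gene_b) and `r`.
#' @export
pearson_all_pairs <- function(m) {
  check_expr(m)
  if (ncol(m) - 1L < 3L) stop("need at least 3 samples", call. = FALSE)
  if (expr_state(m) != "quantile_normalized") {
    warning("correlating a matrix that is not quantile_normalized",
            call. = FALSE)
  }
  v <- expr_values(m)
  v <- v[order(rownames(v)), , drop = FALSE]
  cor_to_pairs(row_cor(v))
}

#' Correlation table across the two measurement levels
#'
#' @param sc,bulk processed `coex_expr` matrices over the identical gene set.
#' @return tibble `gene_a`, `gene_b`, `r_sc`, `r_bulk` (one row per unordered
#'   pair).
#' @export
correlate_levels <- function(sc, bulk) {
  if (!setequal(expr_genes(sc), expr_genes(bulk))) {
    stop("gene universes differ; run intersect_genes() first", call. = FALSE)
  }
  t_sc <- pearson_all_pairs(sc)
  t_bulk <- dplyr::rename(pearson_all_pairs(bulk), r_bulk = "r")
  dplyr::inner_join(dplyr::rename(t_sc, r_sc = "r"), t_bulk,
                    by = c("gene_a", "gene_b"))
}

#' Top-k most positively correlated pairs at one level
#'
#' Pairs are ranked by decreasing correlation; ties are broken
#' lexicographically by gene IDs, so the selection is deterministic.
#' Undefined (NA) correlations are excluded.
#'
#' @param tbl a correlation table with columns `gene_a`, `gene_b` and either
#'   `r` or `r_sc`/`r_bulk`.
#' @param level `"single_cell"` or `"bulk"` (ignored when `tbl` has a plain
#'   `r` column).
#' @param k number of pairs (default 1000).
#' @return tibble of the k selected rows, ordered.
#' @export
top_k_pairs <- function(tbl, level = c("single_cell", "bulk"), k = 1000) {
  level <- match.arg(level)
  col <- if ("r" %in% names(tbl)) "r" else {
    if (level == "single_cell") "r_sc" else "r_bulk"
  }
  r <- tbl[[col]]
  tbl <- tbl[!is.na(r), ]
  if (k > nrow(tbl)) {
    stop(sprintf("k = %d exceeds the %d available pairs", k, nrow(tbl)),
         call. = FALSE)
  }
  ord <- order(-tbl[[col]], tbl$gene_a, tbl$gene_b)
  tbl[ord[seq_len(k)], ]
}

#' Split-half robustness of the top-k selection
#'
#' Randomly partitions the samples into two equal halves (odd sizes give the
#' extra sample to half 1), recomputes all-pairs correlations in each half and
#' returns the overlap of the two top-k pair sets.
#'
#' @param m a `coex_expr` with at least 6 samples.
#' @param k size of the top list per half.
#' @param seed integer seed for the split.
#' @return integer overlap count, with attributes `k` and `half_sizes`.
#' @export
split_half_overlap <- function(m, k = 1000, seed = 1L) {
  check_expr(m)
  n <- ncol(m) - 1L
  if (n < 6L) stop("need at least 6 samples", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n))
  n1 <- ceiling(n / 2)
  half <- function(ix) {
    new_coex_expr(m[, c(1L, 1L + sort(ix))], expr_level(m), expr_state(m))
  }
  tops <- lapply(list(idx[seq_len(n1)], idx[-seq_len(n1)]), function(ix) {
    t <- suppressWarnings(pearson_all_pairs(half(ix)))
    with(top_k_pairs(t, k = k), pair_key(gene_a, gene_b))
  })
  structure(length(intersect(tops[[1]], tops[[2]])),
            k = k, half_sizes = c(n1, n - n1))
}

#' Hierarchical clustering of samples by expression similarity
#'
#' Clusters sample columns with distance `1 - Pearson r` and complete
#' linkage. Several matrices (sharing a gene universe) may be supplied and
#' are combined column-wise — e.g. genuine bulk tumors next to pseudo-bulk
#' averages of single cells.
#'
#' @param ms a `coex_expr` or list of them.
#' @return an [stats::hclust] tree over samples.
#' @export
cluster_samples <- function(ms) {
  if (inherits(ms, "coex_expr")) ms <- list(ms)
  genes <- Reduce(intersect, lapply(ms, expr_genes))
  if (length(genes) < 2) stop("shared gene universe too small", call. = FALSE)
  vals <- do.call(cbind, lapply(ms, function(m) {
    expr_values(m)[genes, , drop = FALSE]
  }))
  d <- stats::as.dist(1 - stats::cor(vals))
  stats::hclust(d, method = "complete")
}
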