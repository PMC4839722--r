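#' Gene filters for bulk and single-cell RPKM matrices
#'
#' `filter_bulk_genes()` drops genes whose mean RPKM across samples falls
#' below `min_mean` (a mean exactly equal to `min_mean` is kept: only values
#' strictly below the cutoff are excluded). `filter_sc_genes()` drops genes
#' whose fraction of zero entries across cells exceeds `max_zero_fraction`
#' (exactly two-thirds zeros is kept: only fractions strictly over the cutoff
#' are excluded).
#'
#' @param m a `coex_expr` in state `raw_rpkm` (bulk or single_cell level,
#'   respectively).
#' @param min_mean minimum mean RPKM retained (default 100).
#' @param max_zero_fraction maximum tolerated zero fraction (default 2/3).
#' @return the filtered `coex_expr`; errors if no gene survives.
#' @export
filter_bulk_genes <- function(m, min_mean = 100) {
  check_expr(m, state = "raw_rpkm", level = "bulk")
  keep <- rowMeans(expr_values(m)) >= min_mean
  if (!any(keep)) stop("no genes survive filter", call. = FALSE)
  new_coex_expr(m[keep, ], expr_level(m), expr_state(m))
}

#' @rdname filter_bulk_genes
#' @export
filter_sc_genes <- function(m, max_zero_fraction = 2 / 3) {
  check_expr(m, state = "raw_rpkm", level = "single_cell")
  zf <- rowMeans(expr_values(m) == 0)
  keep <- zf <= max_zero_fraction
  if (!any(keep)) stop("no genes survive filter", call. = FALSE)
  new_coex_expr(m[keep, ], expr_level(m), expr_state(m))
}

#' Restrict two expression matrices to their common gene universe
#'
#' Both outputs carry the identical, identically ordered gene set (sorted
#' intersection).
#'
#' @param a,b `coex_expr` objects.
#' @return named list with elements `a` and `b`.
#' @export
intersect_genes <- function(a, b) {
  check_expr(a, arg = "a")
  check_expr(b, arg = "b")
  common <- sort(intersect(expr_genes(a), expr_genes(b)))
  if (length(common) == 0) stop("empty gene intersection", call. = FALSE)
  list(a = new_coex_expr(a[match(common, a$gene), ], expr_level(a),
                         expr_state(a)),
       b = new_coex_expr(b[match(common, b$gene), ], expr_level(b),
                         expr_state(b)))
}

#' Expression normalization chain
#'
#' `log2_plus_one()` maps every RPKM value v to `log2(v + 1)`.
#' `center_genes()` subtracts each gene's mean across samples
#' (centralization). `quantile_normalize()` forces every sample column to the
#' cross-sample mean quantile vector (average-of-span tie convention, via
#' \pkg{limma}), preserving within-column rank order. States advance
#' `raw_rpkm -> log2 -> centered -> quantile_normalized`.
#'
#' @param m a `coex_expr` in the state the operation expects.
#' @return the transformed `coex_expr` in the next state.
#' @export
log2_plus_one <- function(m) {
  check_expr(m, state = "raw_rpkm")
  v <- expr_values(m)
  if (any(v < 0)) stop("negative RPKM values", call. = FALSE)
  advance_state(replace_values(m, log2(v + 1)), "log2")
}

#' @rdname log2_plus_one
#' @export
center_genes <- function(m) {
  check_expr(m, state = "log2")
  v <- expr_values(m)
  advance_state(replace_values(m, v - rowMeans(v)), "centered")
}

#' @rdname log2_plus_one
#' @export
quantile_normalize <- function(m) {
  check_expr(m, state = "centered")
  v <- limma::normalizeQuantiles(expr_values(m), ties = TRUE)
  advance_state(replace_values(m, v), "quantile_normalized")
}

#' Average single-cell profiles into pseudo-bulk tumor profiles
#'
#' One output column per tumor containing the per-gene mean over that tumor's
#' cells — the single-cell counterpart used to compare against genuine bulk
#' profiles of the same tumors.
#'
#' @param m a single-cell `coex_expr`.
#' @param cell_to_tumor named character vector (or two-column data frame
#'   `cell`, `tumor`) mapping every cell to its tumor.
#' @return a bulk-level `coex_expr` (same state as the input) of pseudo-bulk
#'   columns.
#' @export
average_cell_profile <- function(m, cell_to_tumor) {
  check_expr(m, level = "single_cell")
  if (is.data.frame(cell_to_tumor)) {
    cell_to_tumor <- stats::setNames(cell_to_tumor$tumor, cell_to_tumor$cell)
  }
  cells <- expr_samples(m)
  missing <- setdiff(cells, names(cell_to_tumor))
  if (length(missing) > 0) {
    stop(sprintf("unmapped cells: %s", paste(utils::head(missing, 3),
                                             collapse = ", ")), call. = FALSE)
  }
  v <- expr_values(m)
  tumor <- cell_to_tumor[cells]
  means <- vapply(split(seq_along(cells), tumor),
                  function(ix) rowMeans(v[, ix, drop = FALSE]),
                  numeric(nrow(v)))
  out <- tibble::as_tibble(means, rownames = "gene")
  new_coex_expr(out, level = "bulk", state = expr_state(m))
}

#' Full preprocessing chain for a paired single-cell / bulk dataset
#'
#' Applies the level-specific gene filters, intersects the gene universes,
#' then log2(+1)-transforms, centers genes and quantile-normalizes each level
#' separately.
#'
#' @param sc,bulk raw RPKM `coex_expr` matrices.
#' @param min_mean bulk mean-RPKM filter cutoff.
#' @param max_zero_fraction single-cell zero-fraction filter cutoff.
#' @return list with processed `sc` and `bulk` matrices
#'   (state `quantile_normalized`).
#' @export
preprocess_pipeline <- function(sc, bulk, min_mean = 100,
                                max_zero_fraction = 2 / 3) {
  sc <- filter_sc_genes(sc, max_zero_fraction)
  bulk <- filter_bulk_genes(bulk, min_mean)
  both <- intersect_genes(sc, bulk)
  chain <- function(m) quantile_normalize(center_genes(log2_plus_one(m)))
  list(sc = chain(both$a), bulk = chain(both$b))
}
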