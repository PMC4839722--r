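#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a survival-signature search
#'
#' One row per tested unit (single subnetworks and combinations) with its
#' log-rank statistic, p and BH q.
#'
#' @param x a `coex_signature`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy coex_signature
#' @export
tidy.coex_signature <- function(x, ...) {
  dplyr::select(x$units, "unit_id", "class", "combo_size", "n_genes",
                "statistic", "p", "q")
}

#' @rdname tidy.coex_signature
#' @method glance coex_signature
#' @export
glance.coex_signature <- function(x, ...) {
  if (is.null(x$best)) {
    return(tibble::tibble(unit_id = NA_character_, n_genes = NA_integer_,
                          statistic = NA_real_, p = NA_real_, q = NA_real_,
                          silhouette = NA_real_))
  }
  tibble::tibble(unit_id = x$best$unit_id,
                 n_genes = length(x$best$genes),
                 statistic = x$best$statistic, p = x$best$p, q = x$best$q,
                 silhouette = x$best$silhouette)
}

#' Tidy an enrichment result
#'
#' @param x a `coex_enrichment`.
#' @param ... unused.
#' @return a one-row tibble with the observed fraction, control mean/sd,
#'   fold and both p-values.
#' @method tidy coex_enrichment
#' @export
tidy.coex_enrichment <- function(x, ...) {
  tibble::tibble(observed = x$observed, control_mean = x$control_mean,
                 control_sd = x$control_sd, fold = x$fold, p_t = x$p_t,
                 p_empirical = x$p_empirical, n_sets = x$n_sets,
                 set_size = x$set_size)
}
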