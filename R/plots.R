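#' Plot a classified correlation table
#'
#' Scatter of bulk versus single-cell correlation for every pair, coloured by
#' co-expression class, with the positive cutoffs and no-correlation
#' intervals drawn as reference lines.
#'
#' @param object a `coex_class_table`.
#' @param max_points subsample cap for the `other` class (default 20000).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot coex_class_table
#' @export
autoplot.coex_class_table <- function(object, max_points = 20000, ...) {
  th <- attr(object, "thresholds")
  tb <- tibble::as_tibble(object)
  other <- tb[tb$class == "other", ]
  if (nrow(other) > max_points) {
    other <- other[seq(1, nrow(other), length.out = max_points), ]
  }
  tb <- dplyr::bind_rows(other, tb[tb$class != "other", ])
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$r_sc, y = .data$r_bulk,
                                        colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "single-cell correlation", y = "bulk correlation",
                  colour = "class") +
    ggplot2::theme_minimal()
  if (!is.null(th)) {
    t_sc <- th[th$level == "single_cell", ]
    t_bulk <- th[th$level == "bulk", ]
    p <- p +
      ggplot2::geom_vline(xintercept = c(t_sc$pos_cutoff, t_sc$no_lo,
                                         t_sc$no_hi),
                          linetype = "dashed", colour = "grey50") +
      ggplot2::geom_hline(yintercept = c(t_bulk$pos_cutoff, t_bulk$no_lo,
                                         t_bulk$no_hi),
                          linetype = "dashed", colour = "grey50")
  }
  p
}

#' Kaplan–Meier curves of a signature's patient partition
#'
#' @param object a `coex_signature` with a winning unit.
#' @param cohort clinical tibble (`patient`, `time`, `event`).
#' @param ... unused.
#' @return a ggplot of the two survival curves.
#' @method autoplot coex_signature
#' @export
autoplot.coex_signature <- function(object, cohort, ...) {
  if (is.null(object$best)) stop("signature has no winning unit",
                                 call. = FALSE)
  km <- km_table(cohort, object$best$partition)
  km0 <- dplyr::bind_rows(
    tibble::tibble(cluster = unique(km$cluster), time = 0,
                   n_risk = NA_integer_, n_event = 0L, survival = 1),
    km)
  ggplot2::ggplot(km0, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = factor(.data$cluster))) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival",
                  colour = "patient group",
                  subtitle = sprintf("log-rank p = %.2g", object$best$p)) +
    ggplot2::theme_minimal()
}

#' Null distribution with derived cutoffs
#'
#' Histogram of the pooled shuffled-expression correlations with the
#' positive/negative cutoffs and the no-correlation interval marked.
#'
#' @param null a `coex_null`.
#' @param thresholds a `coex_thresholds`.
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_null_thresholds <- function(null, thresholds, bins = 100) {
  th <- thresholds[thresholds$level == null$level, ]
  x <- null$values
  if (length(x) > 2e5) x <- x[seq(1, length(x), length.out = 2e5)]
  ggplot2::ggplot(tibble::tibble(r = x), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(th$pos_cutoff, th$neg_cutoff),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(th$no_lo, th$no_hi),
                        colour = "blue", linetype = "dotted") +
    ggplot2::labs(x = sprintf("shuffled-expression correlation (%s)",
                              null$level), y = "count") +
    ggplot2::theme_minimal()
}
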