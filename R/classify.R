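#' Shuffled-expression null distribution of pair correlations
#'
#' For each replicate, every gene's values are independently permuted across
#' samples, destroying all pair structure while preserving gene marginals;
#' all-pairs Pearson correlations of the shuffled matrix are pooled over
#' replicates into one empirical null. Constant (zero-variance) genes are
#' excluded up front.
#'
#' @param m a preprocessed `coex_expr`.
#' @param n_reps number of shuffle replicates (default 1000).
#' @param seed integer seed.
#' @return a `coex_null` list: `values` (pooled correlations), `n_reps`,
#'   `n_pairs`, `n_samples`, `level`, `seed`.
#' @export
build_null <- function(m, n_reps = 1000, seed = 1L) {
  check_expr(m)
  n_reps <- check_count(n_reps, "n_reps")
  v <- expr_values(m)
  keep <- apply(v, 1, stats::sd) > 0
  v <- v[keep, , drop = FALSE]
  p <- nrow(v)
  n <- ncol(v)
  n_pairs <- p * (p - 1) / 2
  ut <- upper.tri(matrix(0, p, p))
  values <- withr::with_seed(seed, {
    out <- numeric(n_reps * n_pairs)
    for (rep in seq_len(n_reps)) {
      shuf <- v
      for (g in seq_len(p)) shuf[g, ] <- shuf[g, sample.int(n)]
      out[(rep - 1) * n_pairs + seq_len(n_pairs)] <- row_cor(shuf)[ut]
    }
    out
  })
  structure(list(values = values, n_reps = n_reps, n_pairs = n_pairs,
                 n_samples = n, level = expr_level(m), seed = seed),
            class = "coex_null")
}

#' @export
print.coex_null <- function(x, ...) {
  cat(sprintf(paste0("<coex_null: level=%s, %d reps x %d pairs = %d values, ",
                     "sd=%.4f>\n"),
              x$level, x$n_reps, x$n_pairs, length(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' Correlation cutoffs from shuffled nulls
#'
#' Per level: the positive cutoff is the `1 - pos_tail` quantile of the pooled
#' null and the negative cutoff the `pos_tail` quantile; the no-correlation
#' interval covers `nocorr_mass_per_side` of null probability mass on each
#' side of the null median, i.e. the quantile interval
#' `[0.5 - mass, 0.5 + mass]`.
#'
#' When the pooled null holds fewer than `10 / pos_tail` values, the extreme
#' quantiles cannot be estimated empirically; a normal distribution is then
#' fitted to the pooled null and its analytic quantiles are used (`tail_method
#' = "auto"` does this silently-with-warning; request `"normal"` or
#' `"empirical"` explicitly to pick a method without the warning).
#'
#' @param null_sc,null_bulk `coex_null` objects for the two levels.
#' @param pos_tail upper-tail probability for positive correlation
#'   (default 1e-6).
#' @param nocorr_mass_per_side null mass on each side of the median inside the
#'   no-correlation interval (default 0.3; 0.5 spans the whole null).
#' @param tail_method `"auto"`, `"empirical"` or `"normal"`.
#' @return a `coex_thresholds` tibble: one row per level with `pos_cutoff`,
#'   `neg_cutoff`, `no_lo`, `no_hi`, `tail_method`, `n_pooled`.
#' @export
derive_thresholds <- function(null_sc, null_bulk, pos_tail = 1e-6,
                              nocorr_mass_per_side = 0.3,
                              tail_method = c("auto", "empirical", "normal")) {
  tail_method <- match.arg(tail_method)
  if (pos_tail <= 0 || pos_tail >= 0.5) {
    stop("`pos_tail` must be in (0, 0.5)", call. = FALSE)
  }
  if (nocorr_mass_per_side <= 0 || nocorr_mass_per_side > 0.5) {
    stop("`nocorr_mass_per_side` must be in (0, 0.5]", call. = FALSE)
  }
  one <- function(null) {
    stopifnot(inherits(null, "coex_null"))
    x <- null$values
    method <- tail_method
    if (method == "auto") {
      if (length(x) < 10 / pos_tail) {
        warning(sprintf(paste0("pooled null too small (%d values) for an ",
                               "empirical %g tail quantile; extrapolating ",
                               "from a fitted normal"),
                        length(x), pos_tail), call. = FALSE)
        method <- "normal"
      } else {
        method <- "empirical"
      }
    }
    if (method == "normal") {
      mu <- mean(x)
      s <- stats::sd(x)
      pos <- stats::qnorm(1 - pos_tail, mu, s)
      neg <- stats::qnorm(pos_tail, mu, s)
    } else {
      q <- stats::quantile(x, c(pos_tail, 1 - pos_tail), names = FALSE)
      neg <- q[1]
      pos <- q[2]
    }
    m <- nocorr_mass_per_side
    no <- stats::quantile(x, c(max(0.5 - m, 0), min(0.5 + m, 1)),
                          names = FALSE)
    tibble::tibble(level = null$level, pos_cutoff = pos, neg_cutoff = neg,
                   no_lo = no[1], no_hi = no[2], tail_method = method,
                   n_pooled = length(x))
  }
  th <- dplyr::bind_rows(one(null_sc), one(null_bulk))
  if (!setequal(th$level, c("single_cell", "bulk"))) {
    stop("expected one single_cell and one bulk null", call. = FALSE)
  }
  structure(th, class = c("coex_thresholds", class(tibble::tibble())),
            pos_tail = pos_tail, nocorr_mass_per_side = nocorr_mass_per_side)
}

#' Classify gene pairs into shared / specific co-expression classes
#'
#' Each pair gets a correlation pattern at each level — `+` (at or above the
#' positive cutoff), `-` (at or below the negative cutoff), `0` (inside the
#' no-correlation interval) or `intermediate` (between interval and cutoff) —
#' and a class: `(+,+)` is `shared`, `+` at single-cell with an affirmative
#' `0` at bulk is `sc_specific`, the converse is `bulk_specific`, everything
#' else `other`. The stringent `intermediate` zone means a pair is called
#' specific only when the other level shows affirmative no-correlation.
#' Pairs with undefined correlations are dropped with a message.
#'
#' @param tbl correlation table from [correlate_levels()].
#' @param th a `coex_thresholds`.
#' @return a `coex_class_table` tibble: inputs plus `pattern_sc`,
#'   `pattern_bulk`, `class`.
#' @export
classify_pairs <- function(tbl, th) {
  stopifnot(inherits(th, "coex_thresholds"))
  bad <- is.na(tbl$r_sc) | is.na(tbl$r_bulk)
  if (any(bad)) {
    message(sprintf("dropping %d pairs with undefined correlation", sum(bad)))
    tbl <- tbl[!bad, ]
  }
  pat <- function(r, t) {
    dplyr::case_when(
      r >= t$pos_cutoff ~ "+",
      r <= t$neg_cutoff ~ "-",
      r >= t$no_lo & r <= t$no_hi ~ "0",
      TRUE ~ "intermediate")
  }
  t_sc <- th[th$level == "single_cell", ]
  t_bulk <- th[th$level == "bulk", ]
  out <- dplyr::mutate(
    tbl,
    pattern_sc = pat(.data$r_sc, t_sc),
    pattern_bulk = pat(.data$r_bulk, t_bulk),
    class = dplyr::case_when(
      .data$pattern_sc == "+" & .data$pattern_bulk == "+" ~ "shared",
      .data$pattern_sc == "+" & .data$pattern_bulk == "0" ~ "sc_specific",
      .data$pattern_sc == "0" & .data$pattern_bulk == "+" ~ "bulk_specific",
      TRUE ~ "other"))
  structure(out, class = c("coex_class_table", class(tibble::tibble())),
            thresholds = th)
}
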