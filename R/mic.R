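#' Naive-grid maximal information coefficient
#'
#' Approximates the maximal information coefficient of two numeric vectors by
#' an exhaustive search over equi-count grids: for every bin-count pair
#' (a, b) with a, b >= 2 and a * b <= `max_bins` (default `n^0.6`), both
#' variables are cut at empirical quantiles (ties resolved by first-occurrence
#' rank) and the normalized mutual information
#' `I(a, b) / log(min(a, b))` is recorded; the maximum over grids is returned.
#'
#' This is a documented approximation of MIC — the axis partitions are fixed
#' equi-count cuts rather than optimized — adequate as a robustness check for
#' monotone and simple non-monotone dependence, not a reimplementation of the
#' full dynamic-programming estimator.
#'
#' @param x,y numeric vectors of equal length (>= 25).
#' @param max_bins cap on a * b (default `length(x)^0.6`).
#' @return MIC value in \[0, 1\].
#' @export
mic <- function(x, y, max_bins = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (n < 25) stop("need at least 25 samples", call. = FALSE)
  max_bins <- max_bins %||% max(floor(n^0.6), 4)
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")
  bin <- function(r, k) ceiling(r * k / n)
  best <- 0
  for (a in 2:floor(max_bins / 2)) {
    for (b in 2:floor(max_bins / a)) {
      tab <- table(bin(rx, a), bin(ry, b))
      p <- tab / n
      px <- rowSums(p)
      py <- colSums(p)
      e <- outer(px, py)
      nz <- p > 0
      mi <- sum(p[nz] * log(p[nz] / e[nz]))
      best <- max(best, mi / log(min(a, b)))
    }
  }
  min(best, 1)
}

#' All-pairs MIC
#'
#' @param m a `coex_expr` with at least 25 samples.
#' @param max_bins see [mic()].
#' @return tibble `gene_a`, `gene_b`, `mic`.
#' @export
mic_all_pairs <- function(m, max_bins = NULL) {
  check_expr(m)
  v <- expr_values(m)
  if (ncol(v) < 25) stop("need at least 25 samples", call. = FALSE)
  if (nrow(v) > 200) {
    warning("naive MIC over many genes is slow; consider a subset",
            call. = FALSE)
  }
  v <- v[order(rownames(v)), , drop = FALSE]
  pairs <- all_pairs(rownames(v))
  pairs$mic <- vapply(seq_len(nrow(pairs)), function(i) {
    mic(v[pairs$gene_a[i], ], v[pairs$gene_b[i], ], max_bins)
  }, numeric(1))
  pairs
}
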