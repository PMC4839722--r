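# Independent brute-force oracles used across the suite. Each implements the
# textbook definition directly (loops / enumeration), independent of the
# package's code paths.

make_expr <- function(mat, level = "bulk", state = "quantile_normalized") {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  }
  expression_matrix(mat, level = level, state = state)
}

# Pearson r by direct summation
oracle_pearson <- function(x, y) {
  n <- length(x)
  xm <- sum(x) / n
  ym <- sum(y) / n
  num <- sum((x - xm) * (y - ym))
  num / sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

# hypergeometric upper tail P(X >= q) by enumeration
oracle_hyper_upper <- function(q, m, n_other, k) {
  tot <- 0
  for (i in q:min(m, k)) {
    tot <- tot + choose(m, i) * choose(n_other, k - i) /
      choose(m + n_other, k)
  }
  tot
}

# two-group log-rank chi-square from the O/E/V table over event times
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[ord[i]] / i)
    q[ord[i]] <- prev
  }
  pmin(q, 1)
}

# mean silhouette width from the definition, given a distance matrix
oracle_silhouette <- function(d, cluster) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    if (sum(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(cluster), cluster[i]), function(k) {
      mean(d[i, cluster == k])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Newman-Girvan modularity of a partition (membership vector) of an
# undirected simple graph given as an edge matrix (two columns of node ids)
oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  deg <- table(factor(c(edges[, 1], edges[, 2]),
                      levels = names(membership)))
  q <- 0
  for (com in unique(membership)) {
    nodes <- names(membership)[membership == com]
    e_c <- sum(edges[, 1] %in% nodes & edges[, 2] %in% nodes)
    d_c <- sum(deg[nodes])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# all set partitions of a vector (for exhaustive modularity search, n <= 10)
all_partitions <- function(items) {
  if (length(items) == 1) {
    return(list(list(items)))
  }
  first <- items[1]
  rest <- all_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(first), p)
  }
  out
}

oracle_best_modularity <- function(edges, nodes) {
  best <- -Inf
  for (p in all_partitions(nodes)) {
    memb <- stats::setNames(rep(seq_along(p), lengths(p)), unlist(p))
    memb <- memb[nodes]
    best <- max(best, oracle_modularity(edges, memb))
  }
  best
}

# quantile normalization with average-of-span tie handling, per definition
oracle_quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    out[, j] <- vapply(r, function(ri) {
      lo <- floor(ri)
      hi <- ceiling(ri)
      mean(ref[c(lo, hi)])
    }, numeric(1))
  }
  out
}

# explicit all-unordered-pairs builder for fixtures
all_pairs_of <- function(genes) {
  idx <- utils::combn(length(genes), 2L)
  tibble::tibble(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]])
}

# exponential survival toy cohort generator for calibration tests
toy_cohort <- function(n, hr = 1, seed = 1) {
  withr::with_seed(seed, {
    group <- rep(1:2, length.out = n)
    rate <- ifelse(group == 2, hr, 1) * log(2) / 400
    tibble::tibble(patient = sprintf("p%03d", seq_len(n)),
                   time = stats::rexp(n, rate), event = 1L,
                   cluster = group)
  })
}
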