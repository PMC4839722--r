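# shared internal helpers

# canonical unordered pair key "a|b" with a < b lexicographically
pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "|")
}

# tibble of all unordered pairs over a gene universe, gene_a < gene_b
all_pairs <- function(genes) {
  genes <- sort(genes)
  if (length(genes) < 2L) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  idx <- utils::combn(length(genes), 2L)
  tibble::tibble(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]])
}

# orient a pair table so gene_a < gene_b
orient_pairs <- function(pairs) {
  a <- pmin(pairs$gene_a, pairs$gene_b)
  b <- pmax(pairs$gene_a, pairs$gene_b)
  pairs$gene_a <- a
  pairs$gene_b <- b
  pairs
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name, open_lo = FALSE, open_hi = FALSE) {
  lo_ok <- if (open_lo) x > 0 else x >= 0
  hi_ok <- if (open_hi) x < 1 else x <= 1
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || !lo_ok || !hi_ok) {
    stop(sprintf("`%s` must be a probability in %s0,1%s", name,
                 if (open_lo) "(" else "[", if (open_hi) ")" else "]"),
         call. = FALSE)
  }
  as.numeric(x)
}

# deterministic child seed derived from a root seed and a stage offset,
# kept inside 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

# Pearson correlation matrix between rows of X, via standardized crossprod
# (zero-variance rows yield NA). Much faster than looping cor() per pair.
row_cor <- function(X) {
  n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  ss <- sqrt(rowSums(Xc^2))
  zero <- ss <= .Machine$double.eps * n
  ss[zero] <- NA_real_
  Z <- Xc / ss
  R <- tcrossprod(Z)
  R[R > 1] <- 1
  R[R < -1] <- -1
  R
}

# upper-triangle pair tibble of a symmetric gene x gene correlation matrix
cor_to_pairs <- function(R, value_name = "r") {
  genes <- rownames(R)
  ut <- upper.tri(R)
  idx <- which(ut, arr.ind = TRUE)
  tb <- tibble::tibble(gene_a = genes[idx[, 1L]],
                       gene_b = genes[idx[, 2L]],
                       value = R[ut])
  names(tb)[3] <- value_name
  orient_pairs(tb)
}
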