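#' Build a co-expression network for one pair class
#'
#' Nodes are the genes appearing in at least one pair of the class; edges are
#' the class pairs. Vertices are sorted lexicographically so downstream
#' community detection is deterministic.
#'
#' @param class_table a `coex_class_table`.
#' @param class `"shared"`, `"sc_specific"` or `"bulk_specific"`.
#' @return an undirected [igraph::graph].
#' @export
build_class_network <- function(class_table,
                                class = c("shared", "sc_specific",
                                          "bulk_specific")) {
  class <- match.arg(class)
  edges <- class_table[class_table$class == class, c("gene_a", "gene_b")]
  if (nrow(edges) == 0) {
    warning(sprintf("class '%s' has no pairs; empty network", class),
            call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  verts <- sort(unique(c(edges$gene_a, edges$gene_b)))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Dense subnetworks by greedy modularity maximization
#'
#' Communities are found by the Clauset–Newman–Moore greedy agglomerative
#' modularity scheme (merging the community pair with the largest modularity
#' gain until no gain remains); communities smaller than `min_size` are
#' discarded. Deterministic for a fixed vertex order.
#'
#' @param g undirected graph.
#' @param min_size minimum community size kept (default 3).
#' @param class optional class label stored with each subnetwork.
#' @return tibble `subnetwork_id`, `class`, `n_genes`, `genes` (list column,
#'   sorted).
#' @export
detect_subnetworks <- function(g, min_size = 3, class = NA_character_) {
  empty <- tibble::tibble(subnetwork_id = character(), class = character(),
                          n_genes = integer(), genes = list())
  if (igraph::vcount(g) == 0) {
    return(empty)
  }
  gs <- igraph::simplify(g)
  comm <- igraph::cluster_fast_greedy(gs)
  groups <- igraph::communities(comm)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  groups <- groups[lengths(groups) >= min_size]
  if (length(groups) == 0) {
    return(empty)
  }
  tibble::tibble(
    subnetwork_id = sprintf("%s_sub%02d",
                            ifelse(is.na(class), "net", class),
                            seq_along(groups)),
    class = class,
    n_genes = lengths(groups),
    genes = unname(groups))
}

#' Two-group patient partition by expression of a gene set
#'
#' Hierarchical clustering of patient columns restricted to the gene set,
#' with distance `1 - Pearson r` and complete linkage, cut into two groups.
#'
#' @param expr a bulk `coex_expr`.
#' @param genes gene set (>= 2 genes present in the matrix).
#' @return tibble `patient`, `cluster` (1/2), deterministic.
#' @export
cluster_patients_two_groups <- function(expr, genes) {
  check_expr(expr)
  if (ncol(expr) - 1L < 4L) stop("fewer than 4 patients", call. = FALSE)
  genes <- intersect(genes, expr_genes(expr))
  if (length(genes) < 2) {
    stop("need >= 2 signature genes present in the matrix", call. = FALSE)
  }
  v <- expr_values(expr)[genes, , drop = FALSE]
  r <- suppressWarnings(stats::cor(v))
  r[is.na(r)] <- 0                      # zero-variance patients: neutral
  hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
  tibble::tibble(patient = colnames(v),
                 cluster = unname(stats::cutree(hc, k = 2)[colnames(v)]))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square over the event times (observed minus
#' expected deaths, hypergeometric variance), with the p-value from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param cohort tibble `patient`, `time`, `event`.
#' @param partition tibble `patient`, `cluster` covering the cohort.
#' @return list `statistic`, `p`, `n`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(cohort, partition) {
  d <- dplyr::inner_join(cohort, partition, by = "patient")
  if (length(unique(d$cluster)) != 2) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ cluster,
                               data = d)
  list(statistic = unname(sd_fit$chisq),
       p = stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
       n = nrow(d), observed = unname(sd_fit$obs),
       expected = unname(sd_fit$exp))
}

#' Screen subnetworks for survival separation
#'
#' For every subnetwork: partition the patients on its genes and log-rank
#' test the two groups; subnetworks with `p < alpha` are marked significant.
#'
#' @param subnets tibble from [detect_subnetworks()] (possibly several
#'   classes bound together).
#' @param expr bulk training expression.
#' @param cohort training clinical tibble.
#' @param alpha screening level (default 0.05).
#' @return `subnets` plus `statistic`, `p`, `significant`.
#' @export
screen_subnetworks <- function(subnets, expr, cohort, alpha = 0.05) {
  if (nrow(subnets) == 0) {
    return(dplyr::mutate(subnets, statistic = numeric(), p = numeric(),
                         significant = logical()))
  }
  res <- purrr::map_dfr(subnets$genes, function(gs) {
    part <- cluster_patients_two_groups(expr, gs)
    lr <- logrank_test(cohort, part)
    tibble::tibble(statistic = lr$statistic, p = lr$p)
  })
  dplyr::bind_cols(subnets, res) |>
    dplyr::mutate(significant = .data$p < alpha)
}

#' Benjamini–Hochberg false discovery rate
#'
#' @param p numeric p-values in \[0, 1\].
#' @return BH-adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Mean silhouette width of a patient partition
#'
#' Silhouette over distance `1 - Pearson r` computed on the signature genes.
#' Patients in singleton groups get width 0 by convention.
#'
#' @param expr bulk `coex_expr`.
#' @param genes signature genes.
#' @param partition tibble `patient`, `cluster`.
#' @return list `mean`, `per_patient` (tibble `patient`, `cluster`, `width`).
#' @export
silhouette_width <- function(expr, genes, partition) {
  genes <- intersect(genes, expr_genes(expr))
  v <- expr_values(expr)[genes, partition$patient, drop = FALSE]
  r <- suppressWarnings(stats::cor(v))
  r[is.na(r)] <- 0
  sil <- cluster::silhouette(partition$cluster, stats::as.dist(1 - r))
  widths <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, nrow(partition))
  list(mean = mean(widths),
       per_patient = tibble::tibble(patient = partition$patient,
                                    cluster = partition$cluster,
                                    width = unname(widths)))
}

#' Search subnetwork combinations for the best survival signature
#'
#' Enumerates every combination of 1 to `max_combo` *significant*
#' subnetworks; each combination's union gene set is used to partition the
#' patients and log-rank tested. The winner has the smallest p (ties: fewer
#' genes, then lexicographic combination id). BH q-values are computed over
#' the full set of tested units — all screened singles plus all evaluated
#' combinations — and the winning partition's silhouette width is reported.
#'
#' @param screened output of [screen_subnetworks()].
#' @param expr bulk training expression.
#' @param cohort training clinical tibble.
#' @param max_combo maximal combination size (default 3).
#' @return a `coex_signature` list: `units` (tibble of every tested unit with
#'   `p` and `q`), `best` (list: `unit_id`, `subnetworks`, `genes`,
#'   `composition`, `partition`, `statistic`, `p`, `q`, `silhouette`), or
#'   `best = NULL` when nothing passed screening.
#' @export
combine_and_search <- function(screened, expr, cohort, max_combo = 3) {
  singles <- screened |>
    dplyr::mutate(unit_id = .data$subnetwork_id, combo_size = 1L)
  sig_ids <- screened$subnetwork_id[screened$significant]
  combos <- list()
  if (length(sig_ids) >= 2 && max_combo >= 2) {
    for (k in 2:min(max_combo, length(sig_ids))) {
      cmb <- utils::combn(sort(sig_ids), k, simplify = FALSE)
      combos <- c(combos, cmb)
    }
  }
  combo_rows <- purrr::map_dfr(combos, function(ids) {
    gs <- sort(unique(unlist(
      screened$genes[match(ids, screened$subnetwork_id)])))
    part <- cluster_patients_two_groups(expr, gs)
    lr <- logrank_test(cohort, part)
    tibble::tibble(unit_id = paste(ids, collapse = "+"),
                   class = NA_character_,
                   n_genes = length(gs), genes = list(gs),
                   statistic = lr$statistic, p = lr$p,
                   significant = NA, combo_size = length(ids))
  })
  if (nrow(combo_rows) == 0) {
    combo_rows <- tibble::tibble(unit_id = character(), class = character(),
                                 n_genes = integer(), genes = list(),
                                 statistic = numeric(), p = numeric(),
                                 significant = logical(),
                                 combo_size = integer())
  }
  units <- dplyr::bind_rows(
    singles[, c("unit_id", "class", "n_genes", "genes", "statistic", "p",
                "significant", "combo_size")],
    combo_rows)
  units$q <- bh_fdr(units$p)

  best <- NULL
  candidates <- units[units$unit_id %in% c(sig_ids, combo_rows$unit_id), ]
  if (nrow(candidates) > 0) {
    ord <- order(candidates$p, candidates$n_genes, candidates$unit_id)
    win <- candidates[ord[1], ]
    genes <- win$genes[[1]]
    part <- cluster_patients_two_groups(expr, genes)
    sil <- silhouette_width(expr, genes, part)
    member_ids <- strsplit(win$unit_id, "+", fixed = TRUE)[[1]]
    comp <- screened |>
      dplyr::filter(.data$subnetwork_id %in% member_ids) |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(n_genes = sum(.data$n_genes), .groups = "drop")
    best <- list(unit_id = win$unit_id, subnetworks = member_ids,
                 genes = genes, composition = comp,
                 partition = part, statistic = win$statistic,
                 p = win$p, q = win$q, silhouette = sil$mean)
  }
  structure(list(units = units, best = best), class = "coex_signature")
}

#' @export
print.coex_signature <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<coex_signature: no subnetwork passed screening>\n")
  } else {
    comp <- paste(sprintf("%d %s", x$best$composition$n_genes,
                          x$best$composition$class), collapse = " + ")
    cat(sprintf(paste0("<coex_signature: best unit %s (%s; %d genes), ",
                       "log-rank p = %.3g, q = %.3g, silhouette = %.2f>\n"),
                x$best$unit_id, comp, length(x$best$genes), x$best$p,
                x$best$q, x$best$silhouette))
  }
  invisible(x)
}

#' Align two expression platforms on a shared reference sample
#'
#' Each platform's log-scale matrix is shifted by subtracting the scalar
#' average expression of the reference sample as measured on that platform,
#' putting both platforms on a common location scale.
#'
#' @param expr_a,expr_b `coex_expr` matrices (log scale) both containing
#'   `reference_sample_id` among their samples.
#' @param reference_sample_id the bridging sample.
#' @return list `a`, `b` of shifted matrices.
#' @export
normalize_cross_platform <- function(expr_a, expr_b, reference_sample_id) {
  shift <- function(m) {
    if (!reference_sample_id %in% expr_samples(m)) {
      stop(sprintf("reference sample '%s' missing", reference_sample_id),
           call. = FALSE)
    }
    v <- expr_values(m)
    replace_values(m, v - mean(v[, reference_sample_id]))
  }
  list(a = shift(expr_a), b = shift(expr_b))
}

#' Nearest shrunken centroid classification
#'
#' Class centroids are shrunk toward the overall centroid by soft
#' thresholding of the standardized centroid differences (offset `s0` = the
#' median pooled within-class standard deviation); test samples are assigned
#' to the class with the smallest shrunken discriminant score. The shrinkage
#' `delta` is chosen by cross-validated training accuracy when not supplied.
#'
#' @param train_expr,test_expr `coex_expr` matrices sharing the signature
#'   genes.
#' @param train_labels tibble `patient`, `cluster` for the training columns.
#' @param genes signature genes.
#' @param delta shrinkage threshold; `NULL` picks it by `n_folds`-fold CV
#'   over `delta_grid`.
#' @param delta_grid candidate shrinkage values.
#' @param n_folds CV folds (default 5).
#' @param seed seed for the CV fold assignment.
#' @return tibble `patient`, `cluster` for the test samples, with the chosen
#'   `delta` as an attribute.
#' @export
nsc_classify <- function(train_expr, train_labels, test_expr, genes,
                         delta = NULL, delta_grid = seq(0, 2, by = 0.25),
                         n_folds = 5, seed = 1L) {
  genes <- Reduce(intersect, list(genes, expr_genes(train_expr),
                                  expr_genes(test_expr)))
  if (length(genes) < 1) stop("no signature genes shared", call. = FALSE)
  xtr <- expr_values(train_expr)[genes, train_labels$patient, drop = FALSE]
  y <- train_labels$cluster
  if (length(unique(y)) < 2) {
    stop("training labels must contain two classes", call. = FALSE)
  }
  if (is.null(delta)) {
    folds <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds),
                                                   ncol(xtr))))
    acc <- vapply(delta_grid, function(d) {
      mean(vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2 || sum(!tr) == 0) {
          return(NA_real_)
        }
        fit <- nsc_fit(xtr[, tr, drop = FALSE], y[tr], d)
        mean(nsc_predict(fit, xtr[, !tr, drop = FALSE]) == y[!tr])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    delta <- delta_grid[which.max(acc)]
  }
  fit <- nsc_fit(xtr, y, delta)
  xte <- expr_values(test_expr)[genes, , drop = FALSE]
  pred <- nsc_predict(fit, xte)
  structure(tibble::tibble(patient = colnames(xte), cluster = unname(pred)),
            delta = delta)
}

nsc_fit <- function(x, y, delta) {
  classes <- sort(unique(y))
  n <- ncol(x)
  overall <- rowMeans(x)
  cent <- vapply(classes, function(k) rowMeans(x[, y == k, drop = FALSE]),
                 numeric(nrow(x)))
  nk <- vapply(classes, function(k) sum(y == k), numeric(1))
  # pooled within-class sd with the usual offset s0
  ss <- rowSums(vapply(seq_along(classes), function(i) {
    rowSums((x[, y == classes[i], drop = FALSE] - cent[, i])^2)
  }, numeric(nrow(x))))
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  d_stat <- sweep(cent - overall, 2, mk, "/") / (s + s0)
  d_shrunk <- sign(d_stat) * pmax(abs(d_stat) - delta, 0)
  cent_shrunk <- overall + sweep(d_shrunk * (s + s0), 2, mk, "*")
  prior <- nk / n
  list(classes = classes, centroids = cent_shrunk, s = s, s0 = s0,
       prior = prior)
}

nsc_predict <- function(fit, x) {
  scores <- vapply(seq_along(fit$classes), function(i) {
    colSums((x - fit$centroids[, i])^2 / (fit$s + fit$s0)^2) -
      2 * log(fit$prior[i])
  }, numeric(ncol(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  fit$classes[apply(scores, 1, which.min)]
}

#' Kaplan–Meier curve table for a partitioned cohort
#'
#' @param cohort tibble `patient`, `time`, `event`.
#' @param partition tibble `patient`, `cluster`.
#' @return tibble `cluster`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_table <- function(cohort, partition) {
  d <- dplyr::inner_join(cohort, partition, by = "patient")
  fit <- survival::survfit(survival::Surv(time, event) ~ cluster, data = d)
  strata <- rep(names(fit$strata) %||% "cluster=1", fit$strata %||%
                  length(fit$time))
  tibble::tibble(cluster = as.integer(sub("cluster=", "", strata)),
                 time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, survival = fit$surv)
}
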