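#' Fraction of gene pairs with a protein-protein interaction
#'
#' @param pairs tibble with `gene_a`, `gene_b`.
#' @param ppi PPI edge list tibble (`gene_a`, `gene_b`, undirected).
#' @return fraction of `pairs` present in the edge set.
#' @export
ppi_fraction <- function(pairs, ppi) {
  if (nrow(pairs) == 0) stop("empty pair set", call. = FALSE)
  edges <- pair_key(ppi$gene_a, ppi$gene_b)
  if (any(ppi$gene_a == ppi$gene_b)) stop("self-edges in PPI", call. = FALSE)
  mean(pair_key(pairs$gene_a, pairs$gene_b) %in% edges)
}

#' Random-pair control for an observed pair-level fraction
#'
#' Draws `n_sets` sets of `set_size` gene pairs uniformly from all unordered
#' pairs of the universe and evaluates the hit fraction (PPI membership by
#' default, or any predicate) in each. Significance of the observed fraction
#' is reported both as the one-sample two-sided t-test of the control
#' fractions against the observed value and as the empirical two-sided
#' permutation p.
#'
#' @param universe character vector of genes, or a pair tibble to draw from.
#' @param observed observed fraction to test.
#' @param ppi PPI edge list (ignored when `hit_fun` is given).
#' @param n_sets,set_size control geometry (defaults 1000 x 1000).
#' @param seed integer seed.
#' @param hit_fun optional `function(pairs_tbl) logical-vector` marking hits.
#' @return a `coex_enrichment` list: `observed`, `control_mean`, `control_sd`,
#'   `fold`, `p_t`, `p_empirical`, `n_sets`, `set_size`, `control_fractions`.
#' @export
random_pair_control <- function(universe, observed, ppi = NULL,
                                n_sets = 1000, set_size = 1000, seed = 1L,
                                hit_fun = NULL) {
  if (is.null(hit_fun)) {
    edges <- pair_key(ppi$gene_a, ppi$gene_b)
    hit_fun <- function(p) pair_key(p$gene_a, p$gene_b) %in% edges
  }
  pool <- if (is.data.frame(universe)) universe else all_pairs(universe)
  if (nrow(pool) < set_size) {
    stop("universe has fewer pairs than `set_size`", call. = FALSE)
  }
  fracs <- withr::with_seed(seed, {
    vapply(seq_len(n_sets), function(i) {
      mean(hit_fun(pool[sample.int(nrow(pool), set_size), ]))
    }, numeric(1))
  })
  cm <- mean(fracs)
  p_t <- tryCatch(stats::t.test(fracs, mu = observed)$p.value,
                  error = function(e) NA_real_)
  p_emp <- (1 + 2 * min(sum(fracs >= observed), sum(fracs <= observed))) /
    (n_sets + 1)
  structure(list(observed = observed, control_mean = cm,
                 control_sd = stats::sd(fracs),
                 fold = if (cm > 0) observed / cm else NA_real_,
                 p_t = p_t, p_empirical = min(p_emp, 1),
                 n_sets = n_sets, set_size = set_size,
                 control_fractions = fracs),
            class = "coex_enrichment")
}

#' @export
print.coex_enrichment <- function(x, ...) {
  cat(sprintf(paste0("<coex_enrichment: observed %.4g vs control %.4g ",
                     "(%d x %d sets) = %.2f-fold, t-test p = %.3g>\n"),
              x$observed, x$control_mean, x$n_sets, x$set_size, x$fold,
              x$p_t))
  invisible(x)
}

#' PPI enrichment of one co-expression class against random pairs
#'
#' @param class_pairs pairs of one class (tibble `gene_a`, `gene_b`).
#' @param ppi PPI edge list.
#' @param universe gene universe to draw controls from.
#' @inheritParams random_pair_control
#' @return a `coex_enrichment`.
#' @export
ppi_enrichment <- function(class_pairs, ppi, universe, n_sets = 1000,
                           set_size = 1000, seed = 1L) {
  random_pair_control(universe, observed = ppi_fraction(class_pairs, ppi),
                      ppi = ppi, n_sets = n_sets, set_size = set_size,
                      seed = seed)
}

#' Per-bin PPI fraction across correlation strength
#'
#' Pairs are grouped into half-open correlation bins `[k/10, (k+1)/10)` of
#' width 0.1 on the class-defining correlation (`r_sc` for sc_specific,
#' `r_bulk` for bulk_specific, `pmin(r_sc, r_bulk)` — the limiting level —
#' for shared) and the PPI fraction is computed per class and bin. Bins with
#' fewer than 20 pairs are flagged `low_support`.
#'
#' @param class_table a `coex_class_table`.
#' @param ppi PPI edge list.
#' @param min_support support threshold for the flag (default 20).
#' @return tibble `class`, `bin_lo`, `bin_hi`, `n_pairs`, `ppi_fraction`,
#'   `low_support`.
#' @export
binned_fraction_by_r <- function(class_table, ppi, min_support = 20) {
  edges <- pair_key(ppi$gene_a, ppi$gene_b)
  tb <- class_table |>
    dplyr::filter(.data$class != "other") |>
    dplyr::mutate(
      r_class = dplyr::case_when(
        .data$class == "sc_specific" ~ .data$r_sc,
        .data$class == "bulk_specific" ~ .data$r_bulk,
        TRUE ~ pmin(.data$r_sc, .data$r_bulk)),
      bin_lo = floor(round(.data$r_class * 10, 9)) / 10,
      has_ppi = pair_key(.data$gene_a, .data$gene_b) %in% edges)
  tb |>
    dplyr::group_by(.data$class, .data$bin_lo) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     ppi_fraction = mean(.data$has_ppi), .groups = "drop") |>
    dplyr::mutate(bin_hi = .data$bin_lo + 0.1,
                  low_support = .data$n_pairs < min_support) |>
    dplyr::select("class", "bin_lo", "bin_hi", "n_pairs", "ppi_fraction",
                  "low_support") |>
    dplyr::arrange(.data$class, .data$bin_lo)
}

#' Distribution of co-expression classes inside protein complexes
#'
#' For each complex, counts the internal gene pairs falling in each
#' co-expression class and reports the dominant class (maximum count; ties
#' give `"mixed"`, no co-expressed internal pair gives `"none"`) and the
#' dominant class's fraction of the complex's co-expressed internal pairs.
#' Complexes with fewer than 2 members inside the analyzed gene universe are
#' skipped with a message.
#'
#' @param class_table a `coex_class_table`.
#' @param complexes complex catalog tibble (`complex_id`, `gene`).
#' @return tibble `complex_id`, `n_members`, `n_internal_pairs`,
#'   `n_shared`, `n_sc_specific`, `n_bulk_specific`, `dominant_class`,
#'   `dominant_fraction`.
#' @export
complex_coexpression_map <- function(class_table, complexes) {
  universe <- unique(c(class_table$gene_a, class_table$gene_b))
  cls <- stats::setNames(class_table$class,
                         pair_key(class_table$gene_a, class_table$gene_b))
  out <- purrr::map_dfr(split(complexes$gene, complexes$complex_id),
                        function(gs) {
    gs <- intersect(gs, universe)
    if (length(gs) < 2) {
      return(tibble::tibble())
    }
    pk <- with(all_pairs(gs), pair_key(gene_a, gene_b))
    pc <- cls[pk]
    counts <- c(shared = sum(pc == "shared", na.rm = TRUE),
                sc_specific = sum(pc == "sc_specific", na.rm = TRUE),
                bulk_specific = sum(pc == "bulk_specific", na.rm = TRUE))
    total <- sum(counts)
    dominant <- if (total == 0) {
      "none"
    } else if (sum(counts == max(counts)) > 1) {
      "mixed"
    } else {
      names(counts)[which.max(counts)]
    }
    tibble::tibble(n_members = length(gs),
                   n_internal_pairs = length(pk),
                   n_shared = counts[["shared"]],
                   n_sc_specific = counts[["sc_specific"]],
                   n_bulk_specific = counts[["bulk_specific"]],
                   dominant_class = dominant,
                   dominant_fraction = if (total > 0) {
                     max(counts) / total
                   } else {
                     NA_real_
                   })
  }, .id = "complex_id")
  skipped <- setdiff(unique(complexes$complex_id), out$complex_id)
  if (length(skipped) > 0) {
    message(sprintf("skipped %d complexes with < 2 members in universe",
                    length(skipped)))
  }
  out
}
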