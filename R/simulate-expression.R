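#' Simulate paired single-cell and bulk expression with planted co-expression
#'
#' Generates a single-cell matrix, a bulk matrix and (when `n_validation > 0`)
#' a cross-platform validation matrix over one gene universe, with ground
#' truth for every planted structure:
#'
#' * independent planted pairs per class (`shared`, `sc_only`, `bulk_only`),
#'   each driven by a shared latent factor `x = sqrt(rho) z + sqrt(1-rho) e`
#'   at its planted level(s) and pure noise at the other level;
#' * one planted protein-complex clique per entry of `complex_classes`, whose
#'   internal pairs all carry the complex's class;
#' * a prognostic module of `module_size` genes, co-expressed at both levels,
#'   whose bulk expression additionally carries a +/- direction pattern tied to
#'   a latent two-group patient partition (the survival signal downstream).
#'
#' Values are exported RPKM-like (`2^x - 1` clipped at 0); single-cell entries
#' are zeroed with probability `dropout_rate` before export. The validation
#' matrix emulates a second platform: log2-scale intensities shifted by
#' `platform_offset`, including a re-profiled copy of the first training
#' patient to serve as the cross-platform reference sample.
#'
#' @param config a [sim_config()].
#' @return list with elements `sc`, `bulk` (`coex_expr`, state `raw_rpkm`),
#'   `microarray` (`coex_expr`, state `log2`, or `NULL`), and `truth` (class
#'   `coex_truth`): `pair_labels` (tibble gene_a/gene_b/label), `modules`
#'   (tibble module_id/class/gene), `prognostic_module` (character),
#'   `patient_group` (tibble patient/cohort/group), `genes`, and
#'   `reference_sample`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "coex_sim_config"))
  withr::with_seed(child_seed(config$seed, 1L), {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    cells <- sprintf("c%03d", seq_len(config$n_cells))
    patients <- sprintf("p%03d", seq_len(config$n_bulk))
    vpatients <- if (config$n_validation > 0) {
      sprintf("v%03d", seq_len(config$n_validation))
    } else {
      character()
    }

    plan <- plant_structures(config, genes)

    # latent two-group patient partition (balanced, shuffled)
    grp <- function(n) sample(rep_len(c("high_risk", "low_risk"), n))
    patient_group <- tibble::tibble(
      patient = c(patients, vpatients),
      cohort = c(rep("training", length(patients)),
                 rep("validation", length(vpatients))),
      group = c(grp(length(patients)), grp(length(vpatients))))

    u_sc <- latent_deviates(plan, config, n = config$n_cells,
                            level = "single_cell", group_sign = NULL)
    s_train <- ifelse(patient_group$group[patient_group$cohort == "training"]
                      == "high_risk", 1, -1)
    u_bulk <- latent_deviates(plan, config, n = config$n_bulk,
                              level = "bulk", group_sign = s_train)
    dimnames(u_sc) <- list(genes, cells)
    dimnames(u_bulk) <- list(genes, patients)

    # export scale: log2 -> RPKM-like
    x_sc <- config$baseline_log_mean + config$baseline_log_sd * u_sc
    x_bulk <- config$bulk_log_mean + config$baseline_log_sd * u_bulk
    rpkm_sc <- pmax(2^x_sc - 1, 0)
    rpkm_bulk <- pmax(2^x_bulk - 1, 0)
    drop_mask <- matrix(stats::runif(length(rpkm_sc)) < config$dropout_rate,
                        nrow = nrow(rpkm_sc))
    rpkm_sc[drop_mask] <- 0

    microarray <- NULL
    reference_sample <- NA_character_
    if (config$n_validation > 0) {
      s_val <- ifelse(patient_group$group[patient_group$cohort == "validation"]
                      == "high_risk", 1, -1)
      u_val <- latent_deviates(plan, config, n = config$n_validation,
                               level = "bulk", group_sign = s_val)
      dimnames(u_val) <- list(genes, vpatients)
      x_val <- config$bulk_log_mean + config$baseline_log_sd * u_val +
        config$platform_offset
      # the first training patient re-profiled on the second platform:
      # same biological signal, platform shift plus small technical noise
      reference_sample <- patients[1]
      x_ref <- x_bulk[, reference_sample] + config$platform_offset +
        stats::rnorm(config$n_genes, sd = 0.2)
      x_val <- cbind(x_ref, x_val)
      colnames(x_val) <- c(reference_sample, vpatients)
      rownames(x_val) <- genes
      microarray <- expression_matrix(x_val, level = "bulk", state = "log2")
    }

    truth <- structure(list(
      pair_labels = plan$pair_labels,
      modules = plan$modules,
      prognostic_module = plan$prognostic_module,
      patient_group = patient_group,
      genes = genes,
      reference_sample = reference_sample
    ), class = "coex_truth")

    list(sc = expression_matrix(rpkm_sc, "single_cell", "raw_rpkm"),
         bulk = expression_matrix(rpkm_bulk, "bulk", "raw_rpkm"),
         microarray = microarray,
         truth = truth)
  })
}

# allocate gene-disjoint planted structures over the universe
plant_structures <- function(config, genes) {
  pool <- sample(genes)            # random placement of structures
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }

  modules <- tibble::tibble(module_id = character(), class = character(),
                            gene = character())
  prognostic <- character()
  if (config$module_size > 0) {
    prognostic <- sort(take(config$module_size))
    modules <- dplyr::bind_rows(modules, tibble::tibble(
      module_id = "prognostic", class = "shared", gene = prognostic))
  }
  for (i in seq_along(config$complex_classes)) {
    modules <- dplyr::bind_rows(modules, tibble::tibble(
      module_id = sprintf("complex_%02d", i),
      class = config$complex_classes[i],
      gene = sort(take(config$complex_size))))
  }

  pair_block <- function(n, label) {
    if (n == 0) {
      return(tibble::tibble(gene_a = character(), gene_b = character(),
                            label = character(), pair_id = integer()))
    }
    g <- take(2L * n)
    orient_pairs(tibble::tibble(gene_a = g[seq_len(n)],
                                gene_b = g[n + seq_len(n)],
                                label = label, pair_id = seq_len(n)))
  }
  planted_pairs <- dplyr::bind_rows(
    pair_block(config$n_planted_shared, "shared"),
    pair_block(config$n_planted_sc_only, "sc_only"),
    pair_block(config$n_planted_bulk_only, "bulk_only"))

  module_pair_labels <- if (nrow(modules) == 0) {
    tibble::tibble(gene_a = character(), gene_b = character(),
                   label = character())
  } else {
    modules |>
      dplyr::group_by(.data$module_id, .data$class) |>
      dplyr::summarise(pairs = list(all_pairs(.data$gene)),
                       .groups = "drop") |>
      tidyr::unnest("pairs") |>
      dplyr::transmute(.data$gene_a, .data$gene_b, label = .data$class)
  }

  pair_labels <- dplyr::bind_rows(
    planted_pairs[, c("gene_a", "gene_b", "label")], module_pair_labels)

  list(pair_labels = pair_labels,
       planted_pairs = planted_pairs,
       modules = modules,
       prognostic_module = prognostic)
}

# unit-variance latent deviates (genes x samples) realizing the planted
# structure at one level; group_sign (+1 high risk / -1 low) feeds the
# prognostic module's bulk pattern factor
latent_deviates <- function(plan, config, n, level, group_sign = NULL) {
  u <- matrix(stats::rnorm(config$n_genes * n), nrow = config$n_genes)
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  idx <- function(g) match(g, gene_ids)

  rho <- config$rho
  planted_here <- function(label) {
    label == "shared" ||
      (label == "sc_only" && level == "single_cell") ||
      (label == "bulk_only" && level == "bulk")
  }

  pp <- plan$planted_pairs
  for (i in seq_len(nrow(pp))) {
    if (!planted_here(pp$label[i])) next
    z <- stats::rnorm(n)
    for (g in c(pp$gene_a[i], pp$gene_b[i])) {
      u[idx(g), ] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
    }
  }

  mods <- split(plan$modules$gene, plan$modules$module_id)
  mod_class <- plan$modules |>
    dplyr::distinct(.data$module_id, .data$class)
  for (m in names(mods)) {
    cls <- mod_class$class[mod_class$module_id == m]
    mgenes <- mods[[m]]
    if (m == "prognostic" && level == "bulk") {
      # common factor + direction pattern carrying the latent risk group
      alpha <- config$group_sep
      w <- alpha * group_sign + sqrt(1 - alpha^2) * stats::rnorm(n)
      z <- stats::rnorm(n)
      d <- rep_len(c(1, -1), length(mgenes))
      for (j in seq_along(mgenes)) {
        u[idx(mgenes[j]), ] <- sqrt(config$module_common_rho) * z +
          d[j] * sqrt(config$module_pattern_rho) * w +
          sqrt(1 - config$module_common_rho - config$module_pattern_rho) *
            stats::rnorm(n)
      }
    } else if (planted_here(cls) || m == "prognostic") {
      z <- stats::rnorm(n)
      for (g in mgenes) {
        u[idx(g), ] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
      }
    }
  }
  u
}

#' @export
print.coex_truth <- function(x, ...) {
  cat(sprintf(paste0("<coex_truth: %d planted pair labels, %d modules, ",
                     "%d-gene prognostic module, %d patients>\n"),
              nrow(x$pair_labels), length(unique(x$modules$module_id)),
              length(x$prognostic_module), nrow(x$patient_group)))
  invisible(x)
}
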