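#' Pipeline run configuration
#'
#' Bundles the generator configuration with every stage threshold. All
#' randomness derives deterministically from the single root seed in
#' `sim$seed`.
#'
#' @param sim a [sim_config()] describing the synthetic dataset (or the seed
#'   carrier for a run on files).
#' @param stages subset of
#'   `c("preprocess", "correlate", "classify", "enrich", "regulatory",
#'   "survival")`.
#' @param n_reps shuffle replicates per level for the null.
#' @param pos_tail,nocorr_mass,tail_method threshold parameters
#'   (see [derive_thresholds()]).
#' @param top_k size of the per-level top pair lists.
#' @param control_sets,control_size random-pair control geometry.
#' @param min_mean,max_zero_fraction preprocessing filter cutoffs.
#' @param alpha,max_combo,min_size survival-search parameters.
#' @param flank contact region extension (bp).
#' @param outdir optional directory for the report JSON and stage tables.
#' @return a `coex_run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("preprocess", "correlate", "classify",
                                  "enrich", "regulatory", "survival"),
                       n_reps = 1000, pos_tail = 1e-6, nocorr_mass = 0.3,
                       tail_method = "auto", top_k = 1000,
                       control_sets = 1000, control_size = 1000,
                       min_mean = 100, max_zero_fraction = 2 / 3,
                       alpha = 0.05, max_combo = 3, min_size = 3,
                       flank = 5000, outdir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(sim = sim, stages = stages, n_reps = n_reps,
                 pos_tail = pos_tail, nocorr_mass = nocorr_mass,
                 tail_method = tail_method, top_k = top_k,
                 control_sets = control_sets, control_size = control_size,
                 min_mean = min_mean, max_zero_fraction = max_zero_fraction,
                 alpha = alpha, max_combo = max_combo, min_size = min_size,
                 flank = flank, outdir = outdir),
            class = "coex_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `sim:` (passed to [sim_config()]) and any argument of
#' [run_config()].
#'
#' @param path YAML file.
#' @return a `coex_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  y$sim <- NULL
  do.call(run_config, c(list(sim = sim), y))
}

#' Run the full comparative co-expression pipeline on synthetic data
#'
#' Executes, in order: simulate, preprocess, correlate, classify, enrich,
#' regulatory, survival (each after the first skippable through
#' `config$stages`), and returns a machine-readable report together with the
#' intermediate objects. Stage failures abort with a stage-tagged error.
#' When `config$outdir` is set, the report is written as `report.json`
#' (stable across runs with the same seed).
#'
#' @param config a `coex_run_config`.
#' @return list `report` (plain list, JSON-ready), `data` (intermediate
#'   objects).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "coex_run_config"))
  seed <- config$sim$seed
  report <- list(seed = seed,
                 settings = config[setdiff(names(config),
                                           c("sim", "outdir"))])
  report$settings$sim <- unclass(config$sim)
  data <- list()

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  data$sim <- stage("simulate", function() simulate_dataset(config$sim))
  truth <- data$sim$truth

  if ("preprocess" %in% config$stages) {
    data$proc <- stage("preprocess", function() {
      preprocess_pipeline(data$sim$sc, data$sim$bulk,
                          min_mean = config$min_mean,
                          max_zero_fraction = config$max_zero_fraction)
    })
    report$preprocess <- list(
      n_genes_sc_in = nrow(data$sim$sc),
      n_genes_bulk_in = nrow(data$sim$bulk),
      n_genes_analyzed = nrow(data$proc$sc))
  } else {
    return(finish_report(report, data, config))
  }

  if ("correlate" %in% config$stages) {
    data$corr <- stage("correlate", function() {
      correlate_levels(data$proc$sc, data$proc$bulk)
    })
    k <- min(config$top_k, nrow(data$corr))
    top_sc <- top_k_pairs(data$corr, "single_cell", k)
    top_bulk <- top_k_pairs(data$corr, "bulk", k)
    shared_top <- length(intersect(
      pair_key(top_sc$gene_a, top_sc$gene_b),
      pair_key(top_bulk$gene_a, top_bulk$gene_b)))
    data$top <- list(sc = top_sc, bulk = top_bulk)
    report$correlate <- list(
      n_pairs = nrow(data$corr), top_k = k,
      top_k_overlap = shared_top,
      top_k_overlap_fraction = shared_top / k,
      split_half_overlap_sc = as.integer(
        split_half_overlap(data$proc$sc, k = k,
                           seed = child_seed(seed, 20L))))
  }

  if ("classify" %in% config$stages) {
    data$nulls <- stage("classify", function() {
      list(sc = build_null(data$proc$sc, n_reps = config$n_reps,
                           seed = child_seed(seed, 21L)),
           bulk = build_null(data$proc$bulk, n_reps = config$n_reps,
                             seed = child_seed(seed, 22L)))
    })
    th <- suppressWarnings(
      derive_thresholds(data$nulls$sc, data$nulls$bulk,
                        pos_tail = config$pos_tail,
                        nocorr_mass_per_side = config$nocorr_mass,
                        tail_method = config$tail_method))
    data$thresholds <- th
    data$classes <- classify_pairs(data$corr, th)
    counts <- table(data$classes$class)
    report$classify <- list(
      thresholds = as.list(tibble::as_tibble(th)),
      class_counts = as.list(counts))
  }

  if ("enrich" %in% config$stages) {
    ann <- data$sim$annotations
    universe <- data$proc$sc$gene
    class_pairs <- split(data$classes,
                         data$classes$class)[c("shared", "sc_specific",
                                               "bulk_specific")]
    report$enrich <- stage("enrich", function() {
      enr <- purrr::imap(class_pairs, function(p, cls) {
        if (is.null(p) || nrow(p) == 0) {
          return(NULL)
        }
        e <- ppi_enrichment(p, ann$ppi, universe,
                            n_sets = config$control_sets,
                            set_size = config$control_size,
                            seed = child_seed(seed, 30L))
        g <- go_similarity_fraction(p, ann$terms, universe,
                                    n_sets = min(config$control_sets, 100),
                                    set_size = min(config$control_size, 500),
                                    seed = child_seed(seed, 31L))
        list(n_pairs = nrow(p), ppi_fraction = e$observed,
             ppi_control = e$control_mean, ppi_fold = e$fold,
             ppi_p = e$p_t,
             go_fraction = g$observed, go_control = g$control_mean,
             go_fold = g$fold)
      })
      cmap <- complex_coexpression_map(data$classes, ann$complexes)
      list(classes = enr,
           complexes = as.list(cmap[, c("complex_id", "dominant_class",
                                        "dominant_fraction")]))
    })
  }

  if ("regulatory" %in% config$stages) {
    ann <- data$sim$annotations
    report$regulatory <- stage("regulatory", function() {
      cls_tb <- data$classes[data$classes$class != "other", ]
      dhs <- dhs_correlation(cls_tb, ann$dhs)
      contact <- intra_inter_contact_enrichment(cls_tb, ann$layout,
                                                ann$contacts,
                                                flank = config$flank)
      by_cls <- split(cls_tb, cls_tb$class)
      same_chrom <- purrr::imap(by_cls, function(p, cls) {
        if (nrow(p) == 0) {
          return(NULL)
        }
        sc <- same_chromosome_fraction(p, ann$layout)
        chrom <- stats::setNames(ann$layout$chrom, ann$layout$gene)
        intra <- p[chrom[p$gene_a] == chrom[p$gene_b], ]
        tad <- if (nrow(intra) > 0) {
          same_tad_fraction(intra, ann$layout)$fraction
        } else {
          NA_real_
        }
        list(n = sc$n, same_chromosome = sc$fraction,
             control = sc$control_fraction, same_tad_intra = tad)
      })
      list(dhs_modes = if (!is.null(dhs$summary)) {
        as.list(dhs$summary)
      },
      same_chromosome = same_chrom,
      contacts = as.list(contact))
    })
  }

  if ("survival" %in% config$stages) {
    report$survival <- stage("survival", function() {
      surv_stage(data, config, truth)
    })
    data$signature <- attr(report$survival, "signature")
    attr(report$survival, "signature") <- NULL
  }

  finish_report(report, data, config)
}

surv_stage <- function(data, config, truth) {
  cohort <- data$sim$cohort
  nets <- lapply(c(shared = "shared", sc_specific = "sc_specific",
                   bulk_specific = "bulk_specific"), function(cls) {
    suppressWarnings(build_class_network(data$classes, cls))
  })
  subnets <- purrr::imap_dfr(nets, function(g, cls) {
    detect_subnetworks(g, min_size = config$min_size, class = cls)
  })
  # patient partitions use log2 bulk expression (pre-centering), the scale
  # the cross-platform reference normalization is defined on
  bulk_log <- log2_plus_one(data$sim$bulk)
  screened <- screen_subnetworks(subnets, bulk_log, cohort$training,
                                 alpha = config$alpha)
  sig <- combine_and_search(screened, bulk_log, cohort$training,
                            max_combo = config$max_combo)
  out <- list(n_subnetworks = as.list(table(subnets$class)),
              n_significant = sum(screened$significant))
  if (!is.null(sig$best)) {
    out$best <- list(
      unit = sig$best$unit_id,
      genes = sig$best$genes,
      composition = as.list(sig$best$composition),
      logrank_p = sig$best$p, q = sig$best$q,
      silhouette = sig$best$silhouette)
    if (!is.null(data$sim$microarray) && nrow(cohort$validation) > 0) {
      aligned <- normalize_cross_platform(bulk_log, data$sim$microarray,
                                          truth$reference_sample)
      pred <- nsc_classify(aligned$a, sig$best$partition, aligned$b,
                           sig$best$genes,
                           seed = child_seed(config$sim$seed, 40L))
      vlr <- tryCatch(logrank_test(cohort$validation, pred),
                      error = function(e) NULL)
      out$validation <- if (is.null(vlr)) {
        list(n = nrow(cohort$validation), logrank_p = NA_real_,
             delta = attr(pred, "delta"),
             note = "degenerate one-group prediction")
      } else {
        list(n = vlr$n, logrank_p = vlr$p, delta = attr(pred, "delta"))
      }
    }
  }
  attr(out, "signature") <- sig
  out
}

finish_report <- function(report, data, config) {
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, data = data)
}
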