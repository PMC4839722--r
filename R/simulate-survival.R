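#' Simulate survival outcomes tied to the planted patient groups
#'
#' Event times are exponential: the low-risk group has median
#' `median_survival_days` and the high-risk group a hazard `hazard_ratio`
#' times larger. Censoring is independent exponential with its rate solved
#' numerically so the expected censored fraction equals `censor_fraction`
#' (`censor_fraction = 0` disables censoring). Training and validation
#' cohorts are generated for every patient in `truth$patient_group`.
#'
#' @param config a [sim_config()].
#' @param truth the `coex_truth` from [simulate_expression()].
#' @return a `coex_cohort` list with tibbles `training` and `validation`
#'   (columns patient, time, event, group).
#' @export
simulate_survival <- function(config, truth) {
  stopifnot(inherits(config, "coex_sim_config"), inherits(truth, "coex_truth"))
  if (config$hazard_ratio <= 0) {
    stop("`hazard_ratio` must be > 0", call. = FALSE)
  }
  withr::with_seed(child_seed(config$seed, 3L), {
    lam_low <- log(2) / config$median_survival_days
    lam <- c(low_risk = lam_low,
             high_risk = lam_low * config$hazard_ratio)

    draw <- function(pg) {
      n <- nrow(pg)
      if (n == 0) {
        return(tibble::tibble(patient = character(), time = numeric(),
                              event = integer(), group = character()))
      }
      rate <- lam[pg$group]
      t_event <- stats::rexp(n, rate)
      if (config$censor_fraction > 0) {
        # solve the censoring rate c: mean_g P(cens | g) = target, with
        # P(cens) = c / (c + lambda_g) under independent exponentials
        target <- config$censor_fraction
        f <- function(cc) mean(cc / (cc + rate)) - target
        cc <- stats::uniroot(f, lower = 1e-12, upper = 1e6 * max(lam),
                             tol = 1e-12)$root
        t_cens <- stats::rexp(n, cc)
        tibble::tibble(patient = pg$patient,
                       time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens),
                       group = pg$group)
      } else {
        tibble::tibble(patient = pg$patient, time = t_event,
                       event = 1L, group = pg$group)
      }
    }
    pg <- truth$patient_group
    structure(list(
      training = draw(pg[pg$cohort == "training", ]),
      validation = draw(pg[pg$cohort == "validation", ])
    ), class = "coex_cohort")
  })
}

#' @export
print.coex_cohort <- function(x, ...) {
  cat(sprintf(paste0("<coex_cohort: %d training (%d events), ",
                     "%d validation (%d events)>\n"),
              nrow(x$training), sum(x$training$event),
              nrow(x$validation), sum(x$validation$event)))
  invisible(x)
}

#' Run the full synthetic generator and optionally write all inputs to disk
#'
#' Convenience wrapper around [simulate_expression()],
#' [simulate_annotations()] and [simulate_survival()]. When `outdir` is given,
#' every input is written in its plain-text exchange format: expression TSVs
#' (+ provenance sidecars), PPI edge list, complex catalog, term DAG and
#' annotation tables, genome layout (1-based inclusive coordinates), TAD BED
#' (0-based half-open), DHS matrix, contact pairs, clinical tables, and the
#' ground truth as JSON.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @return list with `sc`, `bulk`, `microarray`, `truth`, `annotations`,
#'   `cohort`.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  expr <- simulate_expression(config)
  ann <- simulate_annotations(config, expr$truth)
  cohort <- simulate_survival(config, expr$truth)
  out <- c(expr, list(annotations = ann, cohort = cohort))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_expression_tsv(expr$sc, p("expression_sc.tsv"))
    write_expression_tsv(expr$bulk, p("expression_bulk.tsv"))
    if (!is.null(expr$microarray)) {
      write_expression_tsv(expr$microarray, p("expression_microarray.tsv"))
    }
    readr::write_tsv(ann$ppi, p("ppi_edges.tsv"), progress = FALSE)
    readr::write_tsv(ann$complexes, p("complexes.tsv"), progress = FALSE)
    readr::write_tsv(ann$terms$dag, p("term_dag.tsv"), progress = FALSE)
    readr::write_tsv(ann$terms$annotation, p("term_annotation.tsv"),
                     progress = FALSE)
    write_layout_tsv(ann$layout, p("genome_layout.tsv"))
    readr::write_tsv(ann$tads, p("tads.tsv"), progress = FALSE)
    readr::write_tsv(ann$dhs, p("dhs_matrix.tsv"), progress = FALSE)
    readr::write_tsv(ann$contacts, p("contacts.tsv"), progress = FALSE)
    readr::write_tsv(cohort$training, p("clinical_training.tsv"),
                     progress = FALSE)
    readr::write_tsv(cohort$validation, p("clinical_validation.tsv"),
                     progress = FALSE)
    truth_json <- list(
      pair_labels = expr$truth$pair_labels,
      modules = expr$truth$modules,
      prognostic_module = expr$truth$prognostic_module,
      patient_group = expr$truth$patient_group,
      reference_sample = expr$truth$reference_sample)
    jsonlite::write_json(truth_json, p("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
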