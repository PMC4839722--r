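#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults encode the
#' desk-scale study conditions: 300 genes measured in 200 single cells and 120
#' bulk tumors, 40 planted co-expressed pairs per class at target correlation
#' 0.9, 30% single-cell dropout, three planted protein-complex cliques, and a
#' six-gene prognostic module with hazard ratio 3 between the two latent
#' patient groups.
#'
#' Expression is generated on the log2 scale as
#' `location + spread * u`, where `u` is a unit-variance latent deviate built
#' from per-pair (or per-module) factors, `x = sqrt(rho) * z + sqrt(1-rho) * e`,
#' so a planted pair attains population correlation `rho` at its planted
#' level(s) and is independent noise at the other level. Values are exported
#' on an RPKM-like scale (`2^x - 1`, clipped at 0); single-cell entries are
#' then zeroed independently with probability `dropout_rate`.
#'
#' @param n_genes,n_cells,n_bulk matrix dimensions.
#' @param n_planted_shared,n_planted_sc_only,n_planted_bulk_only number of
#'   planted gene-disjoint pairs per class.
#' @param rho target pair correlation in (0,1) for every planted structure.
#' @param dropout_rate probability in \[0,1) that a single-cell entry is zeroed.
#' @param baseline_log_mean,baseline_log_sd log2-scale location and spread of
#'   single-cell expression.
#' @param bulk_log_mean log2-scale location of bulk expression (bulk shares
#'   `baseline_log_sd`); the default keeps mean RPKM well above the 100-RPKM
#'   bulk filter.
#' @param ppi_odds named odds (per class: shared, sc_only, bulk_only) of a PPI
#'   edge on a planted pair relative to background; scalars are recycled.
#' @param ppi_background background PPI edge probability.
#' @param term_coupling per-class probability that a planted pair is given a
#'   common ontology leaf term.
#' @param same_chrom_prob per-class probability that a planted structure is
#'   co-located on one chromosome.
#' @param same_tad_prob per-class probability, given same chromosome, that a
#'   planted structure falls in one topological domain.
#' @param dhs_rho cross-cell-type promoter-accessibility correlation planted on
#'   shared and bulk_only structures (0 = uncoupled).
#' @param contact_prob per-class probability that a planted pair receives a
#'   chromatin contact linking its two gene regions.
#' @param n_background_contacts random contacts independent of classes.
#' @param n_chromosomes,genome_tads_per_chrom genome layout geometry.
#' @param n_cell_types_dhs number of accessibility cell types (default 125).
#' @param complex_classes classes of the planted protein-complex cliques.
#' @param complex_size genes per planted complex clique.
#' @param module_size prognostic-module size (split into two equal direction
#'   halves; must be even and >= 4).
#' @param module_common_rho,module_pattern_rho variance shares of the module's
#'   bulk common factor and its group-pattern factor.
#' @param group_sep correlation in (0,1) between the module pattern factor and
#'   the latent risk group; larger = cleaner patient separation.
#' @param hazard_ratio relative hazard of the high-risk patient group (> 0).
#' @param censor_fraction expected censored fraction in \[0,1).
#' @param median_survival_days median survival of the low-risk group.
#' @param n_validation validation-cohort size (cross-platform profiles).
#' @param platform_offset constant log2-scale shift of the validation platform.
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @return a validated `coex_sim_config` list.
#' @export
sim_config <- function(n_genes = 300, n_cells = 200, n_bulk = 120,
                       n_planted_shared = 40, n_planted_sc_only = 40,
                       n_planted_bulk_only = 40,
                       rho = 0.9, dropout_rate = 0.3,
                       baseline_log_mean = 1, baseline_log_sd = 2,
                       bulk_log_mean = 8,
                       ppi_odds = c(shared = 27, sc_only = 5, bulk_only = 1.6),
                       ppi_background = 0.0034,
                       term_coupling = c(shared = 0.5, sc_only = 0,
                                         bulk_only = 0.25),
                       same_chrom_prob = c(shared = 0.17, sc_only = 0.05,
                                           bulk_only = 0.17),
                       same_tad_prob = c(shared = 0.3, sc_only = 0,
                                         bulk_only = 0.3),
                       dhs_rho = 0.8,
                       contact_prob = c(shared = 0.02, sc_only = 0.15,
                                        bulk_only = 0.15),
                       n_background_contacts = 200,
                       n_chromosomes = 20, genome_tads_per_chrom = 10,
                       n_cell_types_dhs = 125,
                       complex_classes = c("shared", "sc_only", "bulk_only"),
                       complex_size = 5,
                       module_size = 6,
                       module_common_rho = 0.75, module_pattern_rho = 0.2,
                       group_sep = 0.85,
                       hazard_ratio = 3, censor_fraction = 0.2,
                       median_survival_days = 400,
                       n_validation = 100, platform_offset = 1.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_cells = check_count(n_cells, "n_cells"),
    n_bulk = check_count(n_bulk, "n_bulk"),
    n_planted_shared = check_count(n_planted_shared, "n_planted_shared", 0L),
    n_planted_sc_only = check_count(n_planted_sc_only, "n_planted_sc_only", 0L),
    n_planted_bulk_only = check_count(n_planted_bulk_only,
                                      "n_planted_bulk_only", 0L),
    rho = rho, dropout_rate = check_prob(dropout_rate, "dropout_rate",
                                         open_hi = TRUE),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    bulk_log_mean = bulk_log_mean,
    ppi_odds = expand_class_vec(ppi_odds, "ppi_odds"),
    ppi_background = check_prob(ppi_background, "ppi_background",
                                open_lo = TRUE, open_hi = TRUE),
    term_coupling = expand_class_vec(term_coupling, "term_coupling"),
    same_chrom_prob = expand_class_vec(same_chrom_prob, "same_chrom_prob"),
    same_tad_prob = expand_class_vec(same_tad_prob, "same_tad_prob"),
    dhs_rho = check_prob(dhs_rho, "dhs_rho", open_hi = TRUE),
    contact_prob = expand_class_vec(contact_prob, "contact_prob"),
    n_background_contacts = check_count(n_background_contacts,
                                        "n_background_contacts", 0L),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    genome_tads_per_chrom = check_count(genome_tads_per_chrom,
                                        "genome_tads_per_chrom"),
    n_cell_types_dhs = check_count(n_cell_types_dhs, "n_cell_types_dhs", 3L),
    complex_classes = complex_classes,
    complex_size = check_count(complex_size, "complex_size", 2L),
    module_size = check_count(module_size, "module_size", 0L),
    module_common_rho = module_common_rho,
    module_pattern_rho = module_pattern_rho,
    group_sep = check_prob(group_sep, "group_sep", open_lo = TRUE,
                           open_hi = TRUE),
    hazard_ratio = hazard_ratio,
    censor_fraction = check_prob(censor_fraction, "censor_fraction",
                                 open_hi = TRUE),
    median_survival_days = median_survival_days,
    n_validation = check_count(n_validation, "n_validation", 0L),
    platform_offset = platform_offset,
    seed = check_count(seed, "seed", 0L)
  )
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1) {
    stop("`rho` must be strictly between 0 and 1", call. = FALSE)
  }
  if (hazard_ratio <= 0) stop("`hazard_ratio` must be > 0", call. = FALSE)
  if (any(cfg$ppi_odds <= 0)) stop("`ppi_odds` must be > 0", call. = FALSE)
  if (cfg$module_size > 0 &&
      (cfg$module_size < 4L || cfg$module_size %% 2L != 0L)) {
    stop("`module_size` must be 0 or an even number >= 4", call. = FALSE)
  }
  if (cfg$module_common_rho < 0 || cfg$module_pattern_rho < 0 ||
      cfg$module_common_rho + cfg$module_pattern_rho >= 1) {
    stop("module variance shares must be >= 0 and sum to < 1", call. = FALSE)
  }
  if (!all(cfg$complex_classes %in% c("shared", "sc_only", "bulk_only"))) {
    stop("`complex_classes` must be shared/sc_only/bulk_only", call. = FALSE)
  }
  # genes needed by planted structures must fit in (and stay disjoint within)
  # the gene universe
  need <- cfg$module_size + length(cfg$complex_classes) * cfg$complex_size +
    2L * (cfg$n_planted_shared + cfg$n_planted_sc_only + cfg$n_planted_bulk_only)
  if (need > cfg$n_genes) {
    stop(sprintf(paste0("planted structures need %d genes but n_genes = %d; ",
                        "planted pairs cannot be disjoint"),
                 need, cfg$n_genes), call. = FALSE)
  }
  structure(cfg, class = "coex_sim_config")
}

expand_class_vec <- function(x, name) {
  classes <- c("shared", "sc_only", "bulk_only")
  if (is.null(names(x)) && length(x) == 1L) {
    x <- stats::setNames(rep(as.numeric(x), 3L), classes)
  }
  if (!all(classes %in% names(x))) {
    stop(sprintf("`%s` must be a scalar or named for %s", name,
                 paste(classes, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(as.numeric(x[classes]), classes)
}

#' @export
print.coex_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<coex_sim_config: %d genes, %d cells, %d bulk; ",
                     "planted %d/%d/%d shared/sc/bulk pairs, rho=%g, ",
                     "dropout=%g, seed=%d>\n"),
              x$n_genes, x$n_cells, x$n_bulk, x$n_planted_shared,
              x$n_planted_sc_only, x$n_planted_bulk_only, x$rho,
              x$dropout_rate, x$seed))
  invisible(x)
}
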