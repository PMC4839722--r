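#' Simulate annotation inputs statistically coupled to planted classes
#'
#' Builds every annotation resource the downstream characterization stages
#' consume, with couplings to the planted co-expression classes controlled by
#' the configuration:
#'
#' * a PPI edge list: background pairs carry an edge with probability
#'   `ppi_background`; planted pairs of class `c` with probability `p1` such
#'   that `odds(p1)/odds(p0) = ppi_odds[c]`;
#' * a complex catalog: one complex per planted clique (whose internal pairs
#'   all carry the clique's class), plus the prognostic module;
#' * a small ontology: a single-root DAG (root -> mid terms -> leaf terms);
#'   every gene gets one leaf at random and coupled planted pairs share an
#'   extra common leaf with probability `term_coupling[c]`;
#' * a genome layout: genes placed on `n_chromosomes` chromosomes tiled by
#'   topological domains; planted structures co-located per
#'   `same_chrom_prob` / `same_tad_prob`;
#' * a promoter accessibility (DHS) matrix over `n_cell_types_dhs` cell types:
#'   shared and bulk_only structures get a common latent across cell types at
#'   correlation `dhs_rho`;
#' * a chromatin contact set: planted pairs of class `c` receive a contact
#'   joining their gene regions with probability `contact_prob[c]`, plus
#'   `n_background_contacts` random contacts.
#'
#' @param config a [sim_config()].
#' @param truth the `coex_truth` from [simulate_expression()] (same config).
#' @return a `coex_annotations` list: `ppi`, `complexes`, `terms` (list with
#'   `dag` and `annotation`), `layout`, `tads`, `dhs` (tibble gene x cell
#'   types), `contacts`.
#' @export
simulate_annotations <- function(config, truth) {
  stopifnot(inherits(config, "coex_sim_config"), inherits(truth, "coex_truth"))
  if (any(config$ppi_odds <= 0)) stop("`ppi_odds` must be > 0", call. = FALSE)
  withr::with_seed(child_seed(config$seed, 2L), {
    genes <- truth$genes
    labels <- truth$pair_labels
    label_by_key <- stats::setNames(labels$label,
                                    pair_key(labels$gene_a, labels$gene_b))

    ann <- list(
      ppi = sim_ppi(config, genes, labels),
      complexes = sim_complexes(truth),
      terms = sim_terms(config, genes, labels),
      layout = NULL, tads = NULL,
      dhs = NULL, contacts = NULL)
    geo <- sim_layout(config, genes, truth)
    ann$layout <- geo$layout
    ann$tads <- geo$tads
    ann$dhs <- sim_dhs(config, genes, truth)
    ann$contacts <- sim_contacts(config, labels, geo$layout)
    structure(ann, class = "coex_annotations")
  })
}

sim_ppi <- function(config, genes, labels) {
  p0 <- config$ppi_background
  odds0 <- p0 / (1 - p0)
  p1 <- stats::setNames(vapply(config$ppi_odds, function(o) {
    q <- o * odds0
    q / (1 + q)
  }, numeric(1)), names(config$ppi_odds))

  universe <- all_pairs(genes)
  key <- pair_key(universe$gene_a, universe$gene_b)
  lab <- stats::setNames(labels$label, pair_key(labels$gene_a, labels$gene_b))
  p <- rep(p0, nrow(universe))
  hit <- match(key, names(lab))
  planted <- !is.na(hit)
  p[planted] <- p1[lab[hit[planted]]]
  edge <- stats::runif(nrow(universe)) < p
  universe[edge, ]
}

sim_complexes <- function(truth) {
  tibble::tibble(complex_id = truth$modules$module_id,
                 gene = truth$modules$gene)
}

sim_terms <- function(config, genes, labels) {
  n_mid <- 4L
  n_leaf <- 24L
  mids <- sprintf("M%02d", seq_len(n_mid))
  leaves <- sprintf("L%02d", seq_len(n_leaf))
  dag <- dplyr::bind_rows(
    tibble::tibble(child = mids, parent = "ROOT"),
    tibble::tibble(child = leaves,
                   parent = mids[((seq_len(n_leaf) - 1L) %% n_mid) + 1L]))
  annotation <- tibble::tibble(gene = genes, term = sample(leaves,
                                                           length(genes),
                                                           replace = TRUE))
  coupled <- labels[stats::runif(nrow(labels)) <
                      config$term_coupling[labels$label], ]
  if (nrow(coupled) > 0) {
    common <- sample(leaves, nrow(coupled), replace = TRUE)
    annotation <- dplyr::bind_rows(
      annotation,
      tibble::tibble(gene = coupled$gene_a, term = common),
      tibble::tibble(gene = coupled$gene_b, term = common))
  }
  list(dag = dag, annotation = dplyr::distinct(annotation))
}

sim_layout <- function(config, genes, truth) {
  n_chrom <- config$n_chromosomes
  tads_per <- config$genome_tads_per_chrom
  tad_len <- 1e6
  gap <- 5e4
  chrom_len <- tads_per * (tad_len + gap)
  chroms <- sprintf("chr%d", seq_len(n_chrom))

  # TADs: 1-Mb domains separated by 50-kb gaps (0-based half-open internally)
  tads <- tidyr::expand_grid(chrom = chroms, i = seq_len(tads_per)) |>
    dplyr::mutate(start = (.data$i - 1) * (tad_len + gap),
                  end = .data$start + tad_len,
                  tad_id = sprintf("%s_tad%02d", .data$chrom, .data$i)) |>
    dplyr::select("chrom", "start", "end", "tad_id")

  chrom_of <- sample(chroms, length(genes), replace = TRUE)
  pos <- floor(stats::runif(length(genes), 0, chrom_len - 2e4))
  names(chrom_of) <- names(pos) <- genes

  # co-locate planted structures: independent pairs as pairs, cliques wholesale
  units <- c(
    split(cbind(truth$pair_labels$gene_a, truth$pair_labels$gene_b),
          seq_len(nrow(truth$pair_labels))) |>
      stats::setNames(pair_key(truth$pair_labels$gene_a,
                               truth$pair_labels$gene_b)),
    NULL)
  unit_label <- stats::setNames(truth$pair_labels$label, names(units))
  seen_mod <- unique(truth$modules$module_id)
  for (m in seen_mod) {
    mg <- truth$modules$gene[truth$modules$module_id == m]
    units[[m]] <- mg
    unit_label[m] <- truth$modules$class[truth$modules$module_id == m][1]
  }
  for (uname in names(units)) {
    cls <- unit_label[[uname]]
    members <- units[[uname]]
    if (stats::runif(1) < config$same_chrom_prob[cls]) {
      anchor <- members[1]
      chrom_of[members] <- chrom_of[anchor]
      if (stats::runif(1) < config$same_tad_prob[cls]) {
        tad_i <- sample.int(tads_per, 1L)
        lo <- (tad_i - 1) * (tad_len + gap)
        pos[members] <- floor(stats::runif(length(members), lo,
                                           lo + tad_len - 2e4))
      }
    }
  }

  # layout coordinates are 1-based inclusive (pos is the 0-based body start)
  strand <- sample(c("+", "-"), length(genes), replace = TRUE)
  start <- pos + 1
  end <- pos + 1e4
  tss <- ifelse(strand == "+", start, end)
  layout <- tibble::tibble(gene = genes, chrom = unname(chrom_of),
                           strand = strand,
                           tss = unname(tss), start = unname(start),
                           end = unname(end))
  layout$tad_id <- tad_of(layout$chrom, layout$tss - 1, tads)
  list(layout = layout, tads = tads)
}

# 0-based half-open TAD membership of a position
tad_of <- function(chrom, pos, tads) {
  vapply(seq_along(chrom), function(i) {
    hit <- tads$chrom == chrom[i] & tads$start <= pos[i] & pos[i] < tads$end
    if (any(hit)) tads$tad_id[which(hit)[1]] else NA_character_
  }, character(1))
}

sim_dhs <- function(config, genes, truth) {
  nct <- config$n_cell_types_dhs
  base <- 5
  lat <- matrix(stats::rnorm(length(genes) * nct), nrow = length(genes),
                dimnames = list(genes, sprintf("ct%03d", seq_len(nct))))
  if (config$dhs_rho > 0) {
    rho <- config$dhs_rho
    coupled_cls <- c("shared", "bulk_only")
    pl <- truth$pair_labels[truth$pair_labels$label %in% coupled_cls, ]
    # treat each planted clique as one unit; independent pairs as units of two
    mod_units <- split(truth$modules$gene, truth$modules$module_id)
    mod_cls <- vapply(split(truth$modules$class, truth$modules$module_id),
                      `[`, character(1), 1)
    units <- c(lapply(seq_len(nrow(pl)), function(i) c(pl$gene_a[i],
                                                       pl$gene_b[i])),
               unname(mod_units[mod_cls %in% coupled_cls]))
    # drop clique genes duplicated in pair units (cliques listed separately)
    for (u in units) {
      h <- stats::rnorm(nct)
      for (g in u) {
        lat[g, ] <- sqrt(rho) * h + sqrt(1 - rho) * stats::rnorm(nct)
      }
    }
  }
  vals <- pmax(base + lat, 0)
  tibble::as_tibble(vals, rownames = "gene")
}

sim_contacts <- function(config, labels, layout) {
  anchor <- function(g) {
    i <- match(g, layout$gene)
    mid <- floor((layout$start[i] + layout$end[i]) / 2)
    tibble::tibble(chrom = layout$chrom[i], start = mid, end = mid + 500)
  }
  hit <- labels[stats::runif(nrow(labels)) <
                  config$contact_prob[labels$label], ]
  planted <- if (nrow(hit) > 0) {
    a <- anchor(hit$gene_a)
    b <- anchor(hit$gene_b)
    tibble::tibble(chrom1 = a$chrom, start1 = a$start, end1 = a$end,
                   chrom2 = b$chrom, start2 = b$start, end2 = b$end)
  } else {
    tibble::tibble(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                   chrom2 = character(), start2 = numeric(), end2 = numeric())
  }
  nb <- config$n_background_contacts
  chroms <- unique(layout$chrom)
  chrom_len <- max(layout$end) + 5e4
  rand_anchor <- function(n) {
    s <- floor(stats::runif(n, 0, chrom_len - 500))
    tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                   start = s, end = s + 500)
  }
  a <- rand_anchor(nb)
  b <- rand_anchor(nb)
  background <- tibble::tibble(chrom1 = a$chrom, start1 = a$start,
                               end1 = a$end, chrom2 = b$chrom,
                               start2 = b$start, end2 = b$end)
  dplyr::bind_rows(planted, background)
}

#' @export
print.coex_annotations <- function(x, ...) {
  cat(sprintf(paste0("<coex_annotations: %d PPI edges, %d complexes, ",
                     "%d term annotations, %d genes laid out, DHS over %d ",
                     "cell types, %d contacts>\n"),
              nrow(x$ppi), length(unique(x$complexes$complex_id)),
              nrow(x$terms$annotation), nrow(x$layout), ncol(x$dhs) - 1L,
              nrow(x$contacts)))
  invisible(x)
}
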