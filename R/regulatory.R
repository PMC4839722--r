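#' Genome-layout and interval file readers
#'
#' The layout TSV carries 1-based inclusive coordinates (columns gene, chrom,
#' strand, tss, start, end, optionally tad_id); BED-like peak/TAD files and
#' the contact TSV are 0-based half-open. Internally every interval is
#' 0-based half-open; the layout's 1-based positions are converted where
#' intervals are built. `write_layout_tsv()` round-trips exactly.
#'
#' @param path file path.
#' @param layout layout tibble to write.
#' @return tibbles in the column layout described above.
#' @export
read_layout_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_layout_tsv
#' @export
write_layout_tsv <- function(layout, path) {
  readr::write_tsv(layout, path, progress = FALSE)
  invisible(layout)
}

#' @rdname read_layout_tsv
#' @export
read_bed_peaks <- function(path) {
  tb <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "score"),
                        show_col_types = FALSE, progress = FALSE)
  tb
}

#' @rdname read_layout_tsv
#' @export
read_contacts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# 0-based half-open interval overlap (vectorized over a)
interval_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

# strand-aware promoter, 0-based half-open: `width` bp strictly upstream of
# the TSS. tss is the 1-based TSS position from the layout.
promoter_interval <- function(tss, strand, width = 1000) {
  tss0 <- tss - 1                       # 0-based coordinate of the TSS base
  start <- ifelse(strand == "+", tss0 - width, tss0 + 1)
  tibble::tibble(start = pmax(start, 0), end = start + width)
}

#' Promoter accessibility signal per gene and cell type
#'
#' Assigns DHS peaks to genes when they overlap the promoter — the 1,000 bp
#' strictly upstream of the TSS, strand-aware (`[TSS-1000, TSS)` on `+`,
#' `(TSS, TSS+1000]` on `-`, 1-based terms) — and aggregates the overlapping
#' peak scores (`sum` by default, `max` optionally). Genes without any
#' overlapping peak get 0.
#'
#' @param peaks named list of per-cell-type peak tibbles
#'   (`chrom`, `start`, `end`, `score`; 0-based half-open).
#' @param layout genome layout tibble (1-based; needs `gene`, `chrom`,
#'   `strand`, `tss`).
#' @param promoter_width upstream promoter width in bp (default 1000).
#' @param aggregate `"sum"` or `"max"`.
#' @return tibble `gene` x cell-type columns (the DHS matrix).
#' @export
promoter_dhs_signal <- function(peaks, layout, promoter_width = 1000,
                                aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  if (any(!layout$strand %in% c("+", "-"))) {
    stop("gene with unknown strand", call. = FALSE)
  }
  prom <- promoter_interval(layout$tss, layout$strand, promoter_width)
  agg <- if (aggregate == "sum") sum else max
  out <- tibble::tibble(gene = layout$gene)
  for (ct in names(peaks)) {
    pk <- peaks[[ct]]
    sig <- vapply(seq_len(nrow(layout)), function(i) {
      hit <- pk$chrom == layout$chrom[i] &
        interval_overlaps(pk$start, pk$end, prom$start[i], prom$end[i])
      if (any(hit)) agg(pk$score[hit]) else 0
    }, numeric(1))
    out[[ct]] <- sig
  }
  out
}

#' Cross-cell-type promoter accessibility correlation of gene pairs
#'
#' Pearson correlation of the two genes' DHS signal vectors across cell
#' types, per pair; genes with zero-variance (e.g. all-zero) vectors are
#' undefined and excluded. When the pair table carries a `class` column, a
#' per-class density summary is added: the mode of a Gaussian-kernel density
#' (Silverman's rule-of-thumb bandwidth, recorded in the output).
#'
#' @param pairs tibble `gene_a`, `gene_b` (+ optional `class`).
#' @param dhs DHS matrix tibble from [promoter_dhs_signal()] or the
#'   generator.
#' @return list: `per_pair` (pairs + `r_dhs`), `summary` (per class: `n`,
#'   `mode`, `bandwidth`; `NULL` without a class column).
#' @export
dhs_correlation <- function(pairs, dhs) {
  v <- as.matrix(dhs[, -1, drop = FALSE])
  if (ncol(v) < 3) stop("need at least 3 cell types", call. = FALSE)
  rownames(v) <- dhs$gene
  sds <- apply(v, 1, stats::sd)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]
    b <- pairs$gene_b[i]
    if (!a %in% rownames(v) || !b %in% rownames(v) ||
        sds[a] == 0 || sds[b] == 0) {
      return(NA_real_)
    }
    stats::cor(v[a, ], v[b, ])
  }, numeric(1))
  per_pair <- dplyr::mutate(pairs, r_dhs = r)
  summary <- NULL
  if ("class" %in% names(pairs)) {
    summary <- per_pair |>
      dplyr::filter(!is.na(.data$r_dhs)) |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(n = dplyr::n(),
                       mode = density_mode(.data$r_dhs),
                       bandwidth = stats::bw.nrd0(.data$r_dhs),
                       .groups = "drop")
  }
  list(per_pair = per_pair, summary = summary)
}

# mode of a Gaussian KDE with Silverman's rule-of-thumb bandwidth
density_mode <- function(x) {
  if (length(x) < 2) {
    return(stats::median(x))
  }
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

# gene region [start - flank, end + flank), 0-based half-open, from the
# 1-based inclusive layout
gene_region <- function(layout, flank) {
  tibble::tibble(gene = layout$gene, chrom = layout$chrom,
                 start = pmax(layout$start - 1 - flank, 0),
                 end = layout$end + flank)
}

#' Chromatin-contact overlap of gene pairs
#'
#' A pair is "in contact" when some contact links one gene's region to the
#' other's, the region being the gene body extended by `flank` bp (default
#' 5,000) on both sides. When the pair table has a `class` column, per-class
#' contact fractions are reported together with the fraction over all
#' background pairs of the layout (the random-pair expectation).
#'
#' @param pairs tibble `gene_a`, `gene_b` (+ optional `class`).
#' @param layout genome layout (1-based inclusive gene bodies).
#' @param contacts contact tibble (`chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`; 0-based half-open anchors).
#' @param flank extension in bp.
#' @return list: `per_pair` (pairs + logical `has_contact`), `by_class`
#'   (per-class fraction; `NULL` without classes), `background_fraction`.
#' @export
contact_overlap <- function(pairs, layout, contacts, flank = 5000) {
  regions <- gene_region(layout, flank)
  contact_keys <- contact_pair_keys(regions, contacts)
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  per_pair <- dplyr::mutate(pairs, has_contact = key %in% contact_keys)
  by_class <- NULL
  if ("class" %in% names(pairs)) {
    by_class <- per_pair |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(n = dplyr::n(),
                       fraction = mean(.data$has_contact), .groups = "drop")
  }
  uni <- all_pairs(layout$gene)
  bg <- mean(pair_key(uni$gene_a, uni$gene_b) %in% contact_keys)
  list(per_pair = per_pair, by_class = by_class, background_fraction = bg)
}

# set of gene-pair keys connected by at least one contact
contact_pair_keys <- function(regions, contacts) {
  if (nrow(contacts) == 0) {
    return(character())
  }
  genes_hit <- function(chrom, start, end) {
    regions$gene[regions$chrom == chrom &
                   interval_overlaps(regions$start, regions$end, start, end)]
  }
  keys <- character()
  for (i in seq_len(nrow(contacts))) {
    g1 <- genes_hit(contacts$chrom1[i], contacts$start1[i], contacts$end1[i])
    g2 <- genes_hit(contacts$chrom2[i], contacts$start2[i], contacts$end2[i])
    if (length(g1) > 0 && length(g2) > 0) {
      grid <- expand.grid(a = g1, b = g2, stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, ]
      keys <- c(keys, pair_key(grid$a, grid$b))
    }
  }
  unique(keys)
}

#' Same-chromosome and same-domain co-location of gene pairs
#'
#' `same_chromosome_fraction()` reports the fraction of pairs whose genes lie
#' on one chromosome, along with the exact fraction over all pairs of the
#' layout (random-pair control). `same_tad_fraction()` reports, over
#' same-chromosome pairs, the fraction whose TSSs fall inside one topological
#' domain (a TSS outside all domains never counts as same-domain).
#'
#' @param pairs tibble `gene_a`, `gene_b`.
#' @param layout genome layout.
#' @param tads TAD tibble (`chrom`, `start`, `end`, `tad_id`;
#'   0-based half-open). Defaults to the `tad_id` column of the layout.
#' @return list(`fraction`, `control_fraction`, `n`) /
#'   list(`fraction`, `n_intra`).
#' @export
same_chromosome_fraction <- function(pairs, layout) {
  chrom <- stats::setNames(layout$chrom, layout$gene)
  same <- chrom[pairs$gene_a] == chrom[pairs$gene_b]
  uni <- all_pairs(layout$gene)
  ctrl <- mean(chrom[uni$gene_a] == chrom[uni$gene_b])
  list(fraction = mean(same), control_fraction = ctrl, n = nrow(pairs))
}

#' @rdname same_chromosome_fraction
#' @export
same_tad_fraction <- function(pairs, layout, tads = NULL) {
  chrom <- stats::setNames(layout$chrom, layout$gene)
  intra <- chrom[pairs$gene_a] == chrom[pairs$gene_b]
  if (!all(intra)) {
    stop("same_tad_fraction expects same-chromosome pairs only",
         call. = FALSE)
  }
  tad <- if (is.null(tads)) {
    stats::setNames(layout$tad_id, layout$gene)
  } else {
    stats::setNames(tad_of(layout$chrom, layout$tss - 1, tads), layout$gene)
  }
  same <- !is.na(tad[pairs$gene_a]) & !is.na(tad[pairs$gene_b]) &
    tad[pairs$gene_a] == tad[pairs$gene_b]
  list(fraction = mean(same), n_intra = nrow(pairs))
}

#' Contact enrichment stratified by chromosome relationship
#'
#' Splits each class's pairs into intrachromosomal and interchromosomal
#' strata and reports the contact fraction per class and stratum, next to the
#' matched background fraction (all layout pairs of the same stratum). Empty
#' strata yield `NA`.
#'
#' @param class_table a `coex_class_table` (or any pair table with `class`).
#' @param layout genome layout.
#' @param contacts contact tibble.
#' @param flank region extension in bp.
#' @return tibble `class`, `stratum`, `n_pairs`, `fraction`,
#'   `control_fraction`.
#' @export
intra_inter_contact_enrichment <- function(class_table, layout, contacts,
                                           flank = 5000) {
  regions <- gene_region(layout, flank)
  contact_keys <- contact_pair_keys(regions, contacts)
  chrom <- stats::setNames(layout$chrom, layout$gene)
  stratum_of <- function(a, b) {
    ifelse(chrom[a] == chrom[b], "intra", "inter")
  }
  uni <- all_pairs(layout$gene)
  uni$stratum <- stratum_of(uni$gene_a, uni$gene_b)
  uni$hit <- pair_key(uni$gene_a, uni$gene_b) %in% contact_keys
  bg <- uni |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(control_fraction = mean(.data$hit), .groups = "drop")

  tb <- class_table |>
    dplyr::filter(.data$class %in% c("shared", "sc_specific",
                                     "bulk_specific")) |>
    dplyr::mutate(stratum = stratum_of(.data$gene_a, .data$gene_b),
                  hit = pair_key(.data$gene_a, .data$gene_b) %in%
                    contact_keys)
  grid <- tidyr::expand_grid(class = c("shared", "sc_specific",
                                       "bulk_specific"),
                             stratum = c("intra", "inter"))
  tb |>
    dplyr::group_by(.data$class, .data$stratum) |>
    dplyr::summarise(n_pairs = dplyr::n(), fraction = mean(.data$hit),
                     .groups = "drop") |>
    dplyr::right_join(grid, by = c("class", "stratum")) |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L)) |>
    dplyr::left_join(bg, by = "stratum") |>
    dplyr::arrange(.data$class, .data$stratum)
}
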