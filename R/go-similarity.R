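#' Information content and pairwise Lin similarity for an ontology
#'
#' `term_ic()` propagates gene annotations to all ancestors of a single-root
#' DAG and derives each term's information content
#' `IC(t) = -log(freq(t))`, where `freq(t)` is the fraction of annotated
#' genes annotated to `t` or any descendant; the root has IC 0. `term_ic()`
#' also precomputes the term-by-term Lin similarity matrix
#' `sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))` (MICA = the common ancestor
#' of maximal IC), which makes per-pair gene similarity cheap.
#'
#' @param terms list with `dag` (tibble `child`, `parent`; single root,
#'   acyclic) and `annotation` (tibble `gene`, `term`).
#' @return a `coex_ontology` list: `ic` (named numeric), `sim` (matrix),
#'   `gene_terms` (named list), `root`.
#' @export
term_ic <- function(terms) {
  dag <- terms$dag
  ann <- terms$annotation
  parents <- split(dag$parent, dag$child)
  all_terms <- unique(c(dag$child, dag$parent))
  roots <- setdiff(dag$parent, dag$child)
  if (length(roots) != 1) stop("DAG must have a single root", call. = FALSE)

  ancestors <- function(t) {
    out <- t
    frontier <- t
    while (length(frontier) > 0) {
      up <- unique(unlist(parents[intersect(frontier, names(parents))]))
      frontier <- setdiff(up, out)
      out <- c(out, frontier)
    }
    out
  }
  anc <- lapply(stats::setNames(all_terms, all_terms), ancestors)

  # per-gene closure, term frequencies, IC
  gene_terms_raw <- split(ann$term, ann$gene)
  closure <- lapply(gene_terms_raw, function(ts) {
    unique(unlist(anc[unique(ts)]))
  })
  n_ann <- length(closure)
  freq <- table(factor(unlist(closure), levels = all_terms)) / n_ann
  ic <- -log(as.numeric(freq))
  names(ic) <- all_terms
  ic[!is.finite(ic)] <- max(ic[is.finite(ic)], 0) + log(n_ann + 1)
  ic[roots] <- 0

  sim <- matrix(0, length(all_terms), length(all_terms),
                dimnames = list(all_terms, all_terms))
  for (t1 in all_terms) {
    for (t2 in all_terms) {
      common <- intersect(anc[[t1]], anc[[t2]])
      mica <- max(ic[common])
      denom <- ic[t1] + ic[t2]
      sim[t1, t2] <- if (denom > 0) 2 * mica / denom else 0
    }
  }
  structure(list(ic = ic, sim = sim, gene_terms = gene_terms_raw,
                 root = roots),
            ancestors = anc,
            class = "coex_ontology")
}

#' Semantic similarity between two genes (Lin, best-match average)
#'
#' Best-match average over the genes' annotated term sets: every term of one
#' gene is matched to its most similar term of the other, in both directions,
#' and the matches are averaged. Genes without annotation (or annotated only
#' to the root) are undefined and return `NA`.
#'
#' @param gene_a,gene_b gene identifiers.
#' @param ont a `coex_ontology` from [term_ic()].
#' @return similarity in \[0, 1\], or `NA` when undefined.
#' @export
go_similarity <- function(gene_a, gene_b, ont) {
  stopifnot(inherits(ont, "coex_ontology"))
  ta <- setdiff(unique(ont$gene_terms[[gene_a]]), ont$root)
  tb <- setdiff(unique(ont$gene_terms[[gene_b]]), ont$root)
  if (length(ta) == 0 || length(tb) == 0) {
    return(NA_real_)
  }
  s <- ont$sim[ta, tb, drop = FALSE]
  (sum(apply(s, 1, max)) + sum(apply(s, 2, max))) / (nrow(s) + ncol(s))
}

go_similarity_pairs <- function(pairs, ont) {
  vapply(seq_len(nrow(pairs)), function(i) {
    go_similarity(pairs$gene_a[i], pairs$gene_b[i], ont)
  }, numeric(1))
}

#' Fraction of gene pairs with ontology similarity, versus random pairs
#'
#' A pair "has similarity" when its best-match-average Lin similarity is at
#' least `threshold` (default 0.5). The observed fraction (over pairs where
#' similarity is defined) is compared against random pair sets drawn from the
#' universe with the same control machinery as the PPI enrichment.
#'
#' @param class_pairs pairs of one class.
#' @param terms ontology input (see [term_ic()]) or a prebuilt
#'   `coex_ontology`.
#' @param universe gene universe for controls.
#' @param threshold similarity call threshold (default 0.5).
#' @param n_sets,set_size,seed control geometry.
#' @return a `coex_enrichment`.
#' @export
go_similarity_fraction <- function(class_pairs, terms, universe,
                                   threshold = 0.5, n_sets = 100,
                                   set_size = 500, seed = 1L) {
  ont <- if (inherits(terms, "coex_ontology")) terms else term_ic(terms)
  called <- function(p) {
    s <- go_similarity_pairs(p, ont)
    s[!is.na(s)] >= threshold
  }
  obs_calls <- called(class_pairs)
  if (length(obs_calls) == 0) stop("no annotated pairs", call. = FALSE)
  random_pair_control(universe, observed = mean(obs_calls),
                      n_sets = n_sets, set_size = set_size, seed = seed,
                      hit_fun = called)
}

#' Hypergeometric term enrichment with single-module gene assignment
#'
#' Upper-tail hypergeometric test per term (annotations propagated to
#' ancestors) with Benjamini-Hochberg correction, followed by the module
#' rule: each gene of the query set annotated to several enriched terms is
#' assigned to the single most significant one.
#'
#' @param gene_set query genes (subset of `universe`).
#' @param terms ontology input or `coex_ontology`.
#' @param universe background gene universe.
#' @param q_cutoff BH-q threshold defining "enriched" for the assignment
#'   (default 0.05).
#' @return list with `table` (tibble `term`, `n_set`, `n_universe`, `p`, `q`)
#'   and `assignment` (tibble `gene`, `term`).
#' @export
term_enrichment <- function(gene_set, terms, universe, q_cutoff = 0.05) {
  if (!all(gene_set %in% universe)) {
    stop("gene_set must be a subset of universe", call. = FALSE)
  }
  ont <- if (inherits(terms, "coex_ontology")) terms else term_ic(terms)
  closure <- propagate_terms(ont)
  in_univ <- intersect(names(closure), universe)
  closure <- closure[in_univ]
  term_genes <- split(rep(names(closure), lengths(closure)),
                      unlist(closure))
  n_u <- length(in_univ)
  set_in <- intersect(gene_set, in_univ)
  k <- length(set_in)
  tab <- purrr::map_dfr(names(term_genes), function(t) {
    m <- length(intersect(term_genes[[t]], in_univ))
    q <- length(intersect(term_genes[[t]], set_in))
    tibble::tibble(term = t, n_set = q, n_universe = m,
                   p = stats::phyper(q - 1, m, n_u - m, k,
                                     lower.tail = FALSE))
  })
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab <- dplyr::arrange(tab, .data$p, .data$term)

  enriched <- tab$term[tab$q <= q_cutoff & tab$term != ont$root]
  assignment <- purrr::map_dfr(set_in, function(g) {
    ts <- intersect(closure[[g]], enriched)
    if (length(ts) == 0) {
      return(tibble::tibble())
    }
    sub <- tab[match(ts, tab$term), ]
    best <- sub$term[order(sub$p, sub$term)][1]
    tibble::tibble(gene = g, term = best)
  })
  list(table = tab, assignment = assignment)
}

# gene -> propagated term closure (each term plus all its ancestors)
propagate_terms <- function(ont) {
  anc <- attr(ont, "ancestors")
  lapply(ont$gene_terms, function(ts) unique(unlist(anc[unique(ts)])))
}
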