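class_table_fixture <- function(pairs, classes) {
  structure(dplyr::mutate(pairs, r_sc = 0.5, r_bulk = 0.5,
                          pattern_sc = "+", pattern_bulk = "+",
                          class = classes),
            class = c("coex_class_table", class(tibble::tibble())))
}

test_that("class networks collect exactly the class pairs", {
  ct <- class_table_fixture(
    tibble::tibble(gene_a = c("a", "b", "a", "x", "p"),
                   gene_b = c("b", "c", "c", "y", "q")),
    c("shared", "shared", "shared", "shared", "sc_specific"))
  g <- build_class_network(ct, "shared")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  tri <- igraph::induced_subgraph(g, c("a", "b", "c"))
  expect_equal(igraph::ecount(tri), 3)
  expect_warning(empty <- build_class_network(ct, "bulk_specific"),
                 "no pairs")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("greedy modularity communities match the exhaustive-partition
          oracle on two joined cliques", {
  clique <- function(nodes) all_pairs_of(nodes)
  edges <- dplyr::bind_rows(clique(sprintf("a%d", 1:5)),
                            clique(sprintf("b%d", 1:5)),
                            tibble::tibble(gene_a = "a1", gene_b = "b1"))
  ct <- class_table_fixture(edges, "shared")
  g <- build_class_network(ct, "shared")
  subs <- detect_subnetworks(g, min_size = 3)
  expect_equal(nrow(subs), 2)
  expect_equal(sort(subs$genes[[1]]), sprintf("a%d", 1:5))
  expect_equal(sort(subs$genes[[2]]), sprintf("b%d", 1:5))
  # the detected partition attains the exhaustive-search optimum, and the
  # package modularity agrees with the formula oracle to 1e-10
  memb <- stats::setNames(rep(1:2, each = 5),
                          c(sprintf("a%d", 1:5), sprintf("b%d", 1:5)))
  em <- as.matrix(edges)
  expect_equal(oracle_modularity(em, memb),
               igraph::modularity(g, memb[igraph::V(g)$name]),
               tolerance = 1e-10)
  best <- oracle_best_modularity(em, names(memb))
  expect_equal(igraph::modularity(g, memb[igraph::V(g)$name]), best,
               tolerance = 1e-10)
  # a single clique is one community; an empty graph gives an empty list
  g1 <- build_class_network(class_table_fixture(clique(sprintf("c%d", 1:5)),
                                                "shared"), "shared")
  expect_equal(nrow(detect_subnetworks(g1, min_size = 3)), 1)
  expect_equal(nrow(detect_subnetworks(igraph::make_empty_graph(
    0, directed = FALSE))), 0)
  # detected modularity is at least the trivial one-community partition's
  one <- stats::setNames(rep(1, 10), names(memb))
  expect_gte(igraph::modularity(g, memb[igraph::V(g)$name]),
             oracle_modularity(em, one))
})

test_that("patient clustering recovers opposite expression blocks and is
          order-invariant", {
  withr::with_seed(61, {
    sig <- rep(c(1, -1), each = 3)                 # gene direction pattern
    grp <- rep(c(1, -1), each = 10)                # patient blocks
    v <- outer(sig, grp) * 2 +
      matrix(stats::rnorm(6 * 20, sd = 0.4), 6, 20)
  })
  rownames(v) <- sprintf("g%d", 1:6)
  colnames(v) <- sprintf("p%02d", 1:20)
  m <- make_expr(v, state = "log2")
  part <- cluster_patients_two_groups(m, rownames(v))
  expect_equal(length(unique(part$cluster[1:10])), 1)
  expect_equal(length(unique(part$cluster[11:20])), 1)
  expect_false(part$cluster[1] == part$cluster[20])
  # duplicated patients are co-assigned
  dup <- make_expr(cbind(v, p99 = v[, 1]), state = "log2")
  pd <- cluster_patients_two_groups(dup, rownames(v))
  expect_equal(pd$cluster[pd$patient == "p99"],
               pd$cluster[pd$patient == "p01"])
  # column order does not change the partition
  perm <- make_expr(v[, sample(20)], state = "log2")
  pp <- cluster_patients_two_groups(perm, rownames(v))
  joined <- dplyr::inner_join(part, pp, by = "patient")
  agree <- mean(joined$cluster.x == joined$cluster.y)
  expect_true(agree %in% c(0, 1))
  expect_error(cluster_patients_two_groups(
    make_expr(v[, 1:3], state = "log2"), rownames(v)), "4 patients")
})

test_that("log-rank test equals the O/E/V oracle and survdiff", {
  co <- toy_cohort(6, hr = 4, seed = 63)
  part <- co[, c("patient", "cluster")]
  lr <- logrank_test(co[, c("patient", "time", "event")], part)
  expect_equal(lr$statistic,
               oracle_logrank(co$time, co$event, co$cluster),
               tolerance = 1e-10)
  # identical survival in both groups: duplicate every patient across groups
  dup <- tibble::tibble(patient = sprintf("d%02d", 1:12),
                        time = rep(co$time, 2), event = 1L)
  dpart <- tibble::tibble(patient = dup$patient,
                          cluster = rep(1:2, each = 6))
  lr0 <- logrank_test(dup, dpart)
  expect_equal(lr0$statistic, 0, tolerance = 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-10)
  expect_error(logrank_test(co[, c("patient", "time", "event")],
                            dplyr::mutate(part, cluster = 1)), "non-empty")
  # larger random instances against the oracle
  for (s in 64:66) {
    cc <- toy_cohort(40, hr = 2, seed = s)
    lrx <- logrank_test(cc[, c("patient", "time", "event")],
                        cc[, c("patient", "cluster")])
    expect_equal(lrx$statistic, oracle_logrank(cc$time, cc$event,
                                               cc$cluster),
                 tolerance = 1e-10)
  }
})

test_that("log-rank rejection rate is nominal under the null", {
  rej <- vapply(1:200, function(s) {
    cc <- toy_cohort(40, hr = 1, seed = 1000 + s)
    logrank_test(cc[, c("patient", "time", "event")],
                 cc[, c("patient", "cluster")])$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})

test_that("BH FDR matches the step-up definition oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  withr::with_seed(67, p <- stats::runif(50)^2)
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-15)
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("silhouette equals the definition oracle, including singleton
          convention", {
  withr::with_seed(69, {
    v <- cbind(matrix(stats::rnorm(40, 0, .2), 10, 4) + 1,
               matrix(stats::rnorm(40, 0, .2), 10, 4) - 1)
    v <- v * rep(c(1, -1), each = 5)
  })
  rownames(v) <- sprintf("g%02d", 1:10)
  colnames(v) <- sprintf("p%02d", 1:8)
  m <- make_expr(v, state = "log2")
  part <- tibble::tibble(patient = colnames(v),
                         cluster = rep(1:2, each = 4))
  sw <- silhouette_width(m, rownames(v), part)
  d <- 1 - stats::cor(v)
  expect_equal(sw$mean, oracle_silhouette(d, part$cluster),
               tolerance = 1e-10)
  expect_gt(sw$mean, 0.5)
  # random partition of homogeneous data is near zero
  withr::with_seed(71, hom <- matrix(stats::rnorm(10 * 8), 10, 8))
  rownames(hom) <- rownames(v)
  colnames(hom) <- colnames(v)
  swh <- silhouette_width(make_expr(hom, state = "log2"), rownames(hom),
                          part)
  expect_lt(abs(swh$mean), 0.25)
  # singleton group: width 0 for the singleton
  p1 <- tibble::tibble(patient = colnames(v),
                       cluster = c(1, rep(2, 7)))
  s1 <- silhouette_width(m, rownames(v), p1)
  expect_equal(s1$per_patient$width[1], 0)
  expect_equal(s1$mean, oracle_silhouette(d, p1$cluster), tolerance = 1e-10)
})

test_that("cross-platform normalization cancels constant platform shifts", {
  withr::with_seed(73, v <- matrix(stats::rnorm(30, 5), 5, 6))
  rownames(v) <- sprintf("g%d", 1:5)
  colnames(v) <- sprintf("p%d", 1:6)
  a <- make_expr(v, state = "log2")
  b <- make_expr(v + 2.5, state = "log2")
  out <- normalize_cross_platform(a, b, "p3")
  expect_equal(expr_values(out$a), expr_values(out$b), tolerance = 1e-12)
  same <- normalize_cross_platform(a, a, "p1")
  expect_equal(expr_values(same$a), expr_values(same$b))
  expect_error(normalize_cross_platform(a, b, "nope"), "missing")
})

test_that("nearest shrunken centroid: delta 0 is nearest-centroid, large
          delta collapses to the prior majority", {
  # two-gene separable toy set
  withr::with_seed(79, {
    tr <- cbind(matrix(c(2, -2), 2, 6) + stats::rnorm(12, sd = .1),
                matrix(c(-2, 2), 2, 4) + stats::rnorm(8, sd = .1))
  })
  rownames(tr) <- c("gA", "gB")
  colnames(tr) <- sprintf("p%02d", 1:10)
  labs <- tibble::tibble(patient = colnames(tr),
                         cluster = rep(1:2, c(6, 4)))
  te <- cbind(matrix(c(2, -2), 2, 3), matrix(c(-2, 2), 2, 3))
  rownames(te) <- rownames(tr)
  colnames(te) <- sprintf("t%d", 1:6)
  m_tr <- make_expr(tr, state = "log2")
  m_te <- make_expr(te, state = "log2")
  pred <- nsc_classify(m_tr, labs, m_te, c("gA", "gB"), delta = 0)
  expect_equal(pred$cluster, rep(1:2, each = 3))
  # hand-computed centroid distances at delta 0: test point 1 is closer to
  # the class-1 centroid on both genes
  pred_cv <- nsc_classify(m_tr, labs, m_te, c("gA", "gB"), seed = 3)
  expect_equal(pred_cv$cluster, rep(1:2, each = 3))
  big <- nsc_classify(m_tr, labs, m_te, c("gA", "gB"), delta = 1e6)
  expect_true(all(big$cluster == 1))      # prior majority class
  # duplicated training point classifies to its own class at delta 0
  self_pred <- nsc_classify(m_tr, labs, m_tr, c("gA", "gB"), delta = 0)
  expect_equal(self_pred$cluster, labs$cluster)
  expect_error(nsc_classify(m_tr, dplyr::mutate(labs, cluster = 1), m_te,
                            c("gA", "gB"), delta = 0), "two classes")
})

test_that("screening keeps planted prognostic modules and passes nulls at
          the nominal rate", {
  cfg <- sim_config(seed = 75)
  sim <- simulate_dataset(cfg)
  bulk_log <- log2_plus_one(sim$bulk)
  subnets <- tibble::tibble(
    subnetwork_id = c("planted", "noise"),
    class = "shared",
    n_genes = c(length(sim$truth$prognostic_module), 4L),
    genes = list(sim$truth$prognostic_module,
                 setdiff(sim$truth$genes,
                         sim$truth$prognostic_module)[1:4]))
  scr <- screen_subnetworks(subnets, bulk_log, sim$cohort$training)
  expect_true(scr$significant[scr$subnetwork_id == "planted"])
  expect_lt(scr$p[1], 1e-4)
  # empty input stays empty
  expect_equal(nrow(screen_subnetworks(subnets[0, ], bulk_log,
                                       sim$cohort$training)), 0)
})

test_that("combination search prefers the jointly-strong pair of weak
          modules and reports composition", {
  # two 3-gene modules, each carrying half of the group pattern: alone the
  # within-module pattern is weak, jointly the six-gene pattern separates
  # the groups sharply
  wins <- vapply(1:8, function(s) {
    withr::with_seed(100 + s, {
      n <- 100
      grp <- rep(c(1, -1), each = n / 2)
      half <- function(sign) {
        t(vapply(c(0.9, 1.0, 1.1), function(l) {
          sign * l * grp * 0.8 + stats::rnorm(n)
        }, numeric(n)))
      }
      v <- rbind(half(1), half(-1))
      rownames(v) <- sprintf("g%d", 1:6)
      colnames(v) <- sprintf("p%03d", 1:n)
      time <- stats::rexp(n, ifelse(grp == 1, 3, 1) * log(2) / 400)
      cohort <- tibble::tibble(patient = colnames(v), time = time,
                               event = 1L)
    })
    m <- make_expr(v, state = "log2")
    screened <- tibble::tibble(
      subnetwork_id = c("m1", "m2"), class = "shared", n_genes = 3L,
      genes = list(sprintf("g%d", 1:3), sprintf("g%d", 4:6)),
      statistic = NA_real_, p = c(0.01, 0.01), significant = TRUE)
    sig <- combine_and_search(screened, m, cohort)
    sig$best$unit_id == "m1+m2"
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("combination search handles a single significant subnetwork and
          q >= p", {
  cfg <- sim_config(seed = 77)
  sim <- simulate_dataset(cfg)
  bulk_log <- log2_plus_one(sim$bulk)
  subnets <- tibble::tibble(
    subnetwork_id = "planted", class = "shared",
    n_genes = length(sim$truth$prognostic_module),
    genes = list(sim$truth$prognostic_module))
  scr <- screen_subnetworks(subnets, bulk_log, sim$cohort$training)
  sig <- combine_and_search(scr, bulk_log, sim$cohort$training)
  expect_equal(sig$best$unit_id, "planted")
  expect_gte(sig$best$q, sig$best$p)
  expect_equal(sig$best$composition$class, "shared")
  td <- tidy(sig)
  expect_equal(nrow(td), 1)
  gl <- glance(sig)
  expect_equal(gl$unit_id, "planted")
})

test_that("Kaplan-Meier table tracks risk sets and survival drops", {
  co <- tibble::tibble(patient = sprintf("p%d", 1:4),
                       time = c(10, 20, 30, 40), event = c(1L, 0L, 1L, 1L))
  part <- tibble::tibble(patient = co$patient, cluster = c(1, 1, 2, 2))
  km <- km_table(co, part)
  g1 <- km[km$cluster == 1, ]
  expect_equal(g1$n_risk, c(2, 1))
  expect_equal(g1$survival, c(0.5, 0.5))
  g2 <- km[km$cluster == 2, ]
  expect_equal(g2$survival, c(0.5, 0))
})
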