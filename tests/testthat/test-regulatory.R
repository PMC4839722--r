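toy_layout <- function() {
  tibble::tibble(
    gene = c("gp", "gm", "far"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(5000, 5000, 2000),
    start = c(5000, 1000, 2000),
    end = c(9000, 5000, 6000))
}

test_that("promoter assignment is strand-aware with exact boundaries", {
  layout <- toy_layout()
  # peak [4500, 4600) with score 7: inside [4000, 5000) upstream of + TSS
  peaks <- list(ct1 = tibble::tibble(chrom = "chr1", start = 4500,
                                     end = 4600, score = 7))
  dhs <- promoter_dhs_signal(peaks, layout)
  expect_equal(dhs$ct1[dhs$gene == "gp"], 7)
  # same peak is on the wrong side of the - strand promoter (5000, 6000]
  expect_equal(dhs$ct1[dhs$gene == "gm"], 0)
  # peak overlapping [5000, 6000) does hit the - strand promoter
  peaks2 <- list(ct1 = tibble::tibble(chrom = "chr1", start = 5999,
                                      end = 6100, score = 3))
  dhs2 <- promoter_dhs_signal(peaks2, layout)
  expect_equal(dhs2$ct1[dhs2$gene == "gm"], 3)
  # one bp past the promoter end misses
  peaks3 <- list(ct1 = tibble::tibble(chrom = "chr1", start = 6000,
                                      end = 6100, score = 3))
  expect_equal(promoter_dhs_signal(peaks3, layout)$ct1, c(0, 0, 0))
  # + promoter covers 1-based positions 4000..4999, i.e. [3999, 4999)
  # 0-based: a peak ending at 0-based 4000 still touches position 3999,
  # one ending at 3999 does not
  in_pk <- list(ct1 = tibble::tibble(chrom = "chr1", start = 3990,
                                     end = 4000, score = 2))
  out_pk <- list(ct1 = tibble::tibble(chrom = "chr1", start = 3990,
                                      end = 3999, score = 2))
  expect_equal(promoter_dhs_signal(in_pk, layout)$ct1[1], 2)
  expect_equal(promoter_dhs_signal(out_pk, layout)$ct1[1], 0)
  # aggregation: sum vs max over overlapping peaks
  two <- list(ct1 = tibble::tibble(chrom = "chr1", start = c(4100, 4500),
                                   end = c(4200, 4600), score = c(5, 7)))
  expect_equal(promoter_dhs_signal(two, layout)$ct1[1], 12)
  expect_equal(promoter_dhs_signal(two, layout,
                                   aggregate = "max")$ct1[1], 7)
  # unknown strand errors; no peaks give an all-zero matrix
  bad <- layout
  bad$strand[1] <- "."
  expect_error(promoter_dhs_signal(peaks, bad), "strand")
  empty <- promoter_dhs_signal(
    list(ct1 = tibble::tibble(chrom = character(), start = numeric(),
                              end = numeric(), score = numeric())), layout)
  expect_true(all(empty$ct1 == 0))
})

test_that("DHS correlation handles identical, planted and undefined
          vectors", {
  withr::with_seed(53, {
    h <- stats::rnorm(50)
    dhs <- tibble::tibble(
      gene = c("a", "b", "c", "d", "z"),
      !!!stats::setNames(as.data.frame(rbind(
        h, h,
        sqrt(0.95) * h + sqrt(0.05) * stats::rnorm(50),
        stats::rnorm(50),
        rep(0, 50))), sprintf("ct%02d", 1:50)))
  })
  pairs <- tibble::tibble(gene_a = c("a", "a", "a", "a"),
                          gene_b = c("b", "c", "d", "z"))
  res <- dhs_correlation(pairs, dhs)
  expect_equal(res$per_pair$r_dhs[1], 1)
  expect_gt(res$per_pair$r_dhs[2], 0.9)
  expect_lt(abs(res$per_pair$r_dhs[3]), 0.5)
  expect_true(is.na(res$per_pair$r_dhs[4]))
})

test_that("planted promoter synchrony puts the class density mode in the
          high-correlation regime", {
  cfg <- sim_config(n_genes = 120, n_cells = 30, n_bulk = 30,
                    n_planted_shared = 25, n_planted_sc_only = 25,
                    n_planted_bulk_only = 0, module_size = 0,
                    complex_classes = character(), dhs_rho = 0.95,
                    n_validation = 0, seed = 55)
  sim <- simulate_expression(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  lab <- dplyr::rename(sim$truth$pair_labels, class = "label")
  res <- dhs_correlation(lab, ann$dhs)
  modes <- stats::setNames(res$summary$mode, res$summary$class)
  expect_gt(modes[["shared"]], 0.8)       # coupled class
  expect_lt(abs(modes[["sc_only"]]), 0.35)  # uncoupled class centers near 0
})

test_that("contact overlap respects the 5 kb flank with half-open
          boundaries", {
  layout <- toy_layout()
  # gp region on chr1: [start-1-flank, end+flank) = [-1 -> 0, 14000)
  # gm region: [0, 10000); far on chr2: [0 -> , 11000)
  touching <- tibble::tibble(chrom1 = "chr1", start1 = 13999, end1 = 14050,
                             chrom2 = "chr2", start2 = 100, end2 = 200)
  outside <- tibble::tibble(chrom1 = "chr1", start1 = 14000, end1 = 14050,
                            chrom2 = "chr2", start2 = 100, end2 = 200)
  pairs <- tibble::tibble(gene_a = "gp", gene_b = "far")
  expect_true(contact_overlap(pairs, layout, touching)$per_pair$has_contact)
  expect_false(contact_overlap(pairs, layout, outside)$per_pair$has_contact)
  # symmetry in the anchor order
  swapped <- touching[, c(4:6, 1:3)]
  names(swapped) <- names(touching)
  expect_true(contact_overlap(pairs, layout, swapped)$per_pair$has_contact)
  # monotone in flank: a contact missed at small flank is found at larger
  narrow <- contact_overlap(pairs, layout, outside, flank = 4999)
  wide <- contact_overlap(pairs, layout, outside, flank = 5001)
  expect_false(narrow$per_pair$has_contact)
  expect_true(wide$per_pair$has_contact)
  # empty contact set gives all-false
  none <- contact_overlap(pairs, layout, touching[0, ])
  expect_false(none$per_pair$has_contact)
  expect_equal(none$background_fraction, 0)
})

test_that("same-chromosome and same-domain fractions have exact counting
          semantics", {
  layout <- tibble::tibble(
    gene = sprintf("g%d", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr3"),
    strand = "+",
    tss = c(100, 1100, 2000100, 100, 900, 100),
    start = c(100, 1100, 2000100, 100, 900, 100),
    end = c(600, 1600, 2000600, 600, 1400, 600))
  tads <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                         start = c(0, 2e6, 0), end = c(1e6, 3e6, 1e6),
                         tad_id = c("t1", "t2", "t3"))
  pairs <- tibble::tibble(gene_a = c("g1", "g1", "g4", "g1", "g2"),
                          gene_b = c("g2", "g3", "g5", "g4", "g6"))
  sc <- same_chromosome_fraction(pairs, layout)
  expect_equal(sc$fraction, 3 / 5)
  expect_equal(sc$control_fraction,
               (choose(3, 2) + choose(2, 2)) / choose(6, 2))
  intra <- pairs[1:3, ]
  st <- same_tad_fraction(intra, layout, tads)
  # g1/g2 share t1; g1/g3 are in t1 vs t2; g4/g5 share t3
  expect_equal(st$fraction, 2 / 3)
  expect_error(same_tad_fraction(pairs, layout, tads), "same-chromosome")
  # a TSS at a domain boundary belongs to the half-open interval containing
  # it: 1-based position 1e6 is 0-based 999999, inside [0, 1e6)
  edge_layout <- layout
  edge_layout$tss[2] <- 1e6
  st2 <- same_tad_fraction(intra[1, ], edge_layout, tads)
  expect_equal(st2$fraction, 1)
  edge_layout$tss[2] <- 1e6 + 1           # 0-based 1e6 falls in the gap
  expect_equal(same_tad_fraction(intra[1, ], edge_layout, tads)$fraction, 0)
})

test_that("uniform chromosome assignment matches the analytic expectation", {
  withr::with_seed(57, {
    layout <- tibble::tibble(gene = sprintf("g%03d", 1:400),
                             chrom = sample(sprintf("chr%d", 1:10), 400,
                                            replace = TRUE),
                             strand = "+", tss = 1, start = 1, end = 500)
    pairs <- all_pairs_of(layout$gene)[sample(choose(400, 2), 2000), ]
  })
  sc <- same_chromosome_fraction(pairs, layout)
  expect_equal(sc$fraction, 1 / 10, tolerance = 0.15)
})

test_that("contact enrichment concentrates in the planted class-stratum
          cell", {
  layout <- tibble::tibble(
    gene = sprintf("g%d", 1:8),
    chrom = rep(c("chr1", "chr2"), each = 4), strand = "+",
    tss = rep(c(1e4, 2e6, 4e6, 6e6), 2),
    start = rep(c(1e4, 2e6, 4e6, 6e6), 2),
    end = rep(c(1e4, 2e6, 4e6, 6e6), 2) + 1e4)
  # one interchromosomal contact joining g1 (chr1) and g5 (chr2)
  contacts <- tibble::tibble(chrom1 = "chr1", start1 = 1.2e4, end1 = 1.3e4,
                             chrom2 = "chr2", start2 = 1.2e4, end2 = 1.3e4)
  ct <- tibble::tibble(gene_a = c("g1", "g2", "g1"),
                       gene_b = c("g5", "g3", "g2"),
                       class = c("sc_specific", "shared", "shared"))
  enr <- intra_inter_contact_enrichment(ct, layout, contacts)
  cell <- enr[enr$class == "sc_specific" & enr$stratum == "inter", ]
  expect_equal(cell$fraction, 1)
  others <- enr[!(enr$class == "sc_specific" & enr$stratum == "inter") &
                  enr$n_pairs > 0, ]
  expect_true(all(others$fraction == 0))
  # no contacts at all: zero everywhere
  enr0 <- intra_inter_contact_enrichment(ct, layout, contacts[0, ])
  expect_true(all(enr0$fraction[enr0$n_pairs > 0] == 0))
})

test_that("layout TSV round trip preserves interval relationships exactly", {
  layout <- toy_layout()
  layout$tad_id <- c("t1", "t1", NA)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layout_tsv(layout, path)
  back <- read_layout_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(layout))
  prom1 <- promoter_dhs_signal(
    list(ct = tibble::tibble(chrom = "chr1", start = 4500, end = 4600,
                             score = 1)), layout)
  prom2 <- promoter_dhs_signal(
    list(ct = tibble::tibble(chrom = "chr1", start = 4500, end = 4600,
                             score = 1)), back)
  expect_equal(prom1, prom2)
})
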