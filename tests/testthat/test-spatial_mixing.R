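# Pair counting, mixing score, architecture classification, threshold
# derivation, tumor labels, mixing heterogeneity.

cells_at <- function(phenotype, x, y) {
  tibble::tibble(x = x, y = y, phenotype = phenotype)
}

test_that("interaction counting: boundary-inclusive unordered pairs", {
  # one tumor and one immune cell 10 um apart
  c1 <- cells_at(c("Neoplastic tumor", "CD8 T cell"), c(0, 10), c(0, 0))
  expect_equal(count_interactions(c1, "Neoplastic tumor",
                                  immune_phenotypes(), 15), 1)
  # three immune cells on an equilateral triangle of side 12
  tri <- cells_at(rep("B cell", 3), c(0, 12, 6), c(0, 0, 6 * sqrt(3)))
  expect_equal(count_interactions(tri, immune_phenotypes(),
                                  immune_phenotypes(), 15), 3)
  # two cells 15.1 um apart do not interact; exactly 15.0 um do
  far <- cells_at(c("B cell", "B cell"), c(0, 15.1), c(0, 0))
  expect_equal(count_interactions(far, immune_phenotypes(),
                                  immune_phenotypes(), 15), 0)
  near <- cells_at(c("B cell", "B cell"), c(0, 15), c(0, 0))
  expect_equal(count_interactions(near, immune_phenotypes(),
                                  immune_phenotypes(), 15), 1)
  # empty sets count zero
  expect_equal(count_interactions(near, "Neoplastic tumor",
                                  immune_phenotypes(), 15), 0)
  # ordered convention doubles the count
  expect_equal(count_interactions(c1, "Neoplastic tumor",
                                  immune_phenotypes(), 15, ordered = TRUE),
               2)
})

test_that("interaction counting is symmetric and matches brute force", {
  cells <- random_layout(300, size = 400, seed = 5)
  tum <- cells$phenotype == "Neoplastic tumor"
  imm <- cells$phenotype %in% immune_phenotypes()
  expected_ti <- oracle_pair_count(cells$x[tum], cells$y[tum],
                                   cells$x[imm], cells$y[imm], 15)
  expected_ii <- oracle_pair_count(cells$x[imm], cells$y[imm], r = 15)
  expect_equal(count_interactions(cells, "Neoplastic tumor",
                                  immune_phenotypes(), 15), expected_ti)
  expect_equal(count_interactions(cells, immune_phenotypes(),
                                  "Neoplastic tumor", 15), expected_ti)
  expect_equal(count_interactions(cells, immune_phenotypes(),
                                  immune_phenotypes(), 15), expected_ii)
  # overlapping sets decompose correctly: immune vs (immune + tumor)
  all_types <- phenotype_levels()
  both <- cells$phenotype %in% setdiff(all_types, "aSMA+ mesenchymal")
  expected_mixed <- oracle_pair_count(cells$x[both], cells$y[both], r = 15) -
    oracle_pair_count(cells$x[tum], cells$y[tum], r = 15)
  expect_equal(count_interactions(cells, immune_phenotypes(),
                                  setdiff(all_types, "aSMA+ mesenchymal"),
                                  15),
               expected_mixed)
})

test_that("mixing score equals the pair-count ratio and flags no-immune regions", {
  cells <- cells_at(
    c("Neoplastic tumor", "CD8 T cell", "B cell", "Macrophage",
      "aSMA+ mesenchymal"),
    c(0, 10, 20, 14, 5), c(0, 0, 0, 8, 5))
  res <- mixing_score(cells, mixing_config(), area_mm2 = 1)
  # pairs by hand: TI = {tumor-CD8 (10), tumor-Mac (16.1 -> no)} = 1
  # II = {CD8-B (10), CD8-Mac (8.9), B-Mac (10)} = 3; aSMA excluded
  expect_equal(res$n_tumor_immune_pairs, 1)
  expect_equal(res$n_immune_immune_pairs, 3)
  expect_equal(res$mixing_score, 1 / 3)
  expect_equal(res$immune_density, 3)
  # a 1:10 pair ratio gives score 0.1
  ten <- cells_at(c("Neoplastic tumor", rep("CD8 T cell", 5)),
                  c(0, 10, 20, 24, 30, 36), rep(0, 6))
  r10 <- mixing_score(ten, mixing_config(), area_mm2 = 1)
  expect_equal(r10$mixing_score,
               r10$n_tumor_immune_pairs / r10$n_immune_immune_pairs)
  # zero immune-immune pairs -> undefined score
  lone <- cells_at(c("Neoplastic tumor", "CD8 T cell"), c(0, 10), c(0, 0))
  res_lone <- mixing_score(lone, mixing_config(), area_mm2 = 1)
  expect_true(is.na(res_lone$mixing_score))
  expect_false(res_lone$score_defined)
  # zero tumor-immune pairs -> score 0
  apart <- cells_at(c("Neoplastic tumor", "B cell", "B cell"),
                    c(0, 100, 110), c(0, 0, 0))
  expect_equal(mixing_score(apart, mixing_config(),
                            area_mm2 = 1)$mixing_score, 0)
})

test_that("mixing score is invariant under rigid motions", {
  cells <- random_layout(250, size = 300, seed = 8)
  base <- mixing_score(cells, mixing_config(), area_mm2 = 1)
  th <- pi / 5
  rot <- cells
  rot$x <- cells$x * cos(th) - cells$y * sin(th) + 1000
  rot$y <- cells$x * sin(th) + cells$y * cos(th) - 55
  moved <- mixing_score(rot, mixing_config(), area_mm2 = 1)
  expect_equal(moved$n_tumor_immune_pairs, base$n_tumor_immune_pairs)
  expect_equal(moved$n_immune_immune_pairs, base$n_immune_immune_pairs)
  expect_equal(moved$mixing_score, base$mixing_score)
})

test_that("classification applies the cold rule first, then the threshold", {
  cfg <- mixing_config()  # threshold 0.107, cold below 390.625 cells/mm^2
  expect_equal(classify_region(0.2, 600, cfg), "mixed")
  expect_equal(classify_region(0.5, 100, cfg), "cold")
  expect_equal(classify_region(NA_real_, 100, cfg), "cold")
  expect_equal(classify_region(0.107, 600, cfg), "compartmentalized")
  expect_equal(classify_region(0.05, 600, cfg), "compartmentalized")
  # the count-per-area rule converts to a density bound
  expect_equal(classify_region(0.2, 390.624, cfg), "cold")
  expect_equal(classify_region(0.2, 390.626, cfg), "mixed")
  expect_error(classify_region(NA_real_, 600, cfg), "undefined")
})

test_that("threshold derivation is the median over primary regions", {
  tab <- tibble::tibble(
    timepoint = c("primary", "primary", "primary", "recurrent"),
    tumor_id = c("t1", "t1", "t2", "t3"),
    mixing_score = c(0.05, 0.107, 0.2, 9))
  expect_equal(derive_mixing_threshold(tab), 0.107)
  expect_equal(derive_mixing_threshold(tab[3, ]), 0.2)
  expect_equal(derive_mixing_threshold(tab[c(1, 3), ]), 0.125)
  # per-tumor granularity averages regions first
  expect_equal(derive_mixing_threshold(tab, granularity = "tumor"),
               median(c(mean(c(0.05, 0.107)), 0.2)))
  expect_error(derive_mixing_threshold(tab[4, ]), "primary")
})

test_that("tumor labels average non-cold regions", {
  mk <- function(scores, labels) {
    tibble::tibble(tumor_id = "t1", patient_id = "p1",
                   timepoint = "primary",
                   region_id = paste0("r", seq_along(scores)),
                   mixing_score = scores, label = labels)
  }
  cfg <- mixing_config(mix_threshold = 0.107)
  t1 <- tumor_mixing_label(mk(c(0.05, 0.15),
                              c("compartmentalized", "mixed")), cfg)
  expect_equal(t1$mixing_score, 0.1)
  expect_equal(t1$label, "compartmentalized")
  # single-region tumor inherits the region label
  t2 <- tumor_mixing_label(mk(0.3, "mixed"), cfg)
  expect_equal(t2$label, "mixed")
  # cold regions are excluded from the average
  t3 <- tumor_mixing_label(mk(c(0.3, 0.01), c("mixed", "cold")), cfg)
  expect_equal(t3$mixing_score, 0.3)
  expect_equal(t3$label, "mixed")
  expect_equal(t3$n_cold, 1)
  # all-cold tumors stay cold
  t4 <- tumor_mixing_label(mk(c(NA, NA), c("cold", "cold")), cfg)
  expect_equal(t4$label, "cold")
})

test_that("mixing heterogeneity matches hand arithmetic", {
  tab <- tibble::tibble(
    region_id = c("r1", "r2", "r3"),
    tumor_id = c("t1", "t1", "t2"),
    patient_id = c("p1", "p1", "p2"),
    timepoint = "primary",
    anatomic_site = c("oral cavity", "oral cavity", "larynx"),
    mixing_score = c(0.1, 0.3, 0.2),
    label = "mixed")
  het <- mixing_heterogeneity(tab)
  g <- function(rid, lev) het$abs_diff[het$region_id == rid &
                                         het$level == lev]
  expect_equal(g("r1", "intra_tumor"), abs(0.1 - 0.2))
  expect_equal(g("r2", "intra_tumor"), abs(0.3 - 0.2))
  # single-region tumor: degenerate zero
  expect_equal(g("r3", "intra_tumor"), 0)
  expect_true(het$degenerate[het$region_id == "r3" &
                               het$level == "intra_tumor"])
  expect_equal(g("r1", "inter_patient_all"), abs(0.1 - 0.2))
  # identical scores -> all differences zero
  tab$mixing_score <- rep(0.2, 3)
  expect_true(all(mixing_heterogeneity(tab)$abs_diff == 0))
  # leave-one-out variant
  tab$mixing_score <- c(0.1, 0.3, 0.2)
  loo <- mixing_heterogeneity(tab, leave_one_out = TRUE)
  expect_equal(loo$abs_diff[loo$region_id == "r1" &
                              loo$level == "intra_tumor"], abs(0.1 - 0.3))
})

test_that("every region receives exactly one architecture label", {
  coh <- generate_cohort(small_synth_config(rng_seed = 12))
  mt <- region_mixing_table(coh, mixing_config(mix_threshold = NULL))
  expect_equal(nrow(mt), nrow(coh$regions))
  expect_true(all(mt$label %in% c("mixed", "compartmentalized", "cold")))
  expect_false(any(is.na(mt$label)))
  # and the derived threshold is recorded
  expect_true(is.numeric(attr(mt, "mix_threshold")))
})
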