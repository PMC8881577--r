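# Composition profiling, CoV, KL heterogeneity, normalizations, clustering
# and embedding.

make_count_cohort <- function(counts, sites = NULL) {
  # counts: named list region -> c(tumor, patient, timepoint, and a named
  # vector of phenotype counts); cells placed on a grid (positions ignored)
  cells <- list()
  regs <- list()
  for (rid in names(counts)) {
    spec <- counts[[rid]]
    n <- sum(spec$n)
    ph <- rep(names(spec$n), spec$n)
    cells[[rid]] <- toy_cells(rid, spec$tumor, spec$patient, spec$timepoint,
                              ph, x = seq_len(n) * 100,
                              y = rep(50, n))
    regs[[rid]] <- toy_regions(rid, spec$tumor, spec$patient,
                               spec$timepoint,
                               anatomic_site = if (is.null(sites)) {
                                 "oral cavity"
                               } else sites[[rid]])
  }
  suppressWarnings(time_cohort(dplyr::bind_rows(cells),
                               dplyr::bind_rows(regs)))
}

test_that("densities and fractions follow count / area arithmetic", {
  coh <- make_count_cohort(list(
    r1 = list(tumor = "t1", patient = "p1", timepoint = "primary",
              n = c("Neoplastic tumor" = 100)),
    r2 = list(tumor = "t1", patient = "p1", timepoint = "primary",
              n = c("Neoplastic tumor" = 50, "CD8 T cell" = 25))))
  d <- cell_densities(coh)
  d1 <- d[d$region_id == "r1", ]
  expect_equal(d1$density[d1$phenotype == "Neoplastic tumor"], 100 / 6.25)
  expect_equal(sum(d1$n), 100)
  d2 <- d[d$region_id == "r2", ]
  expect_equal(d2$fraction[d2$phenotype == "Neoplastic tumor"], 2 / 3)
  expect_equal(d2$fraction[d2$phenotype == "CD8 T cell"], 1 / 3)
  expect_equal(sum(d2$fraction), 1)
  # immune-only fractions renormalize over the CD45+ classes
  expect_equal(d2$immune_fraction[d2$phenotype == "CD8 T cell"], 1)
})

test_that("empty regions are flagged with undefined fractions", {
  cells <- toy_cells("r1", "t1", "p1", "primary", "B cell", 1, 1)
  regions <- toy_regions(c("r1", "r2"), "t1", "p1", "primary")
  coh <- time_cohort(cells, regions)
  d <- cell_densities(coh)
  d2 <- d[d$region_id == "r2", ]
  expect_true(all(d2$empty))
  expect_true(all(d2$density == 0))
  expect_true(all(is.na(d2$fraction)))
})

test_that("coefficient of variation follows the chosen std convention", {
  coh <- make_count_cohort(list(
    r1 = list(tumor = "t1", patient = "p1", timepoint = "primary",
              n = c("B cell" = 5, "CD8 T cell" = 1)),
    r2 = list(tumor = "t1", patient = "p1", timepoint = "primary",
              n = c("B cell" = 5, "CD8 T cell" = 2)),
    r3 = list(tumor = "t1", patient = "p1", timepoint = "primary",
              n = c("B cell" = 5, "CD8 T cell" = 3))))
  # absent phenotypes are excluded with a warning by design
  expect_warning(cv <- coefficient_of_variation(coh), "undefined")
  b <- cv$per_tumor$cov[cv$per_tumor$phenotype == "B cell"]
  expect_equal(b, 0)  # constant densities
  cd8 <- cv$per_tumor$cov[cv$per_tumor$phenotype == "CD8 T cell"]
  expect_equal(cd8, 0.5)  # sd([1,2,3]) / 2 with n-1 convention
  cvp <- suppressWarnings(coefficient_of_variation(coh,
                                                   sd_type = "population"))
  cd8p <- cvp$per_tumor$cov[cvp$per_tumor$phenotype == "CD8 T cell"]
  expect_equal(cd8p, sqrt(2 / 3) / 2)
  # phenotypes absent everywhere in the tumor are excluded
  expect_false("Macrophage" %in% cv$per_tumor$phenotype)
  # single-region tumors contribute no CoV at all
  coh1 <- make_count_cohort(list(
    r1 = list(tumor = "t1", patient = "p1", timepoint = "primary",
              n = c("B cell" = 5))))
  expect_equal(nrow(coefficient_of_variation(coh1)$per_tumor), 0)
})

test_that("KL divergence matches direct evaluation and its properties", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5), pseudocount = 0), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75), pseudocount = 0),
               0.5 * log2(0.5 / 0.25) + 0.5 * log2(0.5 / 0.75))
  expect_equal(round(kl_divergence(c(0.5, 0.5), c(0.25, 0.75),
                                   pseudocount = 0), 4), 0.2075)
  expect_equal(kl_divergence(c(1, 0), c(0, 1), pseudocount = 0), Inf)
  # natural-log base option
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75), pseudocount = 0,
                             base = exp(1)),
               0.2075187 * log(2), tolerance = 1e-6)
  # non-negativity and identity of indiscernibles over random pairs
  set.seed(42)
  for (i in 1:25) {
    p <- runif(10); p <- p / sum(p)
    q <- runif(10); q <- q / sum(q)
    expect_gte(kl_divergence(p, q), 0)
    expect_equal(kl_divergence(p, p), 0)
    if (max(abs(p - q)) > 1e-3) expect_gt(kl_divergence(p, q), 0)
  }
})

test_that("heterogeneity panel matches a hand-computed toy", {
  coh <- make_count_cohort(
    list(
      r1 = list(tumor = "t1P", patient = "p1", timepoint = "primary",
                n = c("B cell" = 30, "CD8 T cell" = 10)),
      r2 = list(tumor = "t1P", patient = "p1", timepoint = "primary",
                n = c("B cell" = 10, "CD8 T cell" = 30)),
      r3 = list(tumor = "t1R", patient = "p1", timepoint = "recurrent",
                n = c("B cell" = 20, "CD8 T cell" = 20)),
      r4 = list(tumor = "t2P", patient = "p2", timepoint = "primary",
                n = c("B cell" = 40, "CD8 T cell" = 40))),
    sites = list(r1 = "oral cavity", r2 = "oral cavity",
                 r3 = "oral cavity", r4 = "larynx"))
  eps <- 1e-6
  kl2 <- function(p, q) { # direct spreadsheet arithmetic
    p <- p + eps; q <- q + eps
    p <- p / sum(p); q <- q / sum(q)
    sum(p * log2(p / q))
  }
  pad <- function(b, c8) {
    v <- setNames(rep(0, 10), phenotype_levels())
    v["B cell"] <- b; v["CD8 T cell"] <- c8
    v
  }
  f1 <- pad(0.75, 0.25); f2 <- pad(0.25, 0.75)
  f3 <- pad(0.5, 0.5); f4 <- pad(0.5, 0.5)
  panel <- heterogeneity_panel(coh, pseudocount = eps)
  g <- function(rid, lev) panel$kl[panel$region_id == rid &
                                     panel$level == lev]
  # intra-tumor: r1 vs mean(r1, r2); r3, r4 vs themselves (degenerate 0)
  expect_equal(g("r1", "intra_tumor"), kl2(f1, (f1 + f2) / 2))
  expect_equal(g("r3", "intra_tumor"), 0)
  expect_true(panel$degenerate[panel$region_id == "r3" &
                                 panel$level == "intra_tumor"])
  # intra-patient: r1 vs mean(r1, r2, r3)
  expect_equal(g("r1", "intra_patient"), kl2(f1, (f1 + f2 + f3) / 3))
  # timepoint level: r4 vs mean of primary regions r1, r2, r4
  expect_equal(g("r4", "inter_patient_timepoint"),
               kl2(f4, (f1 + f2 + f4) / 3))
  # site level: r4 is the only larynx region
  expect_equal(g("r4", "inter_patient_site"), 0)
  # global level: r2 vs mean of all four
  expect_equal(g("r2", "inter_patient_all"),
               kl2(f2, (f1 + f2 + f3 + f4) / 4))
})

test_that("identical regions give an all-zero panel", {
  coh <- make_count_cohort(list(
    r1 = list(tumor = "t1", patient = "p1", timepoint = "primary",
              n = c("B cell" = 10, "CD8 T cell" = 10)),
    r2 = list(tumor = "t1", patient = "p1", timepoint = "primary",
              n = c("B cell" = 10, "CD8 T cell" = 10))))
  panel <- heterogeneity_panel(coh)
  expect_true(all(panel$kl == 0))
})

test_that("intra-patient heterogeneity is below inter-patient on divergent cohorts", {
  coh <- generate_cohort(small_synth_config(n_patients = 6, rng_seed = 9))
  panel <- heterogeneity_panel(coh)
  intra <- median(panel$kl[panel$level == "intra_patient"])
  inter <- median(panel$kl[panel$level == "inter_patient_all"])
  expect_lt(intra, inter)
})

test_that("log10 + 1 normalization", {
  expect_equal(log10p1_normalize(c(0, 9, 99)), c(0, 1, 2))
  expect_error(log10p1_normalize(-1), "non-negative")
})

test_that("Ward clustering separates blobs and merges duplicates first", {
  set.seed(1)
  blob1 <- matrix(rnorm(40, 0, 1), ncol = 2)
  blob2 <- matrix(rnorm(40, 20, 1), ncol = 2)
  fit <- hierarchical_cluster(rbind(blob1, blob2), 2)
  expect_equal(length(unique(fit$labels[1:20])), 1)
  expect_equal(length(unique(fit$labels[21:40])), 1)
  expect_true(fit$labels[1] != fit$labels[21])
  # n_rows groups -> singletons
  m <- matrix(c(0, 0, 5, 5, 9, 9), ncol = 2, byrow = TRUE)
  expect_equal(sort(unname(hierarchical_cluster(m, 3)$labels)), 1:3)
  # duplicated rows merge at height zero
  dup <- rbind(c(1, 1), c(1, 1), c(5, 5))
  expect_equal(min(hierarchical_cluster(dup, 2)$tree$height), 0)
  expect_error(hierarchical_cluster(m, 4), "n_groups")
})

test_that("PCA embedding: variance shares and fixed orientation", {
  v <- c(1, 2)
  scores1d <- seq(-2, 2, length.out = 9)
  m <- outer(scores1d, v)  # rank one
  fit <- pca_embed(m)
  expect_equal(fit$explained_variance[1], 1)
  # sign convention: the dominant loading is positive
  expect_gt(fit$rotation[which.max(abs(fit$rotation[, 1])), 1], 0)
  # mirrored input yields mirrored scores under the same orientation rule
  set.seed(2)
  m2 <- matrix(rnorm(60), ncol = 3)
  f1 <- pca_embed(m2)
  f2 <- pca_embed(-m2)
  expect_equal(abs(f1$scores), abs(f2$scores), tolerance = 1e-8)
  expect_error(pca_embed(matrix(1, 4, 3)), "constant")
})

test_that("signed [-1,1] change normalization follows the stated procedure", {
  out <- normalized_density_change(c(a = 4, b = 0, c = 0),
                                   c(a = 0, b = 2, c = 0),
                                   scope = "global")
  expect_equal(unname(out[1, ]), c(-1, 0.5, 0))
  # all-zero changes stay zero
  expect_equal(unname(normalized_density_change(c(a = 1), c(a = 1))[1, ]), 0)
  # single phenotype: change -3 -> -1
  expect_equal(unname(normalized_density_change(c(a = 3), c(a = 0))[1, ]), -1)
  # column scope: each phenotype scaled across patients
  prim <- rbind(p1 = c(a = 0, b = 0), p2 = c(a = 0, b = 0))
  rec <- rbind(p1 = c(a = 2, b = -1), p2 = c(a = 4, b = 3))
  out2 <- normalized_density_change(prim, rec, scope = "phenotype")
  expect_equal(unname(out2[, "a"]), c(0.5, 1))
  expect_equal(unname(out2[, "b"]), c(-1 / 3, 1))
  # properties: sign preserved, max |out| = 1 whenever any change != 0
  set.seed(3)
  for (i in 1:10) {
    p <- matrix(runif(20, 0, 50), ncol = 5)
    r <- matrix(runif(20, 0, 50), ncol = 5)
    o <- normalized_density_change(p, r, scope = "global")
    expect_equal(sign(o), sign(r - p))
    expect_equal(max(abs(o)), 1)
    expect_true(all(abs(o) <= 1))
  }
})

test_that("cohort change features pair timepoints per patient", {
  coh <- generate_cohort(small_synth_config())
  ch <- density_change_features(coh)
  expect_equal(sort(rownames(ch)), sort(unique(coh$clinical$patient_id)))
  expect_true(all(abs(ch) <= 1))
})
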