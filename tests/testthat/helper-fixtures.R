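# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (all-pairs distance scans, direct formula evaluation)
# and never call the spatial-index code paths they check.

# scaled-down generator settings for fast tests; the spatial and clinical
# structure is unchanged, only region size / patient count shrink
small_synth_config <- function(...) {
  args <- list(...)
  defaults <- list(region_size_um = 1000, n_regions_per_tumor = 2,
                   n_patients = 4, rng_seed = 101L)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  do.call(synth_config, defaults)
}

# a tiny hand-built cohort: 2 patients x primary/recurrent x 1-2 regions,
# with deterministic coordinates and counts for spreadsheet-style checks
toy_cells <- function(region_id, tumor_id, patient_id, timepoint,
                      phenotype, x, y, PD1 = FALSE) {
  tibble::tibble(patient_id = patient_id, tumor_id = tumor_id,
                 timepoint = timepoint, region_id = region_id,
                 x = x, y = y, phenotype = phenotype,
                 PD1 = PD1, PDL1 = FALSE, KI67 = FALSE)
}

toy_regions <- function(region_id, tumor_id, patient_id, timepoint,
                        area_mm2 = 6.25, anatomic_site = "oral cavity") {
  tibble::tibble(region_id = region_id, tumor_id = tumor_id,
                 patient_id = patient_id, timepoint = timepoint,
                 area_mm2 = area_mm2, anatomic_site = anatomic_site)
}

# brute-force unordered pair count between two coordinate sets (or within
# one set when b is NULL); boundary inclusive
oracle_pair_count <- function(ax, ay, bx = NULL, by = NULL, r) {
  if (is.null(bx)) {
    n <- length(ax)
    if (n < 2) return(0)
    total <- 0
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      total <- total + sum((ax[j] - ax[i])^2 + (ay[j] - ay[i])^2 <= r^2)
    }
    return(total)
  }
  total <- 0
  for (i in seq_along(ax)) {
    total <- total + sum((bx - ax[i])^2 + (by - ay[i])^2 <= r^2)
  }
  total
}

# brute-force neighborhood profiles: per seed, phenotype counts of all
# cells within r excluding the seed itself
oracle_neighborhoods <- function(cells, seed_phenotype, r) {
  seeds <- which(cells$phenotype == seed_phenotype)
  out <- list()
  for (s in seeds) {
    d2 <- (cells$x - cells$x[s])^2 + (cells$y - cells$y[s])^2
    nb <- which(d2 <= r^2)
    nb <- setdiff(nb, s)
    if (length(nb) == 0) next
    comp <- table(factor(cells$phenotype[nb], levels = phenotype_levels()))
    out[[length(out) + 1]] <- c(seed_id = s, neighbor_count = length(nb),
                                as.numeric(comp) / length(nb))
  }
  if (length(out) == 0) {
    return(matrix(numeric(0), ncol = 2 + length(phenotype_levels())))
  }
  do.call(rbind, out)
}

# random cell layout on a square region
random_layout <- function(n, size = 500, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    x = runif(n, 0, size), y = runif(n, 0, size),
    phenotype = sample(phenotype_levels(), n, replace = TRUE,
                       prob = c(rep(1, 8), 1.5, 4)))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
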