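# Synthetic cohort generator: spatially structured cell tables plus linked
# clinical outcomes, emulating the structure the downstream analyses assume.

#' Default per-phenotype expected densities (cells/mm^2)
#'
#' Calibrated so a full region carries roughly 3400 cells/mm^2 in total,
#' dominated by neoplastic cells, which puts the mean 30-um neighborhood
#' size near ten neighbors.
#'
#' @return Named numeric vector over [phenotype_levels()].
#' @export
default_phenotype_rates <- function() {
  c("CD8 T cell" = 135, "CD4 T helper" = 160,
    "CD4 regulatory T cell" = 65, "B cell" = 100,
    "Macrophage" = 160, "Granulocyte" = 100,
    "Antigen presenting cell" = 100, "Other immune" = 160,
    "aSMA+ mesenchymal" = 120, "Neoplastic tumor" = 750)
}

#' Default architecture-dependent functional-marker positivity rates
#'
#' PD-1 on lymphocytes is elevated in mixed regions; Ki-67 on antigen
#' presenting cells is elevated in compartmentalized regions. Combinations
#' not listed here fall back to the config's `base_marker_rate`.
#'
#' @rdname default_phenotype_rates
#' @details `default_phenotype_sdlog()` gives the log-scale SDs of the
#'   independent per-region rate multipliers; all rate multipliers use
#'   `meanlog = -sdlog^2 / 2` so expected densities equal the configured
#'   rates.
#' @export
default_phenotype_sdlog <- function() {
  s <- setNames(rep(0.3, length(phenotype_levels())), phenotype_levels())
  s["B cell"] <- 0.5
  s["aSMA+ mesenchymal"] <- 0.45
  s["Neoplastic tumor"] <- 0.45
  s
}

#' @return Tibble with columns phenotype, marker, mixed, compartmentalized.
#' @export
default_marker_rates <- function() {
  tibble::tribble(
    ~phenotype,               ~marker, ~mixed, ~compartmentalized,
    "CD8 T cell",             "PD1",   0.30,   0.12,
    "CD4 T helper",           "PD1",   0.30,   0.12,
    "B cell",                 "PD1",   0.30,   0.12,
    "Antigen presenting cell","KI67",  0.10,   0.25,
    "Neoplastic tumor",       "PDL1",  0.20,   0.20
  )
}

#' Synthetic cohort configuration
#'
#' Study-like defaults: square 2500-um regions, two to three regions per
#' tumor, nine patients with matched primary/recurrent tumors, Poisson cell
#' placement with tumor-cell blobs, a compartmentalization axis controlling
#' how strongly immune cells avoid the blobs, Matern-style B-cell clusters,
#' two alpha-SMA neighborhood archetypes, architecture-dependent marker
#' rates, and exponential progression-free survival with a hazard
#' multiplier for mixed primaries.
#'
#' @param region_size_um Side of the square region in micrometers.
#' @param n_regions_per_tumor Candidate region counts per tumor; one value
#'   is drawn uniformly per tumor.
#' @param n_patients Number of patients (each contributes a primary and a
#'   recurrent tumor).
#' @param phenotype_rates Named expected densities, cells/mm^2.
#' @param compartmentalization Named values in `[0, 1]` per architecture: the
#'   probability an immune cell is forced outside tumor blobs (0 = fully
#'   mixed placement, 1 = fully compartmentalized).
#' @param prop_compartmentalized Fraction of primary tumors assigned the
#'   compartmentalized architecture.
#' @param recurrent_concordance Probability a recurrent tumor keeps its
#'   patient's primary architecture.
#' @param n_tumor_blobs,blob_radius_um Number and radius of circular
#'   neoplastic-cell blobs; `blob_radius_um = NULL` scales the radius to
#'   0.26 x region size.
#' @param immune_aggregation Fraction of non-B immune cells placed inside
#'   shared immune aggregates (lymphoid-aggregate-like niches) rather than
#'   dispersed; aggregation is what keeps immune-immune proximity pairs
#'   abundant relative to tumor-immune pairs in real tissue.
#' @param aggregate_size,aggregate_radius_um Mean cells per immune
#'   aggregate and aggregate radius.
#' @param sdlog_immune_tumor Log-scale SD of a per-tumor immune infiltration
#'   multiplier shared by all immune classes (hot/cold tumors).
#' @param sdlog_immune_region Log-scale SD of a per-region immune multiplier
#'   (within-tumor infiltration variability; drives occasional cold
#'   regions).
#' @param phenotype_sdlog Named log-scale SDs of independent per-region,
#'   per-phenotype rate multipliers (within-tumor compositional dispersion;
#'   larger for B cells, whose density varies most across regions).
#' @param b_cell_cluster_size,b_cell_cluster_radius_um Mean B cells per
#'   aggregate and aggregate radius (Matern-style clustering).
#' @param asma_archetype `"by_architecture"` links the alpha-SMA archetype to
#'   the architecture (lymphoid-adjacent for compartmentalized, tumor-adjacent
#'   for mixed); or force `"lymphoid"` / `"tumor"`.
#' @param asma_anchor_radius_um Placement radius of alpha-SMA cells around
#'   their anchors (B-cell aggregates or neoplastic cells).
#' @param marker_rates Tibble as [default_marker_rates()].
#' @param base_marker_rate Positivity rate for unlisted
#'   phenotype-marker pairs.
#' @param pfs_median_days Baseline median PFS for compartmentalized
#'   primaries.
#' @param mixed_hazard_ratio Hazard multiplier applied to patients whose
#'   primary tumor is mixed (1 = architecture-independent null).
#' @param rng_seed Root seed; every random draw in the generator flows from
#'   it through per-region subseeds.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(region_size_um = 2500,
                         n_regions_per_tumor = 2:3,
                         n_patients = 9,
                         phenotype_rates = default_phenotype_rates(),
                         compartmentalization = c(mixed = 0.45,
                                                  compartmentalized = 0.9),
                         prop_compartmentalized = 0.5,
                         recurrent_concordance = 0.7,
                         n_tumor_blobs = 2,
                         blob_radius_um = NULL,
                         immune_aggregation = 0.75,
                         aggregate_size = 25,
                         aggregate_radius_um = 70,
                         sdlog_immune_tumor = 0.4,
                         sdlog_immune_region = 0.3,
                         phenotype_sdlog = default_phenotype_sdlog(),
                         b_cell_cluster_size = 12,
                         b_cell_cluster_radius_um = 60,
                         asma_archetype = "by_architecture",
                         asma_anchor_radius_um = 30,
                         marker_rates = default_marker_rates(),
                         base_marker_rate = 0.05,
                         pfs_median_days = 400,
                         mixed_hazard_ratio = 4,
                         rng_seed = 1L) {
  stopifnot(region_size_um > 0,
            all(phenotype_rates >= 0),
            all(compartmentalization >= 0 & compartmentalization <= 1),
            prop_compartmentalized >= 0, prop_compartmentalized <= 1,
            pfs_median_days > 0, mixed_hazard_ratio > 0)
  missing <- setdiff(phenotype_levels(), names(phenotype_rates))
  if (length(missing) > 0) {
    stop("phenotype_rates missing: ", paste(missing, collapse = ", "))
  }
  structure(as.list(environment()), class = "synth_config")
}

# fold out-of-bounds offsets back into [0, L] by reflection (avoids the
# coincident-point pile-up that clamping to the border would create)
reflect_into <- function(v, L) {
  v <- abs(v)
  ifelse(v > L, 2 * L - v, v)
}

inside_blobs <- function(x, y, blobs) {
  inside <- rep(FALSE, length(x))
  if (is.null(blobs) || nrow(blobs) == 0) return(inside)
  for (b in seq_len(nrow(blobs))) {
    inside <- inside |
      ((x - blobs$cx[b])^2 + (y - blobs$cy[b])^2 <= blobs$r[b]^2)
  }
  inside
}

# Draw n points uniform over the region; each point is, with probability
# `comp`, required to fall outside all tumor blobs (rejection resampling).
place_compartmentalized <- function(n, L, blobs, comp) {
  x <- runif(n, 0, L)
  y <- runif(n, 0, L)
  if (n == 0 || comp <= 0 || is.null(blobs) || nrow(blobs) == 0) {
    return(cbind(x = x, y = y))
  }
  must_exit <- runif(n) < comp
  for (iter in seq_len(200)) {
    bad <- must_exit & inside_blobs(x, y, blobs)
    if (!any(bad)) break
    x[bad] <- runif(sum(bad), 0, L)
    y[bad] <- runif(sum(bad), 0, L)
  }
  cbind(x = x, y = y)
}

# Canonical lineage flags implied by each phenotype (markers not on the
# phenotype's gate path are FALSE).
canonical_lineage_flags <- function(phenotype) {
  on <- list(
    "CD8 T cell" = c("CD45", "CD3", "CD8"),
    "CD4 T helper" = c("CD45", "CD3"),
    "CD4 regulatory T cell" = c("CD45", "CD3", "FOXP3"),
    "B cell" = c("CD45", "CD20"),
    "Macrophage" = c("CD45", "CD68"),
    "Granulocyte" = c("CD45", "CD66B"),
    "Antigen presenting cell" = c("CD45", "MHCII"),
    "Other immune" = "CD45",
    "aSMA+ mesenchymal" = "ASMA",
    "Neoplastic tumor" = "PANCK")
  lut <- vapply(lineage_markers(), function(m) {
    vapply(phenotype_levels(), function(p) m %in% on[[p]], logical(1))
  }, logical(length(phenotype_levels())))
  tibble::as_tibble(lut[match(phenotype, phenotype_levels()), , drop = FALSE])
}

sample_marker_flags <- function(phenotype, architecture, config) {
  n <- length(phenotype)
  out <- list()
  for (m in functional_markers()) {
    rate <- rep(config$base_marker_rate, n)
    rows <- config$marker_rates[config$marker_rates$marker == m, ]
    for (i in seq_len(nrow(rows))) {
      rate[phenotype == rows$phenotype[i]] <- rows[[architecture]][i]
    }
    out[[m]] <- runif(n) < rate
  }
  tibble::as_tibble(out)
}

#' Generate one synthetic tissue region
#'
#' Cells are placed by a two-component spatial process: neoplastic cells
#' uniformly within circular blobs; immune cells uniformly with probability
#' mass shifted outside the blobs in proportion to the compartmentalization
#' level; B cells as Matern-style clusters (cluster parents obey the same
#' compartmentalization rule); alpha-SMA+ cells anchored either to B-cell
#' aggregates (lymphoid-adjacent archetype) or to neoplastic cells
#' (tumor-adjacent archetype). Functional-marker flags are sampled from the
#' architecture's rates. Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed for this region.
#' @param architecture `"mixed"` or `"compartmentalized"`; selects the
#'   default compartmentalization level and the marker-rate column.
#' @param compartmentalization Optional explicit level in `[0, 1]`,
#'   overriding the architecture's default.
#' @param asma_archetype Optional `"lymphoid"` or `"tumor"`, overriding the
#'   config policy.
#' @return Tibble of cells: `x`, `y` (um), `phenotype`, lineage flags,
#'   functional flags.
#' @export
generate_region <- function(config, seed,
                            architecture = c("compartmentalized", "mixed"),
                            compartmentalization = NULL,
                            asma_archetype = NULL,
                            tumor_immune_factor = 1) {
  stopifnot(inherits(config, "synth_config"))
  architecture <- match.arg(architecture)
  if (is.null(compartmentalization)) {
    compartmentalization <- unname(config$compartmentalization[architecture])
  }
  if (is.null(asma_archetype)) {
    asma_archetype <- if (config$asma_archetype == "by_architecture") {
      if (architecture == "compartmentalized") "lymphoid" else "tumor"
    } else config$asma_archetype
  }
  set.seed(seed)
  L <- config$region_size_um
  area <- (L / 1000)^2
  R <- if (is.null(config$blob_radius_um)) 0.26 * L else config$blob_radius_um
  R <- min(R, L / 2)
  lo <- min(R, L / 2)
  blobs <- tibble::tibble(cx = runif(config$n_tumor_blobs, lo, L - lo),
                          cy = runif(config$n_tumor_blobs, lo, L - lo),
                          r = R)
  # per-region rate dispersion: a shared immune infiltration multiplier
  # plus independent per-phenotype multipliers (mean-preserving lognormals)
  sdl <- config$phenotype_sdlog[names(config$phenotype_rates)]
  type_mult <- stats::rlnorm(length(sdl), meanlog = -sdl^2 / 2, sdlog = sdl)
  sr <- config$sdlog_immune_region
  immune_mult <- stats::rlnorm(1, meanlog = -sr^2 / 2, sdlog = sr) *
    tumor_immune_factor
  rates <- config$phenotype_rates * type_mult
  imm <- names(rates) %in% immune_phenotypes()
  rates[imm] <- rates[imm] * immune_mult
  counts <- rpois(length(rates), rates * area)
  names(counts) <- names(config$phenotype_rates)

  # neoplastic cells: uniform within the blob union
  n_t <- counts[["Neoplastic tumor"]]
  bi <- sample.int(nrow(blobs), n_t, replace = TRUE)
  rad <- blobs$r[bi] * sqrt(runif(n_t))
  th <- runif(n_t, 0, 2 * pi)
  tx <- pmin(pmax(blobs$cx[bi] + rad * cos(th), 0), L)
  ty <- pmin(pmax(blobs$cy[bi] + rad * sin(th), 0), L)

  # non-B immune cells: a fraction sit in shared aggregates whose parents
  # obey the compartmentalization rule; the rest are dispersed under the
  # same rule
  imm_types <- setdiff(immune_phenotypes(), "B cell")
  imm_n <- counts[imm_types]
  n_imm <- sum(imm_n)
  imm_xy <- cbind(x = runif(n_imm, 0, L), y = runif(n_imm, 0, L))
  if (n_imm > 0 && config$immune_aggregation > 0) {
    n_agg_cells <- round(n_imm * config$immune_aggregation)
    if (n_agg_cells > 0) {
      n_par <- max(1L, round(n_agg_cells / config$aggregate_size))
      agg_parents <- place_compartmentalized(n_par, L, blobs,
                                             compartmentalization)
      in_agg <- sample.int(n_imm, n_agg_cells)
      pid <- sample.int(n_par, n_agg_cells, replace = TRUE)
      rr <- config$aggregate_radius_um * sqrt(runif(n_agg_cells))
      tt <- runif(n_agg_cells, 0, 2 * pi)
      imm_xy[in_agg, 1] <- reflect_into(agg_parents[pid, 1] + rr * cos(tt),
                                        L)
      imm_xy[in_agg, 2] <- reflect_into(agg_parents[pid, 2] + rr * sin(tt),
                                        L)
    }
  }
  # enforce the compartmentalization rule at the cell level: each immune
  # cell is, with probability `compartmentalization`, kept out of the blobs
  if (n_imm > 0 && compartmentalization > 0 && nrow(blobs) > 0) {
    must_exit <- runif(n_imm) < compartmentalization
    for (iter in seq_len(200)) {
      bad <- must_exit & inside_blobs(imm_xy[, 1], imm_xy[, 2], blobs)
      if (!any(bad)) break
      imm_xy[bad, 1] <- runif(sum(bad), 0, L)
      imm_xy[bad, 2] <- runif(sum(bad), 0, L)
    }
  }
  imm_pheno <- rep(imm_types, imm_n)

  # B cells: Matern-style clusters whose parents obey compartmentalization
  n_b <- counts[["B cell"]]
  if (n_b > 0) {
    n_par <- max(1L, round(n_b / config$b_cell_cluster_size))
    parents <- place_compartmentalized(n_par, L, blobs, compartmentalization)
    pi_ <- sample.int(n_par, n_b, replace = TRUE)
    br <- config$b_cell_cluster_radius_um * sqrt(runif(n_b))
    bth <- runif(n_b, 0, 2 * pi)
    bx <- reflect_into(parents[pi_, 1] + br * cos(bth), L)
    by <- reflect_into(parents[pi_, 2] + br * sin(bth), L)
    if (compartmentalization > 0 && nrow(blobs) > 0) {
      must_exit <- runif(n_b) < compartmentalization
      for (iter in seq_len(200)) {
        bad <- must_exit & inside_blobs(bx, by, blobs)
        if (!any(bad)) break
        bx[bad] <- runif(sum(bad), 0, L)
        by[bad] <- runif(sum(bad), 0, L)
      }
    }
  } else {
    parents <- matrix(numeric(0), ncol = 2)
    bx <- by <- numeric(0)
  }

  # alpha-SMA+ cells: anchored per archetype
  n_a <- counts[["aSMA+ mesenchymal"]]
  if (n_a > 0) {
    anchors <- if (asma_archetype == "lymphoid") {
      # structured: anchored to B cells, i.e. spread through the TLS-like
      # B-cell aggregates rather than piled at their centers
      if (n_b > 0) cbind(bx, by) else
        cbind(runif(1, 0, L), runif(1, 0, L))
    } else {
      if (n_t > 0) cbind(tx, ty) else cbind(runif(1, 0, L), runif(1, 0, L))
    }
    ai <- sample.int(nrow(anchors), n_a, replace = TRUE)
    ar <- config$asma_anchor_radius_um * sqrt(runif(n_a))
    ath <- runif(n_a, 0, 2 * pi)
    ax <- reflect_into(anchors[ai, 1] + ar * cos(ath), L)
    ay <- reflect_into(anchors[ai, 2] + ar * sin(ath), L)
  } else {
    ax <- ay <- numeric(0)
  }

  cells <- tibble::tibble(
    x = c(tx, imm_xy[, 1], bx, ax),
    y = c(ty, imm_xy[, 2], by, ay),
    phenotype = c(rep("Neoplastic tumor", n_t), imm_pheno,
                  rep("B cell", n_b), rep("aSMA+ mesenchymal", n_a)))
  cells <- dplyr::bind_cols(cells,
                            canonical_lineage_flags(cells$phenotype),
                            sample_marker_flags(cells$phenotype,
                                                architecture, config))
  cells
}

#' Generate a synthetic cohort
#'
#' Builds matched primary/recurrent tumors for `n_patients` patients. Primary
#' architectures are split `prop_compartmentalized` / mixed (balanced, then
#' shuffled); recurrent tumors keep the primary architecture with probability
#' `recurrent_concordance`. Progression-free survival is exponential with
#' median `pfs_median_days`, with the hazard multiplied by
#' `mixed_hazard_ratio` for patients whose primary is mixed; progression is
#' treated as observed for every patient (no censoring). All randomness flows
#' from `rng_seed`: cohort-level draws first, then one subseed per region.
#'
#' @param config A [synth_config()].
#' @return A [time_cohort()] whose `regions` table carries the generator
#'   ground truth (`architecture_true`, `asma_archetype_true`,
#'   `compartmentalization`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"), config$n_patients >= 2)
  set.seed(config$rng_seed)
  n <- config$n_patients
  patients <- sprintf("P%02d", seq_len(n))
  sites <- sample(c("oral cavity", "oropharynx", "larynx"), n, replace = TRUE)
  n_comp <- round(n * config$prop_compartmentalized)
  arch_primary <- sample(c(rep("compartmentalized", n_comp),
                           rep("mixed", n - n_comp)))
  flip <- runif(n) > config$recurrent_concordance
  other <- c(mixed = "compartmentalized", compartmentalized = "mixed")
  arch_recurrent <- ifelse(flip, other[arch_primary], arch_primary)
  hazard <- log(2) / config$pfs_median_days *
    ifelse(arch_primary == "mixed", config$mixed_hazard_ratio, 1)
  pfs <- pmax(1L, as.integer(ceiling(rexp(n, rate = hazard))))
  tnm <- integer(n)
  tnm[arch_primary == "mixed"] <-
    sample(c(1L, 4L, 4L, 4L), sum(arch_primary == "mixed"), replace = TRUE)
  tnm[arch_primary != "mixed"] <-
    sample(1:4, sum(arch_primary != "mixed"), replace = TRUE)
  therapy <- sample(c("cisplatin + radiation", "cetuximab + radiation"),
                    n, replace = TRUE, prob = c(0.75, 0.25))
  clinical <- tibble::tibble(
    patient_id = patients, pfs_days = pfs, event = TRUE, therapy = therapy,
    tnm_stage = tnm, anatomic_site = sites, hpv_status = "negative")

  tumors <- tibble::tibble(
    patient_id = rep(patients, each = 2),
    timepoint = rep(c("primary", "recurrent"), n),
    anatomic_site = rep(sites, each = 2),
    architecture = as.vector(rbind(arch_primary, arch_recurrent)))
  tumors$tumor_id <- paste0(tumors$patient_id, "-",
                            ifelse(tumors$timepoint == "primary", "P", "R"))
  st <- config$sdlog_immune_tumor
  tumors$immune_factor <- stats::rlnorm(nrow(tumors),
                                        meanlog = -st^2 / 2, sdlog = st)
  nr_pool <- config$n_regions_per_tumor
  tumors$n_regions <- if (length(nr_pool) == 1) {
    rep(nr_pool, nrow(tumors))
  } else {
    sample(nr_pool, nrow(tumors), replace = TRUE)
  }

  regions <- tumors[rep(seq_len(nrow(tumors)), tumors$n_regions), ]
  regions$region_id <- paste0(
    regions$tumor_id, "-r",
    unlist(lapply(tumors$n_regions, seq_len)))
  regions$n_regions <- NULL
  regions$area_mm2 <- (config$region_size_um / 1000)^2
  regions$compartmentalization <-
    unname(config$compartmentalization[regions$architecture])
  regions$asma_archetype_true <- if (config$asma_archetype ==
                                     "by_architecture") {
    ifelse(regions$architecture == "compartmentalized", "lymphoid", "tumor")
  } else rep(config$asma_archetype, nrow(regions))
  region_seeds <- sample.int(.Machine$integer.max - 1L, nrow(regions))

  cells <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ci <- generate_region(config, region_seeds[i],
                          architecture = regions$architecture[i],
                          asma_archetype = regions$asma_archetype_true[i],
                          tumor_immune_factor = regions$immune_factor[i])
    ci$patient_id <- regions$patient_id[i]
    ci$tumor_id <- regions$tumor_id[i]
    ci$timepoint <- regions$timepoint[i]
    ci$region_id <- regions$region_id[i]
    cells[[i]] <- ci
  }
  cells <- dplyr::bind_rows(cells)
  regions <- dplyr::rename(regions, architecture_true = "architecture")
  regions <- dplyr::select(regions, "region_id", "tumor_id", "patient_id",
                           "timepoint", "area_mm2", "anatomic_site",
                           "architecture_true", "asma_archetype_true",
                           "compartmentalization")
  time_cohort(cells, regions, clinical)
}
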