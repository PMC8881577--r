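# End-to-end driver: cohort -> composition -> mixing -> neighborhoods ->
# markers -> survival, with a run manifest for provenance.

#' Pipeline configuration
#'
#' Houses every numeric parameter of the analysis in one place.
#'
#' @param interaction_radius_um Mixing-score interaction radius (15 um).
#' @param neighborhood_radius_um Seed-cell neighborhood radius (30 um).
#' @param cold_reference_count,cold_reference_area_um2 Cold rule: fewer
#'   immune cells than `count` per `area` labels a region cold.
#' @param mix_threshold `"auto"` derives the median primary-region score;
#'   or a fixed numeric threshold (0.107 is the reference cohort value).
#' @param seed_phenotype Seed cell type for neighborhood analysis.
#' @param k `"auto"` selects the neighborhood cluster count by the elbow
#'   rule over `candidate_k_range`; or a fixed integer (7 in the reference
#'   analysis).
#' @param candidate_k_range Candidate k values for the elbow scan.
#' @param bootstrap_reps Repetitions of the one-region-per-tumor bootstrap.
#' @param kl_pseudocount,kl_log_base KL divergence settings (base 2 = bits).
#' @param cov_sd_type `"sample"` or `"population"` standard deviation for
#'   the coefficient of variation.
#' @param change_scope Normalization scope for density-change features.
#' @param rng_seed Root seed; k-means and bootstrap substreams are derived
#'   from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(interaction_radius_um = 15,
                            neighborhood_radius_um = 30,
                            cold_reference_count = 250,
                            cold_reference_area_um2 = 800^2,
                            mix_threshold = "auto",
                            seed_phenotype = "aSMA+ mesenchymal",
                            k = "auto",
                            candidate_k_range = 2:12,
                            bootstrap_reps = 100,
                            kl_pseudocount = 1e-6,
                            kl_log_base = 2,
                            cov_sd_type = "sample",
                            change_scope = "phenotype",
                            rng_seed = 17L) {
  stopifnot(interaction_radius_um > 0, neighborhood_radius_um > 0,
            cold_reference_count > 0, cold_reference_area_um2 > 0,
            bootstrap_reps >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full spatial TiME analysis
#'
#' Executes composition profiling, KL heterogeneity, density-change
#' features, the mixing score with architecture labels, seed-cell
#' neighborhood clustering with tumor grouping, functional-marker
#' comparisons with the region-resampling bootstrap, and Kaplan-Meier /
#' log-rank survival stratification by both the mixing label and the
#' neighborhood group of each patient's primary tumor. The result bundle is
#' a pure function of (cohort, config).
#'
#' @param cohort A [time_cohort()] (for example from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @return List of class `time_results` with elements `densities`, `cov`,
#'   `heterogeneity`, `heterogeneity_immune`, `change_features` (or NULL),
#'   `mixing` (per-region), `tumor_mixing`, `mixing_heterogeneity`,
#'   `neighborhood_profiles`, `neighborhood_model`, `inertia_curve`,
#'   `cluster_summary`, `cluster_proportions` (region/tumor/patient),
#'   `tumor_groups`, `cluster_correlation`, `marker_tests`, `bootstraps`,
#'   `survival`, and `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "time_cohort"),
            inherits(config, "pipeline_config"))
  set.seed(config$rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2)
  kmeans_seed <- sub_seeds[1]
  boot_seed <- sub_seeds[2]
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  densities <- cell_densities(cohort)
  cov <- coefficient_of_variation(cohort, sd_type = config$cov_sd_type)
  het <- heterogeneity_panel(cohort, immune_only = FALSE,
                             pseudocount = config$kl_pseudocount)
  het_imm <- heterogeneity_panel(cohort, immune_only = TRUE,
                                 pseudocount = config$kl_pseudocount)
  change <- tryCatch(density_change_features(cohort,
                                             scope = config$change_scope),
                     error = function(e) {
                       note("change features skipped: ", conditionMessage(e))
                       NULL
                     })

  mix_cfg <- mixing_config(
    interaction_radius_um = config$interaction_radius_um,
    mix_threshold = if (identical(config$mix_threshold, "auto")) NULL else
      config$mix_threshold,
    cold_reference_count = config$cold_reference_count,
    cold_reference_area_um2 = config$cold_reference_area_um2)
  mixing <- region_mixing_table(cohort, mix_cfg)
  note("mixing threshold: ", format(attr(mixing, "mix_threshold")))
  note("regions cold: ", sum(mixing$label == "cold"), "/", nrow(mixing))
  tumor_mix <- tumor_mixing_label(mixing)
  mix_het <- mixing_heterogeneity(mixing)

  profiles <- extract_neighborhoods(cohort,
                                    seed_phenotype = config$seed_phenotype,
                                    radius_um = config$neighborhood_radius_um)
  n_seeds <- sum(cohort$cells$phenotype == config$seed_phenotype)
  note("neighborhood seeds retained: ", nrow(profiles), "/", n_seeds)
  curve <- inertia_curve(profiles, k_range = config$candidate_k_range,
                         rng_seed = kmeans_seed)
  k <- if (identical(config$k, "auto")) as.integer(elbow_select_k(curve))
  else as.integer(config$k)
  note("neighborhood clusters k = ", k)
  model <- cluster_neighborhoods(profiles, k, rng_seed = kmeans_seed)
  summary_tab <- cluster_composition_summary(model, profiles)
  props <- list(
    region = tumor_cluster_proportions(model, profiles, "region"),
    tumor = tumor_cluster_proportions(model, profiles, "tumor"),
    patient = tumor_cluster_proportions(model, profiles, "patient"))
  primary_tumors <- cohort$regions$tumor_id[
    cohort$regions$timepoint == "primary"]
  prim_props <- props$tumor[props$tumor$tumor_id %in% primary_tumors, ]
  tumor_groups <- if (nrow(prim_props) >= 2) {
    group_tumors_by_neighborhoods(prim_props, n_groups = 2)
  } else NULL
  corr <- if (nrow(prim_props) >= 3) {
    cluster_presence_correlation(prim_props)
  } else NULL

  marker_tests <- tryCatch(
    compare_positivity_by_architecture(cohort, mixing),
    error = function(e) {
      note("marker comparisons skipped: ", conditionMessage(e))
      NULL
    })
  comps <- default_comparisons()
  bootstraps <- lapply(seq_len(nrow(comps)), function(i) {
    bootstrap_positivity(cohort, mixing, comps$marker[i],
                         comps$cell_type[i], reps = config$bootstrap_reps,
                         rng_seed = boot_seed)
  })
  names(bootstraps) <- paste(comps$marker, comps$cell_type, sep = " / ")

  surv <- NULL
  if (!is.null(cohort$clinical)) {
    surv <- list()
    prim_mix <- tumor_mix[tumor_mix$timepoint == "primary" &
                            tumor_mix$label != "cold", ]
    cl <- cohort$clinical[match(prim_mix$patient_id,
                                cohort$clinical$patient_id), ]
    if (length(unique(prim_mix$label)) == 2) {
      surv$mixing_logrank <- logrank_test(cl$pfs_days, cl$event,
                                          prim_mix$label)
      surv$mixing_groups <- tibble::tibble(
        patient_id = prim_mix$patient_id, label = prim_mix$label,
        pfs_days = cl$pfs_days, event = cl$event)
      surv$km_mixed <- km_estimate(cl$pfs_days[prim_mix$label == "mixed"],
                                   cl$event[prim_mix$label == "mixed"])
      surv$km_compartmentalized <- km_estimate(
        cl$pfs_days[prim_mix$label == "compartmentalized"],
        cl$event[prim_mix$label == "compartmentalized"])
    } else {
      note("mixing survival split skipped: fewer than two tumor labels")
    }
    if (!is.null(tumor_groups)) {
      gp <- dplyr::left_join(
        tumor_groups,
        dplyr::distinct(cohort$regions, .data$tumor_id, .data$patient_id),
        by = "tumor_id")
      clg <- cohort$clinical[match(gp$patient_id,
                                   cohort$clinical$patient_id), ]
      if (length(unique(gp$group)) == 2) {
        surv$neighborhood_logrank <- logrank_test(clg$pfs_days, clg$event,
                                                  gp$group)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("timepipe")),
    rng_seed = config$rng_seed,
    kmeans_seed = kmeans_seed,
    bootstrap_seed = boot_seed,
    config = config[setdiff(names(config), character())],
    config_hash = rlang::hash(unclass(config)),
    mix_threshold = attr(mixing, "mix_threshold"),
    k = k,
    n_cells = nrow(cohort$cells),
    n_regions = nrow(cohort$regions),
    log = log)

  structure(list(densities = densities, cov = cov, heterogeneity = het,
                 heterogeneity_immune = het_imm, change_features = change,
                 mixing = mixing, tumor_mixing = tumor_mix,
                 mixing_heterogeneity = mix_het,
                 neighborhood_profiles = profiles,
                 neighborhood_model = model, inertia_curve = curve,
                 cluster_summary = summary_tab,
                 cluster_proportions = props, tumor_groups = tumor_groups,
                 cluster_correlation = corr, marker_tests = marker_tests,
                 bootstraps = bootstraps, survival = surv,
                 manifest = manifest),
            class = "time_results")
}

#' @export
print.time_results <- function(x, ...) {
  cat("<time_results>\n")
  cat("  regions:", x$manifest$n_regions,
      " cells:", x$manifest$n_cells, "\n")
  cat("  mixing threshold:", format(x$manifest$mix_threshold), "\n")
  lab <- table(x$mixing$label)
  cat("  labels:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
  cat("  neighborhood clusters k:", x$manifest$k, "\n")
  invisible(x)
}

#' Write a result bundle to disk
#'
#' Emits the tidy tables as CSV and the manifest (with parameter
#' provenance) as JSON.
#'
#' @param results A `time_results` bundle from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "time_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(tab, name) {
    if (is.null(tab)) return()
    path <- file.path(dir, paste0(name, ".csv"))
    write.csv(tab, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit(results$densities, "region_densities")
  emit(results$cov$per_tumor, "cov_per_tumor")
  emit(results$cov$cohort, "cov_cohort")
  emit(results$heterogeneity, "kl_heterogeneity")
  emit(results$heterogeneity_immune, "kl_heterogeneity_immune")
  if (!is.null(results$change_features)) {
    emit(tibble::as_tibble(results$change_features,
                           rownames = "patient_id"), "change_features")
  }
  emit(results$mixing, "region_mixing")
  emit(results$tumor_mixing, "tumor_mixing")
  emit(results$mixing_heterogeneity, "mixing_heterogeneity")
  emit(results$inertia_curve, "inertia_curve")
  emit(results$cluster_summary, "neighborhood_cluster_summary")
  emit(results$cluster_proportions$tumor, "cluster_proportions_tumor")
  emit(results$cluster_proportions$region, "cluster_proportions_region")
  emit(results$cluster_proportions$patient, "cluster_proportions_patient")
  emit(results$tumor_groups, "tumor_groups")
  emit(results$marker_tests, "marker_tests")
  boots <- dplyr::bind_rows(lapply(results$bootstraps, function(b) {
    tibble::tibble(marker = b$marker, cell_type = b$cell_type,
                   rep = seq_len(b$reps), mixed = b$values_mixed,
                   compartmentalized = b$values_compartmentalized)
  }))
  emit(boots, "bootstrap_positivity")
  if (!is.null(results$survival$mixing_groups)) {
    emit(results$survival$mixing_groups, "survival_groups")
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(results$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  files <- c(files, manifest_path)
  invisible(files)
}
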