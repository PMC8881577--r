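# Tumor-immune mixing score: pairwise proximity counting, region and tumor
# classification into mixed / compartmentalized / cold, threshold
# derivation, and mixing-score heterogeneity.

#' Mixing-score configuration
#'
#' @param interaction_radius_um Two cells interact when their centers are
#'   within this distance (inclusive); default 15 um.
#' @param mix_threshold Score above which a region is mixed; the default
#'   0.107 is the cohort-derived median for the assay this package models,
#'   and [derive_mixing_threshold()] recomputes it for any dataset.
#' @param cold_reference_count,cold_reference_area_um2 A region is cold when
#'   its CD45+ immune density falls below `count / area` (defaults: 250
#'   cells per 800^2 um^2 = 390.625 cells/mm^2). The rule is applied as a
#'   density so it transfers to regions of any size.
#' @param ordered_pairs Count ordered pairs (both counts doubled) instead of
#'   distinct unordered pairs. The score is invariant to this choice; the
#'   flag exists so raw counts can be compared across implementations.
#' @return List of class `mixing_config`.
#' @export
mixing_config <- function(interaction_radius_um = 15,
                          mix_threshold = 0.107,
                          cold_reference_count = 250,
                          cold_reference_area_um2 = 800^2,
                          ordered_pairs = FALSE) {
  stopifnot(interaction_radius_um > 0,
            is.null(mix_threshold) || mix_threshold > 0,
            cold_reference_count > 0, cold_reference_area_um2 > 0)
  structure(as.list(environment()), class = "mixing_config")
}

cold_density_threshold <- function(config) {
  config$cold_reference_count / (config$cold_reference_area_um2 / 1e6)
}

#' Count proximity interactions between two phenotype sets
#'
#' Number of unordered cell pairs, one cell from `set_a` and one from
#' `set_b`, whose centers are within `radius_um` (Euclidean, boundary
#' inclusive). When the sets are equal, distinct unordered pairs within the
#' set are counted; a cell never pairs with itself. Overlapping sets are
#' handled by decomposing into exclusive groups.
#'
#' @param cells Tibble with `x`, `y`, `phenotype` columns.
#' @param set_a,set_b Character vectors of phenotype names.
#' @param radius_um Interaction radius.
#' @param ordered Count ordered pairs (doubles the result).
#' @return Pair count (scalar).
#' @export
count_interactions <- function(cells, set_a, set_b, radius_um = 15,
                               ordered = FALSE) {
  stopifnot(radius_um > 0)
  ia <- cells$phenotype %in% set_a
  ib <- cells$phenotype %in% set_b
  a_only <- ia & !ib
  b_only <- ib & !ia
  both <- ia & ib
  n <- 0
  if (any(a_only) && any(b_only)) {
    n <- n + cpp_pair_count_between(cells$x[a_only], cells$y[a_only],
                                    cells$x[b_only], cells$y[b_only],
                                    radius_um)
  }
  if (any(both)) {
    if (any(a_only)) {
      n <- n + cpp_pair_count_between(cells$x[a_only], cells$y[a_only],
                                      cells$x[both], cells$y[both],
                                      radius_um)
    }
    if (any(b_only)) {
      n <- n + cpp_pair_count_between(cells$x[b_only], cells$y[b_only],
                                      cells$x[both], cells$y[both],
                                      radius_um)
    }
    n <- n + cpp_pair_count_within(cells$x[both], cells$y[both], radius_um)
  }
  if (ordered) n <- 2 * n
  n
}

#' Mixing score of one region
#'
#' Ratio of neoplastic-tumor-cell-to-immune-cell proximity pairs to
#' immune-to-immune proximity pairs within the interaction radius. The
#' immune set is the eight CD45+ classes; alpha-SMA+ mesenchymal cells are
#' excluded from both sets. With zero immune-immune pairs the score is
#' undefined (`NA`, `score_defined = FALSE`) and classification must fall
#' back on the cold rule.
#'
#' @param cells Tibble with `x`, `y`, `phenotype` for one region.
#' @param config A [mixing_config()].
#' @param area_mm2 Measured tissue area, for the immune density.
#' @return One-row tibble: n_tumor_immune_pairs, n_immune_immune_pairs,
#'   mixing_score, immune_density, score_defined.
#' @export
mixing_score <- function(cells, config = mixing_config(), area_mm2 = 6.25) {
  r <- config$interaction_radius_um
  ti <- count_interactions(cells, "Neoplastic tumor", immune_phenotypes(),
                           r, ordered = config$ordered_pairs)
  ii <- count_interactions(cells, immune_phenotypes(), immune_phenotypes(),
                           r, ordered = config$ordered_pairs)
  n_imm <- sum(cells$phenotype %in% immune_phenotypes())
  tibble::tibble(
    n_tumor_immune_pairs = ti,
    n_immune_immune_pairs = ii,
    mixing_score = if (ii > 0) ti / ii else NA_real_,
    immune_density = n_imm / area_mm2,
    score_defined = ii > 0)
}

#' Classify regions as mixed, compartmentalized, or cold
#'
#' The cold rule is checked first: immune density below the cold reference
#' density (250 cells per 800^2 um^2 = 390.625 cells/mm^2 by default) labels
#' the region cold regardless of its score. Otherwise the region is mixed
#' when its score strictly exceeds the threshold and compartmentalized
#' otherwise (a score exactly at the threshold is compartmentalized). An
#' undefined score in a non-cold region is an error.
#'
#' @param score Numeric vector of mixing scores (`NA` = undefined).
#' @param immune_density Immune densities, cells/mm^2.
#' @param config A [mixing_config()]; its `mix_threshold` must be set.
#' @return Character vector over `{mixed, compartmentalized, cold}`.
#' @export
classify_region <- function(score, immune_density,
                            config = mixing_config()) {
  if (is.null(config$mix_threshold)) {
    stop("mix_threshold is unset; derive one with derive_mixing_threshold()")
  }
  cold <- immune_density < cold_density_threshold(config)
  if (any(is.na(score) & !cold)) {
    stop("undefined mixing score in non-cold region(s): pathological input")
  }
  ifelse(cold, "cold",
         ifelse(score > config$mix_threshold, "mixed", "compartmentalized"))
}

#' Per-region mixing table for a cohort
#'
#' Computes scores for every region, derives the threshold from the primary
#' regions when the config leaves it `NULL` (or `derive = TRUE`), and
#' attaches labels.
#'
#' @param cohort A [time_cohort()].
#' @param config A [mixing_config()].
#' @param derive Recompute the threshold from this cohort's primary regions
#'   instead of using `config$mix_threshold`.
#' @return Tibble with one row per region: ids, pair counts, mixing_score,
#'   immune_density, score_defined, label; the threshold used is stored in
#'   the `"mix_threshold"` attribute.
#' @export
region_mixing_table <- function(cohort, config = mixing_config(),
                                derive = is.null(config$mix_threshold)) {
  stopifnot(inherits(cohort, "time_cohort"))
  split_cells <- split(cohort$cells, cohort$cells$region_id)
  rows <- lapply(cohort$regions$region_id, function(rid) {
    cells <- split_cells[[rid]]
    if (is.null(cells)) cells <- cohort$cells[0, ]
    area <- cohort$regions$area_mm2[cohort$regions$region_id == rid]
    res <- mixing_score(cells, config, area_mm2 = area)
    res$region_id <- rid
    res
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(
    dplyr::select(cohort$regions, "region_id", "tumor_id", "patient_id",
                  "timepoint", "anatomic_site"),
    out, by = "region_id")
  threshold <- config$mix_threshold
  if (derive) {
    threshold <- derive_mixing_threshold(out)
    config$mix_threshold <- threshold
  }
  out$label <- classify_region(out$mixing_score, out$immune_density, config)
  attr(out, "mix_threshold") <- threshold
  out
}

#' Derive the mixed/compartmentalized threshold from primary tumors
#'
#' Median of the finite mixing scores over all primary-tumor regions
#' (default), or over per-tumor mean scores with
#' `granularity = "tumor"`. Even-sized sets use the midpoint convention.
#'
#' @param mixing_table Output of [region_mixing_table()] (labels not
#'   required), or any tibble with `timepoint`, `tumor_id`, `mixing_score`.
#' @param granularity `"region"` or `"tumor"`.
#' @return Scalar threshold.
#' @export
derive_mixing_threshold <- function(mixing_table,
                                    granularity = c("region", "tumor")) {
  granularity <- match.arg(granularity)
  prim <- mixing_table[mixing_table$timepoint == "primary" &
                         !is.na(mixing_table$mixing_score), ]
  if (nrow(prim) == 0) stop("no primary region with a finite mixing score")
  if (granularity == "region") {
    median(prim$mixing_score)
  } else {
    per_tumor <- tapply(prim$mixing_score, prim$tumor_id, mean)
    median(per_tumor)
  }
}

#' Tumor-level mixing score and label
#'
#' The tumor score is the unweighted mean of its regions' scores, excluding
#' cold regions (their scores are unstable); the tumor label applies the
#' mixed/compartmentalized threshold to that mean. A tumor whose regions are
#' all cold is labeled cold (`NA` score).
#'
#' @param mixing_table Output of [region_mixing_table()] with labels.
#' @param config The [mixing_config()] used (for the threshold); defaults to
#'   the threshold recorded on `mixing_table`.
#' @return Tibble: tumor_id, patient_id, timepoint, n_regions, n_cold,
#'   mixing_score, label.
#' @export
tumor_mixing_label <- function(mixing_table, config = NULL) {
  threshold <- if (!is.null(config)) config$mix_threshold else
    attr(mixing_table, "mix_threshold")
  if (is.null(threshold)) stop("no mixing threshold available")
  g <- dplyr::group_by(mixing_table, .data$tumor_id, .data$patient_id,
                       .data$timepoint)
  out <- dplyr::summarise(
    g,
    n_regions = dplyr::n(),
    n_cold = sum(.data$label == "cold"),
    mixing_score = if (all(.data$label == "cold")) NA_real_ else
      mean(.data$mixing_score[.data$label != "cold"]),
    .groups = "drop")
  out$label <- ifelse(
    is.na(out$mixing_score), "cold",
    ifelse(out$mixing_score > threshold, "mixed", "compartmentalized"))
  out
}

#' Mixing-score heterogeneity at five cohort levels
#'
#' For each region with a finite score, the absolute difference between its
#' score and the mean score of the same five reference groups used by
#' [heterogeneity_panel()] (the region is included in its own group mean).
#' Singleton groups give 0 and are flagged degenerate.
#'
#' @param mixing_table Output of [region_mixing_table()].
#' @param leave_one_out Exclude the region from its group mean.
#' @return Tibble: region_id, level, abs_diff, n_group, degenerate.
#' @export
mixing_heterogeneity <- function(mixing_table, leave_one_out = FALSE) {
  tab <- mixing_table[!is.na(mixing_table$mixing_score), ]
  groups <- list(
    intra_tumor = tab$tumor_id,
    intra_patient = tab$patient_id,
    inter_patient_timepoint = tab$timepoint,
    inter_patient_site = tab$anatomic_site,
    inter_patient_all = rep("all", nrow(tab)))
  out <- list()
  for (lev in names(groups)) {
    g <- groups[[lev]]
    for (i in seq_len(nrow(tab))) {
      members <- which(g == g[i])
      ref_members <- if (leave_one_out) setdiff(members, i) else members
      if (length(ref_members) == 0) next
      ref <- mean(tab$mixing_score[ref_members])
      out[[length(out) + 1]] <- tibble::tibble(
        region_id = tab$region_id[i], level = lev,
        abs_diff = abs(tab$mixing_score[i] - ref),
        n_group = length(members),
        degenerate = length(members) == 1 && !leave_one_out)
    }
  }
  dplyr::bind_rows(out)
}
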