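# Radius-based cellular neighborhoods around seed cells, k-means clustering
# of neighborhood compositions, summaries, per-unit cluster proportions,
# tumor grouping, and cluster-presence correlations.

#' Extract seed-cell neighborhood composition profiles
#'
#' For every cell of `seed_phenotype`, cells of any phenotype whose centers
#' lie within `radius_um` of the seed's center (inclusive) are its
#' neighbors; the seed is excluded from its own neighborhood. The profile is
#' the fraction of each phenotype among the neighbors. Seeds with zero
#' neighbors are dropped.
#'
#' @param cohort A [time_cohort()] (all regions are processed), or a tibble
#'   of cells with `x`, `y`, `phenotype` (single unnamed region).
#' @param seed_phenotype Phenotype of the seed cells.
#' @param radius_um Neighborhood radius (default 30 um).
#' @return Tibble with one row per retained seed: region/tumor/patient ids
#'   (when available), `seed_id` (row index of the seed in its region's cell
#'   table), `neighbor_count`, and one fraction column per phenotype
#'   (rows sum to 1).
#' @export
extract_neighborhoods <- function(cohort,
                                  seed_phenotype = "aSMA+ mesenchymal",
                                  radius_um = 30) {
  stopifnot(radius_um > 0)
  if (inherits(cohort, "time_cohort")) {
    meta <- cohort$regions
    parts <- lapply(meta$region_id, function(rid) {
      cells <- cohort$cells[cohort$cells$region_id == rid, ]
      p <- region_neighborhoods(cells, seed_phenotype, radius_um)
      if (nrow(p) == 0) return(p)
      info <- meta[meta$region_id == rid, ]
      tibble::add_column(p, region_id = rid, tumor_id = info$tumor_id,
                         patient_id = info$patient_id,
                         timepoint = info$timepoint, .before = 1)
    })
    dplyr::bind_rows(parts)
  } else {
    region_neighborhoods(tibble::as_tibble(cohort), seed_phenotype,
                         radius_um)
  }
}

region_neighborhoods <- function(cells, seed_phenotype, radius_um) {
  types <- phenotype_levels()
  empty <- tibble::tibble(seed_id = integer(), neighbor_count = numeric())
  for (p in types) empty[[p]] <- numeric()
  seeds <- which(cells$phenotype == seed_phenotype)
  if (length(seeds) == 0 || nrow(cells) == 0) return(empty)
  code <- match(cells$phenotype, types)
  counts <- cpp_neighbor_type_counts(as.integer(seeds - 1L),
                                     cells$x, cells$y,
                                     as.integer(code), length(types),
                                     radius_um)
  colnames(counts) <- types
  total <- rowSums(counts)
  keep <- total > 0
  if (!any(keep)) return(empty)
  frac <- counts[keep, , drop = FALSE] / total[keep]
  out <- tibble::tibble(seed_id = seeds[keep], neighbor_count = total[keep])
  dplyr::bind_cols(out, tibble::as_tibble(frac))
}

profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[, phenotype_levels()])
  rownames(m) <- NULL
  m
}

#' K-means clustering of neighborhood composition profiles
#'
#' Lloyd's k-means with `nstart` restarts on the raw composition fraction
#' vectors (Euclidean objective), deterministic given `rng_seed`.
#'
#' @param profiles Output of [extract_neighborhoods()].
#' @param k Number of clusters (>= 2).
#' @param rng_seed Seed for the restarts.
#' @param nstart Number of random restarts.
#' @return List of class `neighborhood_clusters`: `k`, `centroids` (k x
#'   phenotypes), `cluster` (assignment per profile row), `inertia` (total
#'   within-cluster sum of squares), `sizes`.
#' @export
cluster_neighborhoods <- function(profiles, k, rng_seed = 17, nstart = 10) {
  if (k < 2) stop("k must be at least 2")
  m <- profile_matrix(profiles)
  if (nrow(m) < k) stop("need at least k profiles")
  set.seed(rng_seed)
  fit <- kmeans(m, centers = k, nstart = nstart, iter.max = 100)
  structure(list(k = k, centroids = fit$centers, cluster = fit$cluster,
                 inertia = fit$tot.withinss, sizes = fit$size,
                 rng_seed = rng_seed),
            class = "neighborhood_clusters")
}

#' Within-cluster inertia over a range of candidate k
#'
#' @param profiles Output of [extract_neighborhoods()].
#' @param k_range Candidate cluster counts (default 2:12).
#' @param rng_seed,nstart Passed to [cluster_neighborhoods()].
#' @return Tibble: k, inertia.
#' @export
inertia_curve <- function(profiles, k_range = 2:12, rng_seed = 17,
                          nstart = 10) {
  tibble::tibble(
    k = k_range,
    inertia = vapply(k_range, function(k) {
      cluster_neighborhoods(profiles, k, rng_seed, nstart)$inertia
    }, numeric(1)))
}

#' Elbow selection of the cluster count
#'
#' Picks the k at the maximum perpendicular distance from the chord joining
#' the inertia curve's endpoints (a deterministic stand-in for the visual
#' elbow); ties break toward smaller k. The full curve is retained in the
#' `"curve"` attribute so the choice can be overridden.
#'
#' @param curve Tibble with columns `k` and `inertia` over a contiguous
#'   candidate range (see [inertia_curve()]).
#' @return Selected k (integer) with the curve attached as an attribute.
#' @export
elbow_select_k <- function(curve) {
  stopifnot(all(c("k", "inertia") %in% names(curve)), nrow(curve) >= 1)
  if (nrow(curve) == 1) {
    return(structure(curve$k[1], curve = curve))
  }
  if (any(diff(curve$inertia) > 0)) {
    warning("inertia curve is not monotone decreasing")
  }
  x <- curve$k
  y <- curve$inertia
  n <- length(x)
  # distance from each point to the chord (x1,y1)-(xn,yn)
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  d <- abs(dy * x - dx * y + x[n] * y[1] - y[n] * x[1]) / sqrt(dx^2 + dy^2)
  best <- which(d == max(d))[1] # ties toward smaller k
  structure(curve$k[best], curve = curve)
}

#' Mean neighborhood composition per cluster
#'
#' Unweighted mean of member composition vectors for each cluster; rows sum
#' to 1. Empty clusters are excluded with a warning.
#'
#' @param model A `neighborhood_clusters` fit.
#' @param profiles The profiles the model was fitted on.
#' @return Tibble: cluster, n_profiles, one column per phenotype.
#' @export
cluster_composition_summary <- function(model, profiles) {
  m <- profile_matrix(profiles)
  stopifnot(nrow(m) == length(model$cluster))
  out <- list()
  for (cl in seq_len(model$k)) {
    members <- model$cluster == cl
    if (!any(members)) {
      warning("cluster ", cl, " is empty; excluded")
      next
    }
    row <- tibble::as_tibble(rbind(colMeans(m[members, , drop = FALSE])))
    out[[length(out) + 1]] <- dplyr::bind_cols(
      tibble::tibble(cluster = cl, n_profiles = sum(members)), row)
  }
  dplyr::bind_rows(out)
}

#' Per-unit neighborhood cluster proportions
#'
#' For each region, tumor, or patient, the percentage of its neighborhood
#' profiles assigned to each cluster (rows sum to 100). Units with zero
#' profiles do not appear.
#'
#' @param model A `neighborhood_clusters` fit.
#' @param profiles The profiles the model was fitted on, carrying the id
#'   columns from [extract_neighborhoods()] on a cohort.
#' @param level `"tumor"` (default), `"region"`, or `"patient"`.
#' @return Wide tibble: unit id column, then `cluster_1` ... `cluster_k`
#'   percentage columns.
#' @export
tumor_cluster_proportions <- function(model, profiles,
                                      level = c("tumor", "region",
                                                "patient")) {
  level <- match.arg(level)
  id_col <- c(tumor = "tumor_id", region = "region_id",
              patient = "patient_id")[[level]]
  if (!id_col %in% names(profiles)) {
    stop("profiles lack the ", id_col, " column")
  }
  df <- tibble::tibble(unit = profiles[[id_col]],
                       cluster = factor(model$cluster,
                                        levels = seq_len(model$k)))
  tab <- table(df$unit, df$cluster)
  pct <- sweep(tab, 1, rowSums(tab), "/") * 100
  out <- tibble::as_tibble(as.data.frame.matrix(pct), rownames = id_col)
  names(out)[-1] <- paste0("cluster_", seq_len(model$k))
  out
}

#' Group tumors by their neighborhood-cluster usage
#'
#' Ward/Euclidean hierarchical clustering of the log10(percent + 1)
#' normalized cluster-proportion features, cut at `n_groups`.
#'
#' @param percent_table Output of [tumor_cluster_proportions()].
#' @param n_groups Number of groups (default 2).
#' @return Tibble with the unit id and `group`; the tree is attached as the
#'   `"tree"` attribute.
#' @export
group_tumors_by_neighborhoods <- function(percent_table, n_groups = 2) {
  id_col <- names(percent_table)[1]
  m <- log10p1_normalize(as.matrix(percent_table[, -1]))
  rownames(m) <- percent_table[[id_col]]
  fit <- hierarchical_cluster(m, n_groups)
  out <- tibble::tibble(!!id_col := percent_table[[id_col]],
                        group = unname(fit$labels))
  attr(out, "tree") <- fit$tree
  out
}

#' Pairwise correlation of cluster presence across units
#'
#' Pearson (default) correlation between cluster-percentage columns across
#' tumors or patients. Zero-variance columns yield `NA` entries with a
#' warning.
#'
#' @param percent_table Output of [tumor_cluster_proportions()] with at
#'   least three units.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
cluster_presence_correlation <- function(percent_table,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as.matrix(percent_table[, -1])
  if (nrow(m) < 3) stop("need at least three units")
  zero_var <- apply(m, 2, var) == 0
  if (any(zero_var)) {
    warning("zero-variance cluster column(s): ",
            paste(colnames(m)[zero_var], collapse = ", "))
  }
  suppressWarnings(cor(m, method = method))
}
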