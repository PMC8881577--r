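# Per-region composition profiling, coefficient of variation, KL-divergence
# heterogeneity, and the normalization/clustering/embedding utilities built
# on top of composition features.

#' Per-region cell-type densities and fractions
#'
#' Counts each phenotype per region and divides by the region's measured
#' tissue area (cells/mm^2). Fractions are computed over all ten phenotypes
#' and, separately, over the eight CD45+ immune classes; both are `NA` for
#' regions with no cells of the relevant set (flagged by `empty`).
#'
#' @param cohort A [time_cohort()].
#' @return Long tibble: region_id, phenotype, n, density, fraction,
#'   immune_fraction, empty.
#' @export
cell_densities <- function(cohort) {
  stopifnot(inherits(cohort, "time_cohort"))
  if (any(cohort$regions$area_mm2 <= 0)) stop("area_mm2 must be positive")
  grid <- tidyr::expand_grid(region_id = cohort$regions$region_id,
                             phenotype = phenotype_levels())
  counts <- dplyr::count(cohort$cells, .data$region_id, .data$phenotype)
  out <- dplyr::left_join(grid, counts, by = c("region_id", "phenotype"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::left_join(
    out, dplyr::select(cohort$regions, "region_id", "area_mm2"),
    by = "region_id")
  out$density <- out$n / out$area_mm2
  out <- dplyr::group_by(out, .data$region_id)
  out <- dplyr::mutate(
    out,
    total = sum(.data$n),
    fraction = ifelse(.data$total > 0, .data$n / .data$total, NA_real_),
    immune_total = sum(.data$n[.data$phenotype %in% immune_phenotypes()]),
    immune_fraction = ifelse(
      .data$phenotype %in% immune_phenotypes() & .data$immune_total > 0,
      .data$n / .data$immune_total, NA_real_),
    empty = .data$total == 0)
  out <- dplyr::ungroup(out)
  dplyr::select(out, "region_id", "phenotype", "n", "density", "fraction",
                "immune_fraction", "empty")
}

# regions x phenotypes density matrix (rownames = region ids)
density_matrix <- function(cohort) {
  d <- cell_densities(cohort)
  wide <- tidyr::pivot_wider(
    dplyr::select(d, "region_id", "phenotype", "density"),
    names_from = "phenotype", values_from = "density")
  m <- as.matrix(wide[, phenotype_levels()])
  rownames(m) <- wide$region_id
  m
}

# regions x phenotypes fraction matrix; immune_only restricts the support
fraction_matrix <- function(cohort, immune_only = FALSE) {
  d <- cell_densities(cohort)
  col <- if (immune_only) "immune_fraction" else "fraction"
  keep <- if (immune_only) immune_phenotypes() else phenotype_levels()
  d <- d[d$phenotype %in% keep, c("region_id", "phenotype", col)]
  wide <- tidyr::pivot_wider(d, names_from = "phenotype",
                             values_from = dplyr::all_of(col))
  m <- as.matrix(wide[, keep])
  rownames(m) <- wide$region_id
  m
}

#' Coefficient of variation of cell-type densities across a tumor's regions
#'
#' For every tumor with at least two regions, the CoV (standard deviation /
#' mean) of each phenotype's density over the tumor's regions; the cohort
#' value is the unweighted mean over tumors. Phenotypes absent from every
#' region of a tumor (mean density 0) have no defined CoV and are excluded
#' from that tumor.
#'
#' @param cohort A [time_cohort()].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return List with `per_tumor` (tumor_id, phenotype, cov) and `cohort`
#'   (phenotype, mean_cov, n_tumors), the latter sorted by decreasing
#'   mean CoV.
#' @export
coefficient_of_variation <- function(cohort,
                                     sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  d <- cell_densities(cohort)
  d <- dplyr::left_join(
    d, dplyr::select(cohort$regions, "region_id", "tumor_id"),
    by = "region_id")
  sdfun <- function(v) {
    if (sd_type == "sample") sd(v) else sqrt(mean((v - mean(v))^2))
  }
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$tumor_id, .data$phenotype),
    n_regions = dplyr::n(),
    mu = mean(.data$density),
    cov = if (dplyr::n() >= 2 && mean(.data$density) > 0) {
      sdfun(.data$density) / mean(.data$density)
    } else NA_real_,
    .groups = "drop")
  per <- per[per$n_regions >= 2, ]
  dropped <- per[is.na(per$cov), ]
  if (nrow(dropped) > 0) {
    warning("CoV undefined (zero mean density) for ", nrow(dropped),
            " tumor-phenotype pair(s); excluded")
  }
  per <- per[!is.na(per$cov), c("tumor_id", "phenotype", "cov")]
  coh <- dplyr::summarise(dplyr::group_by(per, .data$phenotype),
                          mean_cov = mean(.data$cov),
                          n_tumors = dplyr::n(), .groups = "drop")
  coh <- dplyr::arrange(coh, dplyr::desc(.data$mean_cov))
  list(per_tumor = per, cohort = coh)
}

#' Kullback-Leibler divergence between two composition distributions
#'
#' `sum(p * log(p / q))` in the requested log base (bits for base 2). A
#' pseudocount is added to every category of both distributions before
#' renormalization, so absent phenotypes do not produce infinities; with
#' `pseudocount = 0` a zero in `q` where `p > 0` yields `Inf`.
#'
#' @param p,q Non-negative numeric vectors on the same support (renormalized
#'   internally).
#' @param pseudocount Added to every category before renormalization.
#' @param base Logarithm base (2 = bits).
#' @return Non-negative scalar divergence.
#' @export
kl_divergence <- function(p, q, pseudocount = 1e-6, base = 2) {
  if (length(p) != length(q)) stop("p and q must have the same support")
  if (any(p < 0) || any(q < 0)) stop("distributions must be non-negative")
  p <- p + pseudocount
  q <- q + pseudocount
  if (sum(p) == 0 || sum(q) == 0) stop("degenerate all-zero distribution")
  p <- p / sum(p)
  q <- q / sum(q)
  terms <- rep(0, length(p))
  pos <- p > 0
  terms[pos] <- p[pos] * (log(p[pos]) - log(q[pos])) / log(base)
  # p > 0 against q = 0 (only reachable with pseudocount = 0)
  if (any(pos & q == 0)) return(Inf)
  max(sum(terms), 0)
}

#' Region-level KL heterogeneity panel at five cohort levels
#'
#' For each region, the KL divergence (base 2) from its cell-type fraction
#' vector to the mean fraction vector of five reference groups: regions of
#' the same tumor (`intra_tumor`); the patient's primary and recurrent
#' regions (`intra_patient`); cohort regions of the same timepoint
#' (`inter_patient_timepoint`); cohort regions of the same anatomic site
#' (`inter_patient_site`); and all regions (`inter_patient_all`). The region
#' itself is included in its group means. Singleton groups give a degenerate
#' divergence of 0 and are flagged.
#'
#' @param cohort A [time_cohort()].
#' @param immune_only Restrict the distribution to the eight immune classes.
#' @param pseudocount Passed to [kl_divergence()].
#' @return Tibble: region_id, level, kl, n_group, degenerate.
#' @export
heterogeneity_panel <- function(cohort, immune_only = FALSE,
                                pseudocount = 1e-6) {
  fm <- fraction_matrix(cohort, immune_only = immune_only)
  keep <- rownames(fm)[stats::complete.cases(fm)]
  fm <- fm[keep, , drop = FALSE]
  meta <- cohort$regions[match(keep, cohort$regions$region_id), ]
  groups <- list(
    intra_tumor = meta$tumor_id,
    intra_patient = meta$patient_id,
    inter_patient_timepoint = meta$timepoint,
    inter_patient_site = meta$anatomic_site,
    inter_patient_all = rep("all", nrow(meta)))
  out <- list()
  for (lev in names(groups)) {
    g <- groups[[lev]]
    for (i in seq_along(keep)) {
      members <- which(g == g[i])
      ref <- colMeans(fm[members, , drop = FALSE])
      out[[length(out) + 1]] <- tibble::tibble(
        region_id = keep[i], level = lev,
        kl = kl_divergence(fm[i, ], ref, pseudocount = pseudocount),
        n_group = length(members),
        degenerate = length(members) == 1)
    }
  }
  dplyr::bind_rows(out)
}

#' log10(x + 1) normalization
#'
#' @param x Non-negative numeric vector or matrix.
#' @return Elementwise `log10(x + 1)`.
#' @export
log10p1_normalize <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("log10 + 1 requires non-negative input")
  log10(x + 1)
}

#' Ward/Euclidean hierarchical clustering of a feature matrix
#'
#' Agglomerative clustering with Euclidean distances and Ward linkage
#' (`hclust` method `ward.D2`, the Ward criterion on Euclidean distances),
#' cut to `n_groups`.
#'
#' @param features Numeric matrix or data frame (rows = observations); row
#'   names label the observations.
#' @param n_groups Number of groups the tree is cut into.
#' @return List with `labels` (named integer vector) and `tree` (`hclust`).
#' @export
hierarchical_cluster <- function(features, n_groups) {
  m <- as.matrix(features)
  if (anyNA(m)) stop("feature matrix must have no missing values")
  if (n_groups > nrow(m)) stop("n_groups exceeds the number of rows")
  tree <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  labels <- cutree(tree, k = n_groups)
  list(labels = labels, tree = tree)
}

#' Principal component embedding of composition features
#'
#' Standard PCA on column-centered features. To make orientations
#' reproducible, each component's sign is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param features Numeric matrix (rows = observations).
#' @param n_components Number of components returned (default 2).
#' @return List with `scores` (n x n_components), `explained_variance`
#'   (proportion per returned component), and `rotation`.
#' @export
pca_embed <- function(features, n_components = 2) {
  m <- as.matrix(features)
  if (nrow(m) < 2) stop("PCA needs at least two rows")
  if (all(apply(m, 2, var) == 0)) {
    stop("constant feature matrix: components undefined")
  }
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  for (j in seq_len(ncol(fit$rotation))) {
    pivot <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[pivot, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       rotation = fit$rotation[, seq_len(k), drop = FALSE])
}

#' Signed [-1, 1] normalization of primary-to-recurrent density changes
#'
#' Raw change = recurrent - primary density per phenotype. The absolute
#' changes are scaled to `[0, 1]` by the maximum absolute change within the
#' normalization scope, and the original sign is restored, so outputs lie in
#' `[-1, 1]` with 0 meaning no change. With scope `"phenotype"` each
#' phenotype (column) is scaled across patients; `"global"` uses one scale
#' for the whole matrix.
#'
#' @param primary,recurrent Numeric matrices (patients x phenotypes) of
#'   tumor-averaged densities, or single named vectors for one patient.
#' @param scope `"phenotype"` (column-wise, default) or `"global"`.
#' @return Matrix of normalized changes in `[-1, 1]`.
#' @export
normalized_density_change <- function(primary, recurrent,
                                      scope = c("phenotype", "global")) {
  scope <- match.arg(scope)
  if (is.null(dim(primary))) primary <- rbind(primary)
  if (is.null(dim(recurrent))) recurrent <- rbind(recurrent)
  stopifnot(all(dim(primary) == dim(recurrent)))
  raw <- recurrent - primary
  scale_abs <- function(v) {
    m <- max(abs(v))
    if (m == 0) rep(0, length(v)) else abs(v) / m * sign(v)
  }
  out <- if (scope == "global") {
    matrix(scale_abs(as.vector(raw)), nrow = nrow(raw),
           dimnames = dimnames(raw))
  } else {
    apply(raw, 2, scale_abs)
  }
  if (is.null(dim(out))) out <- rbind(out) # single-patient input
  dimnames(out) <- dimnames(raw)
  out
}

#' Per-patient density-change features from a cohort
#'
#' Averages each phenotype's density over a tumor's regions, pairs each
#' patient's primary and recurrent tumors, and returns the normalized
#' signed change matrix (see [normalized_density_change()]).
#'
#' @param cohort A [time_cohort()] with both timepoints per patient.
#' @param scope Passed to [normalized_density_change()].
#' @return Patients x phenotypes matrix of changes in `[-1, 1]`.
#' @export
density_change_features <- function(cohort, scope = "phenotype") {
  d <- cell_densities(cohort)
  d <- dplyr::left_join(
    d, dplyr::select(cohort$regions, "region_id", "tumor_id", "patient_id",
                     "timepoint"),
    by = "region_id")
  tumor_avg <- dplyr::summarise(
    dplyr::group_by(d, .data$patient_id, .data$timepoint, .data$phenotype),
    density = mean(.data$density), .groups = "drop")
  per_tp <- function(tp) {
    wide <- tidyr::pivot_wider(
      tumor_avg[tumor_avg$timepoint == tp,
                c("patient_id", "phenotype", "density")],
      names_from = "phenotype", values_from = "density")
    m <- as.matrix(wide[, phenotype_levels()])
    rownames(m) <- wide$patient_id
    m
  }
  prim <- per_tp("primary")
  rec <- per_tp("recurrent")
  shared <- intersect(rownames(prim), rownames(rec))
  if (length(shared) == 0) stop("no patient has both timepoints")
  normalized_density_change(prim[shared, , drop = FALSE],
                            rec[shared, , drop = FALSE], scope = scope)
}
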