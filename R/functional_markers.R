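# Functional-marker positivity per cell type per region,
# architecture-stratified comparisons, and the one-region-per-tumor
# bootstrap.

#' Marker positivity of one cell type in one region
#'
#' Fraction of cells of `cell_type` whose flag for `marker` is TRUE. `NA`
#' when the region contains no cell of the type (excluded downstream).
#'
#' @param cells Tibble of one region's cells with `phenotype` and the marker
#'   flag column.
#' @param cell_type A phenotype name.
#' @param marker A functional-marker column name (`"PD1"`, `"PDL1"`,
#'   `"KI67"`).
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
marker_positivity <- function(cells, cell_type, marker) {
  if (!marker %in% names(cells)) stop("no marker column ", marker)
  sel <- cells$phenotype == cell_type
  if (!any(sel)) return(NA_real_)
  mean(cells[[marker]][sel])
}

#' Per-region marker positivity table
#'
#' @param cohort A [time_cohort()].
#' @param comparisons Tibble with columns `marker` and `cell_type`; defaults
#'   to PD-1 on the three lymphocyte classes and Ki-67 on antigen presenting
#'   cells.
#' @return Long tibble: region_id, cell_type, marker, n_cells, positivity
#'   (`NA` where the type is absent).
#' @export
positivity_table <- function(cohort, comparisons = default_comparisons()) {
  stopifnot(inherits(cohort, "time_cohort"))
  out <- list()
  split_cells <- split(cohort$cells, cohort$cells$region_id)
  for (rid in cohort$regions$region_id) {
    cells <- split_cells[[rid]]
    for (i in seq_len(nrow(comparisons))) {
      ct <- comparisons$cell_type[i]
      mk <- comparisons$marker[i]
      n_ct <- if (is.null(cells)) 0L else sum(cells$phenotype == ct)
      out[[length(out) + 1]] <- tibble::tibble(
        region_id = rid, cell_type = ct, marker = mk, n_cells = n_ct,
        positivity = if (n_ct > 0) marker_positivity(cells, ct, mk)
        else NA_real_)
    }
  }
  dplyr::bind_rows(out)
}

#' @rdname positivity_table
#' @details `default_comparisons()` lists the marker/cell-type pairs tested
#'   by default, with the pre-specified one-tailed direction for
#'   architecture comparisons (PD-1 higher in mixed regions; Ki-67 on APCs
#'   higher in compartmentalized regions).
#' @export
default_comparisons <- function() {
  tibble::tribble(
    ~marker, ~cell_type,                ~direction,
    "PD1",   "CD8 T cell",              "mixed_greater",
    "PD1",   "CD4 T helper",            "mixed_greater",
    "PD1",   "B cell",                  "mixed_greater",
    "KI67",  "Antigen presenting cell", "compartmentalized_greater")
}

#' Compare marker positivity between mixed and compartmentalized regions
#'
#' Splits per-region positivity fractions by architecture label and runs a
#' one-tailed Mann-Whitney U test per (marker, cell type) comparison, with
#' Benjamini-Hochberg correction across the family tested in one call. Cold
#' regions are excluded by default; the one-tailed direction is always
#' specified explicitly per comparison, never inferred from the data.
#'
#' @param cohort A [time_cohort()].
#' @param mixing_table Output of [region_mixing_table()] with labels.
#' @param comparisons Tibble with `marker`, `cell_type`, `direction`
#'   (`"mixed_greater"`, `"compartmentalized_greater"`, or `"two_sided"`).
#' @param exclude_cold Drop cold regions before testing (default TRUE).
#' @return Tibble: marker, cell_type, direction, n_mixed,
#'   n_compartmentalized, n_regions, statistic, p, p_adj.
#' @export
compare_positivity_by_architecture <- function(cohort, mixing_table,
                                               comparisons =
                                                 default_comparisons(),
                                               exclude_cold = TRUE) {
  pos <- positivity_table(cohort, comparisons)
  pos <- dplyr::left_join(
    pos, dplyr::select(mixing_table, "region_id", "label"),
    by = "region_id")
  if (exclude_cold) pos <- pos[pos$label != "cold", ]
  out <- list()
  for (i in seq_len(nrow(comparisons))) {
    ct <- comparisons$cell_type[i]
    mk <- comparisons$marker[i]
    dir <- comparisons$direction[i]
    sub <- pos[pos$cell_type == ct & pos$marker == mk &
                 !is.na(pos$positivity), ]
    mixed <- sub$positivity[sub$label == "mixed"]
    comp <- sub$positivity[sub$label == "compartmentalized"]
    if (length(mixed) == 0 || length(comp) == 0) {
      stop("empty architecture group for ", mk, " on ", ct)
    }
    alternative <- switch(dir,
                          mixed_greater = "greater",
                          compartmentalized_greater = "less",
                          two_sided = "two.sided",
                          stop("unknown direction ", dir))
    # exact null distribution when sample sizes permit and there are no
    # ties; normal approximation otherwise (wilcox.test's own policy)
    tst <- suppressWarnings(wilcox.test(mixed, comp,
                                        alternative = alternative))
    out[[length(out) + 1]] <- tibble::tibble(
      marker = mk, cell_type = ct, direction = dir,
      n_mixed = length(mixed), n_compartmentalized = length(comp),
      n_regions = length(mixed) + length(comp),
      statistic = unname(tst$statistic), p = tst$p.value)
  }
  out <- dplyr::bind_rows(out)
  out$p_adj <- bh_correct(out$p)
  out
}

#' One-region-per-tumor bootstrap of marker positivity
#'
#' Each repetition samples one region uniformly from every tumor, splits the
#' sampled regions by their architecture label, and records each group's
#' mean positivity fraction. Repetitions where a group is empty record `NA`
#' for that group but are retained, so both value lists always have length
#' `reps`. Deterministic given `rng_seed`.
#'
#' @param cohort A [time_cohort()].
#' @param mixing_table Output of [region_mixing_table()] with labels.
#' @param marker,cell_type The positivity being bootstrapped.
#' @param reps Number of repetitions (default 100).
#' @param rng_seed Seed.
#' @param exclude_cold Drop cold regions from group means within each rep.
#' @return List of class `bootstrap_result`: marker, cell_type, reps,
#'   rng_seed, values_mixed, values_compartmentalized (each length `reps`).
#' @export
bootstrap_positivity <- function(cohort, mixing_table, marker, cell_type,
                                 reps = 100, rng_seed = 17,
                                 exclude_cold = TRUE) {
  stopifnot(inherits(cohort, "time_cohort"), reps >= 1)
  pos <- positivity_table(cohort,
                          tibble::tibble(marker = marker,
                                         cell_type = cell_type))
  pos <- dplyr::left_join(
    pos,
    dplyr::select(mixing_table, "region_id", "tumor_id", "label"),
    by = "region_id")
  by_tumor <- split(pos, pos$tumor_id)
  if (any(vapply(by_tumor, nrow, integer(1)) == 0)) {
    stop("every tumor needs at least one region")
  }
  set.seed(rng_seed)
  vm <- vc <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    pick <- lapply(by_tumor, function(tt) tt[sample.int(nrow(tt), 1), ])
    pick <- dplyr::bind_rows(pick)
    if (exclude_cold) pick <- pick[pick$label != "cold", ]
    pick <- pick[!is.na(pick$positivity), ]
    m <- pick$positivity[pick$label == "mixed"]
    cc <- pick$positivity[pick$label == "compartmentalized"]
    if (length(m) > 0) vm[r] <- mean(m)
    if (length(cc) > 0) vc[r] <- mean(cc)
  }
  structure(list(marker = marker, cell_type = cell_type, reps = reps,
                 rng_seed = rng_seed, values_mixed = vm,
                 values_compartmentalized = vc),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$marker, " on ", x$cell_type, ", ",
      x$reps, " reps\n", sep = "")
  cat("  mixed:             mean ",
      format(mean(x$values_mixed, na.rm = TRUE), digits = 3), "\n", sep = "")
  cat("  compartmentalized: mean ",
      format(mean(x$values_compartmentalized, na.rm = TRUE), digits = 3),
      "\n", sep = "")
  invisible(x)
}
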