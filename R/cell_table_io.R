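# Cohort data model, phenotype gating, and cell-table readers/writers.

#' Assign cell phenotypes from binary lineage-marker flags
#'
#' Evaluates the hierarchical lineage gate used to phenotype segmented cells:
#' CD45- cells are split by PANCK (neoplastic tumor) then ASMA (mesenchymal);
#' CD45+ cells are split by CD20 (B cell), then CD3 with CD8/FOXP3 (T-cell
#' subsets), then CD66B (granulocyte), CD68 (macrophage), and MHCII (antigen
#' presenting cell), with the CD45+ remainder labeled "Other immune". Markers
#' not named on a branch are don't-cares, so every combination of the ten
#' lineage flags maps to exactly one outcome.
#'
#' CD45- PANCK- ASMA- cells match no gate and are labeled `"unclassifiable"`
#' (or raise an error with `on_unclassifiable = "error"`); [read_cohort()]
#' drops them with a warning by default.
#'
#' @param marker_flags A named logical vector (one cell) or a data frame /
#'   list of logical vectors (one element per marker, rows are cells). Must
#'   contain all of [lineage_markers()].
#' @param on_unclassifiable `"label"` (default) returns `"unclassifiable"`
#'   for gate-less cells; `"error"` stops.
#' @return Character vector of phenotypes (see [phenotype_levels()]).
#' @examples
#' assign_phenotype(c(CD45 = TRUE, CD20 = TRUE, CD3 = FALSE, CD8 = FALSE,
#'   FOXP3 = FALSE, CD66B = FALSE, CD68 = FALSE, MHCII = FALSE,
#'   PANCK = FALSE, ASMA = FALSE))
#' @export
assign_phenotype <- function(marker_flags,
                             on_unclassifiable = c("label", "error")) {
  on_unclassifiable <- match.arg(on_unclassifiable)
  if (is.atomic(marker_flags)) marker_flags <- as.list(marker_flags)
  f <- lapply(marker_flags, function(v) as.logical(v))
  missing <- setdiff(lineage_markers(), names(f))
  if (length(missing) > 0) {
    stop("missing lineage marker flag(s): ", paste(missing, collapse = ", "))
  }
  n <- length(f$CD45)
  if (any(vapply(f[lineage_markers()], anyNA, logical(1)))) {
    stop("lineage marker flags must be TRUE/FALSE with no missing values")
  }
  out <- rep(NA_character_, n)
  neg <- !f$CD45
  out[neg & f$PANCK] <- "Neoplastic tumor"
  out[neg & !f$PANCK & f$ASMA] <- "aSMA+ mesenchymal"
  pos <- f$CD45
  out[pos & f$CD20] <- "B cell"
  tcell <- pos & !f$CD20 & f$CD3
  out[tcell & f$CD8] <- "CD8 T cell"
  out[tcell & !f$CD8 & f$FOXP3] <- "CD4 regulatory T cell"
  out[tcell & !f$CD8 & !f$FOXP3] <- "CD4 T helper"
  myel <- pos & !f$CD20 & !f$CD3
  out[myel & f$CD66B] <- "Granulocyte"
  out[myel & !f$CD66B & f$CD68] <- "Macrophage"
  out[myel & !f$CD66B & !f$CD68 & f$MHCII] <- "Antigen presenting cell"
  out[myel & !f$CD66B & !f$CD68 & !f$MHCII] <- "Other immune"
  if (anyNA(out)) {
    if (on_unclassifiable == "error") {
      stop("unclassifiable cells: CD45- PANCK- ASMA- matches no gate (",
           sum(is.na(out)), " cell(s))")
    }
    out[is.na(out)] <- "unclassifiable"
  }
  out
}

#' Construct a cohort dataset
#'
#' Bundles a cell table, per-region metadata, and a per-patient clinical
#' table into a single validated object that all downstream analyses accept.
#'
#' @param cells Tibble with one row per segmented cell: `patient_id`,
#'   `tumor_id`, `timepoint` ("primary"/"recurrent"), `region_id`, `x`, `y`
#'   (micrometers), `phenotype`, and optionally the lineage and functional
#'   marker flag columns.
#' @param regions Tibble with one row per region: `region_id`, `tumor_id`,
#'   `patient_id`, `timepoint`, `area_mm2` (measured tissue area; 6.25 for a
#'   full 2500x2500 um region), `anatomic_site`. Extra columns (for example
#'   generator ground truth) are carried along. If `NULL`, derived from
#'   `cells` with `area_mm2 = 6.25` and site taken from `clinical`.
#' @param clinical Tibble with one row per patient: `patient_id`, `pfs_days`,
#'   `event`, plus optional `therapy`, `tnm_stage`, `anatomic_site`,
#'   `hpv_status`. May be `NULL` for purely spatial analyses.
#' @return An object of class `time_cohort`.
#' @export
time_cohort <- function(cells, regions = NULL, clinical = NULL) {
  cells <- tibble::as_tibble(cells)
  required <- c("patient_id", "tumor_id", "timepoint", "region_id", "x", "y",
                "phenotype")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    stop("cells table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(cells$x) || !is.numeric(cells$y)) {
    stop("cell coordinates x/y must be numeric")
  }
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y))) {
    stop("cell coordinates must be finite")
  }
  bad <- setdiff(unique(cells$phenotype), phenotype_levels())
  if (length(bad) > 0) {
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  }
  bad_tp <- setdiff(unique(cells$timepoint), c("primary", "recurrent"))
  if (length(bad_tp) > 0) {
    stop("timepoint must be 'primary' or 'recurrent'; found: ",
         paste(bad_tp, collapse = ", "))
  }
  if (is.null(regions)) {
    regions <- dplyr::distinct(cells, .data$region_id, .data$tumor_id,
                               .data$patient_id, .data$timepoint)
    regions$area_mm2 <- 6.25
    if (!is.null(clinical) && "anatomic_site" %in% names(clinical)) {
      regions <- dplyr::left_join(
        regions,
        dplyr::select(tibble::as_tibble(clinical), "patient_id",
                      "anatomic_site"),
        by = "patient_id")
    } else {
      regions$anatomic_site <- NA_character_
    }
  }
  regions <- tibble::as_tibble(regions)
  if (any(regions$area_mm2 <= 0)) stop("area_mm2 must be positive")
  if (anyDuplicated(regions$region_id)) {
    stop("each region_id must map to exactly one tumor/patient")
  }
  orphan <- setdiff(unique(cells$region_id), regions$region_id)
  if (length(orphan) > 0) {
    stop("cells reference unknown region(s): ",
         paste(head(orphan, 5), collapse = ", "))
  }
  if (!is.null(clinical)) {
    clinical <- tibble::as_tibble(clinical)
    if (!all(c("patient_id", "pfs_days", "event") %in% names(clinical))) {
      stop("clinical table needs patient_id, pfs_days, event")
    }
    if (any(clinical$pfs_days < 0)) stop("pfs_days must be >= 0")
    # each patient should contribute a primary and a recurrent tumor
    tp <- table(unique(regions[, c("patient_id", "timepoint")])$patient_id)
    unpaired <- names(tp)[tp < 2]
    unpaired <- intersect(unpaired, clinical$patient_id)
    if (length(unpaired) > 0) {
      warning("patient(s) without both a primary and a recurrent tumor: ",
              paste(unpaired, collapse = ", "))
    }
  }
  structure(list(cells = cells, regions = regions, clinical = clinical),
            class = "time_cohort")
}

#' @export
print.time_cohort <- function(x, ...) {
  cat("<time_cohort>\n")
  cat("  cells:   ", nrow(x$cells), "\n")
  cat("  regions: ", nrow(x$regions), " (", length(unique(x$regions$tumor_id)),
      " tumors, ", length(unique(x$regions$patient_id)), " patients)\n",
      sep = "")
  cat("  clinical:", if (is.null(x$clinical)) "absent" else
    paste(nrow(x$clinical), "patients"), "\n")
  invisible(x)
}

#' Default column dialect for cell tables
#'
#' A dialect maps the canonical column names used by this package onto the
#' columns of a particular export. `columns` is a named character vector
#' (canonical name -> file column); `phenotype_labels` optionally maps file
#' phenotype strings onto [phenotype_levels()]. Dialects can also be read
#' from a YAML/JSON file via [read_cohort()].
#'
#' @return A list with elements `columns` and `phenotype_labels`.
#' @export
cohort_dialect <- function() {
  canonical <- c("patient_id", "tumor_id", "timepoint", "region_id",
                 "x", "y", "phenotype", "area_mm2", "anatomic_site",
                 lineage_markers(), functional_markers())
  list(columns = setNames(canonical, canonical),
       phenotype_labels = NULL)
}

read_dialect_file <- function(path) {
  d <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  d$columns <- unlist(d$columns)
  if (!is.null(d$phenotype_labels)) d$phenotype_labels <- unlist(d$phenotype_labels)
  d
}

#' Read a cohort from delimited cell and clinical tables
#'
#' Reads a one-row-per-cell table (CSV/TSV), optionally remapping column
#' names through a dialect so that external exports can be loaded without
#' renaming files by hand. If the table carries no phenotype column but does
#' carry the ten lineage-marker flags, phenotypes are gated with
#' [assign_phenotype()]. Rows failing validation are reported with their
#' file line numbers.
#'
#' @param cells_path Path to the delimited cell table.
#' @param clinical_path Optional path to a per-patient clinical CSV
#'   (`patient_id`, `pfs_days`, `event`, ...).
#' @param dialect A dialect list (see [cohort_dialect()]), a path to a
#'   YAML/JSON dialect file, or `NULL` for canonical column names.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @param default_area_mm2 Tissue area assigned to regions when the table has
#'   no `area_mm2` column (6.25 = a full 2500x2500 um region).
#' @param unclassifiable Policy for CD45- PANCK- ASMA- cells when gating from
#'   flags: drop with a warning (default), error, or keep labelled.
#' @return A [time_cohort()].
#' @export
read_cohort <- function(cells_path, clinical_path = NULL, dialect = NULL,
                        sep = ",", default_area_mm2 = 6.25,
                        unclassifiable = c("drop", "error", "keep")) {
  unclassifiable <- match.arg(unclassifiable)
  if (is.character(dialect)) dialect <- read_dialect_file(dialect)
  if (is.null(dialect)) dialect <- cohort_dialect()
  cols <- dialect$columns
  raw <- tibble::as_tibble(read.csv(cells_path, sep = sep,
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE))
  # canonical -> file column renaming (only for columns present in the file)
  present <- cols[cols %in% names(raw)]
  raw <- dplyr::rename(raw, !!!setNames(as.list(unname(present)),
                                        names(present)))

  required <- c("patient_id", "tumor_id", "timepoint", "region_id", "x", "y")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("cell table ", cells_path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !is.na(raw[[cc]]) | !is.finite(v))
    if (length(bad) > 0) {
      stop("non-numeric ", cc, " coordinate at file line(s): ",
           paste(head(bad + 1L, 10), collapse = ", "))
    }
    raw[[cc]] <- v
  }
  for (m in intersect(c(lineage_markers(), functional_markers()), names(raw))) {
    raw[[m]] <- as.logical(raw[[m]])
  }
  if (!"phenotype" %in% names(raw)) {
    have <- intersect(lineage_markers(), names(raw))
    if (length(have) < length(lineage_markers())) {
      stop("cell table has neither a phenotype column nor all ten lineage ",
           "marker flags (missing: ",
           paste(setdiff(lineage_markers(), have), collapse = ", "), ")")
    }
    raw$phenotype <- assign_phenotype(raw[lineage_markers()])
    n_uncl <- sum(raw$phenotype == "unclassifiable")
    if (n_uncl > 0) {
      if (unclassifiable == "error") {
        stop(n_uncl, " unclassifiable cell(s) (CD45- PANCK- ASMA-)")
      }
      if (unclassifiable == "drop") {
        warning("dropping ", n_uncl, " unclassifiable cell(s) ",
                "(CD45- PANCK- ASMA-)")
        raw <- raw[raw$phenotype != "unclassifiable", ]
      }
    }
  } else if (!is.null(dialect$phenotype_labels)) {
    mapped <- unname(dialect$phenotype_labels[raw$phenotype])
    hit <- !is.na(mapped)
    raw$phenotype[hit] <- mapped[hit]
  }

  clinical <- NULL
  if (!is.null(clinical_path)) {
    clinical <- tibble::as_tibble(read.csv(clinical_path,
                                           stringsAsFactors = FALSE))
    if ("event" %in% names(clinical)) clinical$event <- as.logical(clinical$event)
  }

  regions <- dplyr::distinct(raw, .data$region_id, .data$tumor_id,
                             .data$patient_id, .data$timepoint)
  if ("area_mm2" %in% names(raw)) {
    areas <- dplyr::distinct(raw, .data$region_id, .data$area_mm2)
    regions <- dplyr::left_join(regions, areas, by = "region_id")
    raw$area_mm2 <- NULL
  } else {
    regions$area_mm2 <- default_area_mm2
  }
  if ("anatomic_site" %in% names(raw)) {
    sites <- dplyr::distinct(raw, .data$region_id, .data$anatomic_site)
    regions <- dplyr::left_join(regions, sites, by = "region_id")
    raw$anatomic_site <- NULL
  } else if (!is.null(clinical) && "anatomic_site" %in% names(clinical)) {
    regions <- dplyr::left_join(
      regions, dplyr::select(clinical, "patient_id", "anatomic_site"),
      by = "patient_id")
  } else {
    regions$anatomic_site <- NA_character_
  }
  time_cohort(raw, regions, clinical)
}

#' Write a cohort to canonical CSV files
#'
#' Serializes the cell table (with region metadata joined back in) and the
#' clinical table so that `read_cohort()` on the output reproduces the
#' dataset field-for-field.
#'
#' @param cohort A [time_cohort()].
#' @param cells_path Output path for the cell CSV.
#' @param clinical_path Optional output path for the clinical CSV.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, cells_path, clinical_path = NULL) {
  stopifnot(inherits(cohort, "time_cohort"))
  meta <- dplyr::select(cohort$regions, "region_id", "area_mm2",
                        "anatomic_site")
  out <- dplyr::left_join(cohort$cells, meta, by = "region_id")
  write.csv(out, cells_path, row.names = FALSE)
  if (!is.null(clinical_path) && !is.null(cohort$clinical)) {
    write.csv(cohort$clinical, clinical_path, row.names = FALSE)
  }
  invisible(cohort)
}

#' Validate a cohort dataset
#'
#' Reporting-only checks: per-region cell counts, duplicated coordinates,
#' empty regions, and cells/regions referencing patients absent from the
#' clinical table (and vice versa).
#'
#' @param cohort A [time_cohort()].
#' @return A list with `counts` (tibble region_id, n_cells) and `issues`
#'   (tibble level, scope, message); `issues` has zero rows for a fully
#'   consistent dataset.
#' @export
validate_dataset <- function(cohort) {
  stopifnot(inherits(cohort, "time_cohort"))
  counts <- dplyr::count(cohort$cells, .data$region_id, name = "n_cells")
  counts <- dplyr::left_join(
    dplyr::select(cohort$regions, "region_id"), counts, by = "region_id")
  counts$n_cells[is.na(counts$n_cells)] <- 0L

  issues <- list()
  add <- function(level, scope, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      level = level, scope = scope, message = message)
  }
  for (r in counts$region_id[counts$n_cells == 0]) {
    add("warning", r, "region contains zero cells")
  }
  dup <- dplyr::count(cohort$cells, .data$region_id, .data$x, .data$y)
  dup <- dup[dup$n > 1, ]
  for (r in unique(dup$region_id)) {
    add("warning", r, paste0(sum(dup$n[dup$region_id == r] - 1),
                             " duplicated (x, y) coordinate pair(s)"))
  }
  if (!is.null(cohort$clinical)) {
    orphans <- setdiff(unique(cohort$cells$patient_id),
                       cohort$clinical$patient_id)
    for (p in orphans) {
      add("error", p, "cells reference a patient absent from clinical table")
    }
    unseen <- setdiff(cohort$clinical$patient_id,
                      unique(cohort$regions$patient_id))
    for (p in unseen) add("warning", p, "clinical patient has no regions")
  }
  issues <- if (length(issues) > 0) dplyr::bind_rows(issues) else
    tibble::tibble(level = character(), scope = character(),
                   message = character())
  list(counts = counts, issues = issues)
}
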