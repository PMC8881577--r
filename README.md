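# timepipe

Spatial analysis of the tumor-immune microenvironment (TiME) from
single-cell imaging cell tables.

Multiplexed tissue imaging (mIHC, CODEX, cyclic immunofluorescence,
imaging mass cytometry) produces tables of segmented cells with
coordinates, a gated phenotype, and functional-marker calls. Beyond *which*
cells a tumor contains, *where* they sit relative to each other carries
prognostic information: tumors whose neoplastic and immune cells are
spatially compartmentalized behave differently from tumors where they are
mixed. `timepipe` implements a reusable version of that analysis for
cohorts of matched primary/recurrent tumors with clinical follow-up, and
ships a synthetic cohort generator so the entire pipeline can be exercised,
calibrated, and tested without access to patient data.

## What it computes

- **Phenotype gating** — a strict hierarchical gate over ten lineage
  markers (CD45, CD20, CD3, CD8, FOXP3, CD66B, CD68, MHCII, PANCK, aSMA)
  assigning each cell one of ten classes.
- **Composition and heterogeneity** — per-region densities (cells/mm²),
  per-tumor coefficients of variation, and Kullback–Leibler divergences
  (bits) of each region's cell-type distribution from five reference
  averages (same tumor, same patient, same timepoint, same anatomic site,
  whole cohort), plus log10+1 normalization, Ward/Euclidean clustering, and
  PCA embedding of composition features.
- **Mixing score** — for each region, the ratio of neoplastic–immune to
  immune–immune cell pairs within 15 µm:

  ```
  MS = #{(i, j) : i neoplastic, j immune, d(i,j) <= 15 um}
       / #{(i, j) : i, j immune, i != j, d(i,j) <= 15 um}
  ```

  Regions with immune density below 250 cells per 800² µm² are **cold**;
  otherwise a region is **mixed** when its score exceeds the cohort
  threshold (median score over primary regions) and **compartmentalized**
  otherwise. Tumor-level labels average region scores.
- **Cellular neighborhoods** — composition profiles of all cells within
  30 µm of each seed cell (αSMA+ mesenchymal by default), k-means
  clustering of the profiles with elbow-based selection of k, per-tumor
  cluster proportions, Ward grouping of tumors by their cluster usage, and
  cluster co-occurrence correlations.
- **Functional markers** — per-region positivity (PD-1, PD-L1, Ki-67) per
  cell type, one-tailed Mann–Whitney comparisons between architectures with
  Benjamini–Hochberg correction, and a one-region-per-tumor bootstrap
  (100 reps) for robustness.
- **Survival** — Kaplan–Meier curves and log-rank tests for patients
  stratified by the mixing label or the neighborhood group of their primary
  tumor; median splits; normality-gated two-sample tests; ANOVA + Tukey.

## Worked example

```r
library(timepipe)

cohort <- generate_cohort(synth_config(rng_seed = 11))
cohort
#> <time_cohort>
#>   cells:    537766
#>   regions: 46 (18 tumors, 9 patients)
#>   clinical: 9 patients

results <- run_pipeline(cohort, pipeline_config(rng_seed = 17))
results
#> <time_results>
#>   regions: 46  cells: 537766
#>   mixing threshold: 0.1017081
#>   labels: cold=5, compartmentalized=20, mixed=21
#>   neighborhood clusters k: 5
```

The derived threshold (0.102) is the median mixing score over primary
regions; each region, then each tumor, is labeled mixed /
compartmentalized / cold:

```r
head(results$tumor_mixing, 4)
#> # A tibble: 4 × 7
#>   tumor_id patient_id timepoint n_regions n_cold mixing_score label
#> 1 P01-P    P01        primary           2      0        0.123 mixed
#> 2 P01-R    P01        recurrent         3      0        0.387 mixed
#> 3 P02-P    P02        primary           3      0        0.399 mixed
#> 4 P02-R    P02        recurrent         2      0        0.282 mixed
```

Functional-marker contrasts between architectures (one-tailed, BH
corrected; the generator plants elevated PD-1 on lymphocytes in mixed
regions and elevated Ki-67 on APCs in compartmentalized regions, and the
pipeline recovers both):

```r
results$marker_tests[, c("marker", "cell_type", "n_regions", "p_adj")]
#>   marker               cell_type n_regions        p_adj
#> 1    PD1              CD8 T cell        41 1.347557e-09
#> 2    PD1            CD4 T helper        41 1.347557e-09
#> 3    PD1                  B cell        41 1.486276e-11
#> 4   KI67 Antigen presenting cell        41 4.503418e-09
```

Patients whose primary tumor is compartmentalized survive longer in this
cohort (the generator's planted hazard ratio is 4):

```r
results$survival$mixing_logrank[c("statistic", "p")]
#> $statistic
#> [1] 3.943711
#> $p
#> [1] 0.04704687
```

`write_results(results, "out/")` serializes every table as CSV plus a JSON
manifest recording the seed, parameters, and a config hash.

Real data enters through `read_cohort("cells.csv", "clinical.csv",
dialect = "dialect.yaml")`, where the YAML dialect maps the export's column
names (and phenotype labels) onto the package's data model. A thin CLI over
the same functions lives at `inst/cli/timepipe.R`
(`simulate` / `run` subcommands).

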