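---
title: "Quantifying tumor-immune spatial architecture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-immune spatial architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`timepipe` analyzes segmented single-cell imaging tables from multiplexed
tissue assays (mIHC, CODEX, cyclic immunofluorescence, imaging mass
cytometry): one row per cell with Cartesian coordinates in micrometers, a
phenotype from a ten-class lineage gate, and binary functional-marker calls.
This vignette explains the statistics the package computes, the parameters
that matter, what the synthetic generator does and does not emulate, and the
design decisions taken where reasonable implementations could differ.

## The data model

A cohort is a set of square tissue regions (typically 2500 x 2500 um)
sampled one-to-three per tumor, with matched primary and recurrent tumors
per patient and a per-patient clinical record (progression-free survival in
days, event indicator, therapy, TNM stage, anatomic site). Phenotypes come
from a strict hierarchical gate over ten lineage markers: CD45- cells are
PANCK+ neoplastic or ASMA+ mesenchymal; CD45+ cells are resolved by CD20,
CD3/CD8/FOXP3, CD66B, CD68, and MHCII, in that order, with the remainder
labeled "Other immune". Markers not named on a branch are don't-cares, so
the gate is total: every flag combination yields exactly one phenotype, and
the one combination outside the gate (CD45- PANCK- ASMA-) is explicitly
unclassifiable — `read_cohort()` drops such cells with a warning by default
because the downstream vocabulary has no class for them.

## Composition and heterogeneity

Densities are counts divided by the measured tissue area in mm^2; the area
is a per-region field (default 6.25 mm^2) because tissue can cover less
than the imaged square. The coefficient of variation (sd/mean of a
phenotype's density across a tumor's regions, averaged over tumors) uses
the sample (n-1) standard deviation by default, with a population option,
since either convention is defensible and published tables rarely say
which was used.

Regional heterogeneity is quantified by the Kullback-Leibler divergence
(base 2) between a region's cell-type fraction vector and the mean fraction
vector of five nested reference groups: the same tumor, the same patient
(both timepoints), all cohort regions of the same timepoint, all regions of
the same anatomic site, and all regions. The region is included in its own
group mean, so a singleton group gives a divergence of exactly 0, which is
flagged as degenerate rather than dropped. Because ten-class counts
routinely contain zeros, a pseudocount (default 1e-6) is added to every
category of both distributions before renormalization; with the pseudocount
disabled, a zero in the reference where the region has mass is reported as
an infinite divergence. An immune-only variant restricts the distribution
to the eight CD45+ classes, which is informative when neoplastic cells
dominate the totals.

Primary-to-recurrent compositional change is summarized per patient as the
difference of tumor-averaged densities, normalized to [-1, 1]: absolute
changes are divided by the maximum absolute change within the normalization
scope and the original sign is restored. The default scope is per phenotype
across patients (each column of the patient-by-phenotype matrix carries its
own scale, which is what a clustered heatmap of change features wants); a
global scope is available. Dividing by the maximum — rather than min-max
with a data-driven lower bound — keeps zero meaning "no change" and
guarantees that some entry reaches magnitude 1 whenever any change is
nonzero.

Feature matrices destined for clustering or embedding are normalized as
log10(x + 1). Hierarchical clustering uses Euclidean distances with Ward
linkage (`hclust` method `ward.D2`, the Ward criterion applied to
Euclidean distances). PCA is computed on centered, unscaled features; each
component's sign is fixed so its largest-magnitude loading is positive,
making score plots reproducible across platforms.

## The mixing score and architecture labels

Two cells interact when their centers are within 15 um, boundary inclusive
("within" is read inclusively; for continuous coordinates the boundary is
measure-zero anyway). The mixing score of a region is the number of
neoplastic-immune interaction pairs divided by the number of immune-immune
pairs, where the immune set is the eight CD45+ classes and ASMA+
mesenchymal cells are excluded from both sets. Pairs are unordered and
deduplicated, and a cell never pairs with itself; a config flag switches to
ordered counting for comparing raw counts with other implementations (the
score itself is invariant because both numerator and denominator double).
No edge correction is applied at region borders.

Regions are labeled cold when their CD45+ immune density falls below 250
cells per 800^2 um^2. Since assayed regions are larger than that reference
window, the rule is applied as the equivalent density, 390.625 cells/mm^2.
The cold rule takes priority: a cold region keeps that label regardless of
its score, and a region with an undefined score (no immune-immune pairs)
that is not cold is treated as a hard error rather than silently labeled.
Non-cold regions are mixed when the score strictly exceeds the threshold
and compartmentalized otherwise, so a score exactly at the threshold is
compartmentalized. The threshold itself is the median score over
primary-tumor regions (midpoint convention for even counts); a per-tumor
granularity (median of tumor-mean scores) is available because "median over
primary tumors" is ambiguous between the two. Tumor-level labels average
region scores excluding cold regions, whose scores are unstable; a tumor
whose regions are all cold is cold.

Mixing-score heterogeneity mirrors the KL panel: per region, the absolute
difference between its score and the mean score of the same five groups
(self included; a leave-one-out flag exists), with singleton groups flagged
degenerate.

## Cellular neighborhoods

For a chosen seed phenotype (ASMA+ mesenchymal by default), every cell
whose center lies within 30 um of a seed's center is that seed's neighbor;
the seed is excluded from its own neighborhood and seeds with zero
neighbors are removed. All ten phenotypes are candidate neighbors,
including neoplastic and other seed-phenotype cells — mesenchymal
neighborhoods dominated by other mesenchymal cells are themselves a
meaningful archetype. The 30 um default is a deliberate contrast to
k-nearest-neighbor neighborhoods: it requires physical proximity and, at
study-like densities (about 2000 cells/mm^2 total), yields roughly ten
neighbors per seed.

Neighborhood composition fractions are clustered with k-means (Euclidean
objective, 10 random restarts, fixed seed; Lloyd's algorithm — at these
problem sizes a mini-batch variant buys nothing and full batches keep the
result exactly reproducible). The cluster count is chosen by a
deterministic elbow rule: the k at maximum perpendicular distance from the
chord joining the endpoints of the inertia curve (candidate range 2-12 by
default), ties broken toward smaller k, with the full curve always
returned so a user can override the choice. Per-unit cluster usage is
reported as percentages (summing to 100) per region, tumor, or patient;
primary tumors are grouped by Ward/Euclidean clustering of log10(percent +
1) features; cluster co-occurrence across tumors uses Pearson correlation
(Spearman available), with zero-variance columns yielding flagged `NA`s.

## Functional markers and the bootstrap

Per-region marker positivity is the flagged fraction of the cell type,
undefined (and excluded downstream) when the type is absent. Architecture
comparisons split per-region fractions by label, exclude cold regions, and
use a one-tailed Mann-Whitney U test with the direction specified
explicitly per comparison — never inferred from the data — followed by
Benjamini-Hochberg correction across the family tested in one call. The
robustness bootstrap samples one region uniformly per tumor, splits the
sampled regions by their own region-level label (a tumor-level variant is a
documented alternative), records each group's mean positivity, and repeats
(default 100). Repetitions with an empty group record a missing value but
are retained, so both output vectors always have exactly `reps` entries.

## Survival and shared statistics

Kaplan-Meier curves use the product-limit estimator and group comparisons
use the standard two-group log-rank chi-square (1 df), both via the
`survival` package. The event indicator defaults to "observed" for every
patient, matching cohorts where all progression times are known; censoring
is supported for reuse. Median splits send values strictly below the
median to "low", strictly above to "high", and values equal to the median
to "low" by default — the assignment of the median patient is a pure
convention, so it is explicit and configurable. Two-sample comparisons are
dispatched by a Shapiro-Wilk normality gate at alpha 0.05 (on the
differences for paired designs, on each sample for independent ones) to a
t-test or the corresponding rank test. One-way ANOVA is followed by Tukey's
HSD only when the omnibus p is below 0.05. BH adjustment wraps the standard
step-up procedure.

## What the synthetic generator emulates

`generate_cohort()` exists so every stage of the pipeline can be exercised
and calibrated without patient data. It emulates, per region:

- **Tumor blobs.** Neoplastic cells uniform within one to three circular
  blobs (radius 0.26 x region size), emulating tumor nests.
- **A compartmentalization axis.** Each immune cell is, with probability
  equal to the `compartmentalization` parameter, forced outside the blobs
  by rejection resampling: 0 gives fully mixed placement, 1 fully
  compartmentalized. Architecture defaults are 0.45 (mixed) and 0.9
  (compartmentalized); expected mixing scores are monotone decreasing in
  the parameter.
- **Immune aggregation.** 75% of non-B immune cells sit in shared
  aggregates (mean 25 cells, radius 70 um) whose parents obey the
  compartmentalization rule. Real immune infiltrates aggregate; without
  this, immune-immune proximity pairs are far rarer than in tissue and
  mixing scores come out an order of magnitude too high.
- **B-cell clusters.** Matern-style clusters (mean 12 cells, radius 60 um),
  reflecting the strong spatial clustering of B cells; B-cell density also
  carries the largest per-region dispersion, making it the most variable
  phenotype within tumors.
- **Density dispersion.** Mean-preserving lognormal rate multipliers: a
  per-tumor immune infiltration factor (sdlog 0.4, creating hot and cold
  tumors), a per-region immune factor (sdlog 0.3), and independent
  per-phenotype factors (sdlog 0.3; 0.5 for B cells, 0.45 for neoplastic
  and mesenchymal). These reproduce realistic intra-tumor coefficients of
  variation (~0.3-0.6) and make a few percent of regions fall below the
  cold threshold, clustered within low-infiltration tumors.
- **Mesenchymal archetypes.** ASMA+ cells are anchored (radius 30 um)
  either to B cells — the "lymphoid-adjacent structured" archetype, placing
  them through TLS-like aggregates — or to neoplastic cells — the
  "tumor-adjacent scattered" archetype. By default the archetype follows
  the architecture (lymphoid-adjacent for compartmentalized tumors).
- **Architecture-dependent marker rates.** PD-1 on CD8/CD4-helper/B cells:
  0.30 in mixed vs 0.12 in compartmentalized regions; Ki-67 on antigen
  presenting cells: 0.10 vs 0.25; a flat 0.05 elsewhere.
- **Outcome linkage.** PFS is exponential (median 400 days for
  compartmentalized primaries) with a configurable hazard multiplier
  (default 4) for patients whose primary tumor is mixed; all events are
  observed. The exponential is the minimal single-parameter model
  sufficient for log-rank power and calibration studies.

Default densities total about 2000 cells/mm^2 and were calibrated once so
that 30 um mesenchymal neighborhoods average approximately ten neighbors,
the regime the neighborhood radius is meant to operate in.

All randomness flows from one root seed: cohort-level draws first
(architectures, sites, PFS, per-tumor factors), then one subseed per
region, so regions are independent yet the whole cohort is byte-for-byte
reproducible. The pipeline similarly derives named subseeds (k-means,
bootstrap) from its root seed.

What the generator does **not** emulate: continuous marker intensities or
images (it produces post-gating tables only), irregular tissue boundaries
and tissue loss (areas are exact squares), cell shapes and sizes (points,
so coincident centers are possible only as a measure-zero event),
spatial correlation between functional-marker calls, therapy-specific
composition shifts between timepoints, and censored follow-up. Passing
tests on synthetic cohorts therefore validates the algorithms and their
contracts, not the biology of any particular dataset.

## Numerical choices and degenerate inputs

- Pair counting and neighborhood extraction use a hash-grid spatial index
  (C++, bin size = query radius) and are exact, including the inclusive
  boundary; tests verify equality with naive all-pairs scans.
- KL divergences clamp tiny negative floating-point sums to zero.
- Empty regions yield zero densities with undefined (flagged) fractions;
  empty k-means clusters are excluded from summaries with a warning;
  zero-variance columns yield `NA` correlations with a warning.
- An all-zero change matrix normalizes to all zeros (no division by zero).
- A non-monotone inertia curve triggers a warning but the elbow rule still
  answers; a single-candidate range returns that k.
- Log-rank with no events in either group returns `NA` with a warning.

## Problem sizes in the test suite

The suite runs the full pipeline on reduced cohorts (1000-1250 um regions,
3-5 patients) and reserves the default 2500 um conditions for the
calibration-sensitive checks (neighborhood size, architecture monotonicity
with 50 regions per compartmentalization level). The log-rank null
calibration simulates 500 cohorts of 40 patients with spatial content
thinned to 5% of the default density, since only the survival arm matters
under the architecture-independent null; the empirical type-I error of the
log-rank chi-square at this size is slightly above the nominal 0.05 (about
0.055), which is a property of the asymptotic approximation with ~40
events, not of the implementation.

## Known limitations

- The elbow rule is a deterministic surrogate for a visual judgment; when
  the inertia curve is nearly straight its answer is weakly determined, and
  the curve should be inspected (it is always returned, and the cluster
  count can be fixed via `pipeline_config(k = ...)`).
- Mixing scores of sparse regions are unstable; the cold rule absorbs the
  worst cases but near-threshold immune densities still produce noisy
  scores.
- The Shapiro-Wilk gate is itself a test with error rates; at alpha 0.05,
  about 10% of truly normal independent-sample pairs are sent to the rank
  test. The gate level is exposed.
- Region-resampling bootstraps with one region per tumor are degenerate by
  construction (every repetition samples the same regions); the output
  makes this visible as a point mass rather than hiding it.
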