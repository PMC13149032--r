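# mfispat

Spatial niche and invasiveness analysis for submicrometre spatial
transcriptomic sections of the human maternal–fetal interface (MFI) — the
basal-plate tissue where fetal extravillous trophoblasts (EVTs) invade the
maternal decidua and remodel uterine spiral arteries. The package is aimed
at computational biologists working with cell-resolved spatial maps
(per-cell coordinates, cell-type labels and a gene × cell count matrix)
plus annotated anatomical landmarks.

Everything is tidyverse-native: data frames in, tibbles out, `ggplot2`
plot helpers, and broom-style `tidy()` / `glance()` methods on fitted
objects.

## What it computes

* **Signed distance fields.** For every cell, the signed Euclidean
  distance `d_I` to the interface polyline (positive = maternal decidua,
  negative = fetal villi; "decidual depth" is the positive part) and the
  signed distance `d_V` to the nearest vessel wall (positive =
  intraluminal, negative = extraluminal), plus distance-binned cell-type
  composition profiles in half-open 100 px bins.
* **Perivascular EVT enrichment.** EVT density in the annulus adjacent to
  each vessel wall versus randomized congruent decidual regions that avoid
  vessel lumina, compared by a two-sided Wilcoxon rank-sum test (exact for
  small untied samples).
* **Endothelial remodelling states.** The PDE3A × VIM quadrant rule
  (caEC → R0 → R1 → R2), bootstrap AUROC for state separability, and the
  spatial ordering of states by |d_V| with BH-corrected pairwise rank-sum
  tests.
* **Expression signatures.** A composite differential-expression score
  `S = sign(log2FC)·|log2FC·Δpct|` with rank-sum FDR; marker selection;
  bin-matched-control module scores (the "endothelium-like" score of
  vessel-adjacent EVTs) and their Spearman association with wall distance.
* **The iScore.** An L1-penalized (lasso) regression of decidual depth on
  depth-window pseudobulk expression over EVT-enriched genes:

  depth ≈ β₀ + Σ_g β_g · z_g,  with the raw per-cell score
  iScore = Σ_{g: β_g ≠ 0} β_g · (x_g − μ_g)/σ_g,

  normalized to mean 0, sd 1 within each tissue section. Positive β_g is
  pro-invasive, negative anti-invasive; validation is the Spearman
  correlation between held-out single-cell iScores and observed depth.
* **Stromal adjacency effects.** iScores of EVTs adjacent (grid-tile
  Chebyshev ≤ 5 tiles of 50 px) to a focal decidual stromal subtype
  (DSC4) versus other-DSC-adjacent EVTs and depth-matched non-adjacent
  controls, with a depth-balance check.
* **Toggle-switch GRN edges.** Signed TF→target coefficients filtered at
  |c| > 0.1 and classified by TF lineage and coefficient sign into
  EVT/SCT activation/repression; target-versus-background expression
  contrasts and Jaccard overlap for shared TFs.
* **Synthetic tissue.** A generator of full sections (landmarks, cells,
  negative-binomial expression, GRN edge lists) with planted ground truth
  — depth-linear invasion programme, wall-decaying endothelium-mimicry
  programme, marker quadrants, local DSC4 suppression — so every stage is
  testable without controlled-access data.

## Worked example

```r
library(mfispat)
library(dplyr)

gs  <- simulate_section(section_config(seed = 42))
sec <- gs$section
sec
#> <tissue_section> synthetic-seed42
#>   cells: 7240 (DSC=1200, EC=240, EVT=4000, Immune=600, SCT=600, VCT=600)
#>   landmarks: interface (61 vertices), 6 vessel(s)

ge  <- simulate_expression(sec, expression_config(seed = 43))
sec <- ge$section
d   <- compute_distances(sec)
xn  <- normalize_log1p(sec$expression)

sp  <- split_evt_train_test(d, seed = 42)
dep <- d |> filter(cell_id %in% sp$train) |>
  transmute(cell_id, depth_px = abs(d_interface_px))
w     <- build_depth_windows(xn, dep, k = 10)
model <- fit_invasion_model(w, seed = 42, train_cells = sp$train)
model
#> <invasion_model> L1-penalized depth regression (iScore)
#>   features: 3000 (0 zero-variance dropped)
#>   lambda: 13.01; selected genes: 61 (21 pro-, 40 anti-invasive)

test_dep <- d |> filter(cell_id %in% sp$test) |>
  transmute(cell_id, depth_px = abs(d_interface_px))
validate_model(model, xn, test_dep)
#> # A tibble: 1 × 3
#>     rho     p     n
#>   <dbl> <dbl> <int>
#> 1 0.904     0  1393

test_vessel_enrichment(sec, d, seed = 44)
#> <enrichment_result> perivascular density vs randomized regions
#>   vessels: n=6, median density 0.000707 px^-2
#>   null:    n=60, median density 0.000178 px^-2
#>   two-sided rank-sum p = 6.17e-05
```

The model recovered a sparse invasion programme (61 genes of 3,000
candidates) whose held-out single-cell scores track decidual depth at
Spearman ρ = 0.90, and the simulated section's perivascular EVT
aggregation (about four-fold over the background decidual density) is
flagged at p ≈ 6 × 10⁻⁵. `tidy(model)` lists the selected genes with
coefficients; `autoplot(model)` draws them.

Real sections are read with `read_section_bundle()` (a directory of
`cells.tsv`, `landmarks.geojson`, and optionally `matrix.mtx` +
`genes.tsv`), and `filter_cells()` applies the standard per-cell QC
(≥ 100 detected genes, ≤ 10,000 transcripts, ≤ 20% mitochondrial).

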