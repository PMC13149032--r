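---
title: "Spatial niche and invasiveness analysis of the maternal-fetal interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial niche and invasiveness analysis of the maternal-fetal interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mfispat analyses submicrometre spatial transcriptomic sections of the human
maternal-fetal interface (MFI): basal-plate tissue in which fetal
extravillous trophoblasts (EVTs) invade the maternal decidua and remodel
uterine spiral arteries. All coordinates are 0.5-micrometre pixels. This
vignette explains the models and procedures, the tunable parameters, what
the synthetic generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open.

```{r setup}
library(mfispat)
library(dplyr)
```

## Signed distance fields and niche composition

Two anatomical landmarks organise every analysis. The *interface polyline*
marks the boundary at the termini of anchoring villi: distance to it is
signed positive on the maternal (decidual) side and negative on the fetal
(villous) side, so "decidual depth" is simply the positive part of the
signed distance. *Vessel walls* (spiral artery cross-sections) are distance
zero; positive distances are intraluminal and negative extraluminal.

The unsigned part is the minimum point-to-segment distance over the
polyline (or polygon ring); the sign comes from the side of the nearest
segment. Two conventions matter numerically:

* When a cell is equidistant from two segments sharing a vertex, the
  segment whose perpendicular foot actually contains the nearest point
  decides the side; if both candidates are clamped endpoints the cross
  products are summed. Without this rule, near-vertical micro-segments in
  a jagged polyline can flip the sign of cells far from the boundary.
* Cells beyond the polyline's extent take their distance from the nearest
  endpoint, so the field is defined everywhere.
* Nearest-vessel ties break to the lowest vessel id, for determinism.

Composition profiles (`bin_composition()`) count cells in half-open bins
`[kW, (k+1)W)` of signed distance, with a default width of 100 px (50 um),
and normalise to per-bin proportions. Half-open bins mean no cell is ever
counted twice and the profile conserves the eligible cell total.

```{r, eval = FALSE}
gs <- simulate_section(section_config(seed = 1))
d  <- compute_distances(gs$section)
bin_composition(d, bin_width = 100) |> plot_composition()
```

## Perivascular EVT enrichment

`test_vessel_enrichment()` asks whether EVT density in the annulus adjacent
to each vessel wall (signed wall distance in `[-w, 0]`, default w = 100 px)
exceeds that of randomized decidual regions. "Size-equivalent" regions are
congruent annuli - identical lumen radius and width - placed uniformly at
random in the maternal compartment, rejected if they cross the interface,
leave the section, or intersect any vessel lumen (the lumen only: a null
region may legitimately overlap another vessel's perivascular zone). The
two density samples are compared with a two-sided Wilcoxon rank-sum test,
enumerated exactly when both groups have at most ten untied values and
approximated normally with tie correction otherwise. Annulus areas are
exact for circular vessels and use the outward Minkowski-buffer formula
(perimeter x w + pi w^2) for convex polygon vessels.

## Endothelial remodelling states

Spiral artery remodelling proceeds through four endothelial states defined
by a PDE3A x VIM quadrant rule: caEC (both high), R0 (PDE3A high, VIM low),
R1 (both low) and R2 (PDE3A low, VIM high). "High" means at or above the
threshold, so boundary cells classify deterministically. The package
defaults to per-marker medians over the endothelial cells of a section
because no absolute cutoff generalises across platforms; percentile and
user-supplied thresholds are available. The median rule presumes the
marker distribution is bimodal with roughly balanced modes - with extremely
unbalanced states a supplied threshold is the better choice.

Separability is quantified by bootstrap AUROC (`bootstrap_auroc()`, default
B = 10 replicates) with the rank-based midrank estimator, which is
invariant under monotone marker transforms. Spatial validation
(`state_distance_profile()`) summarises |wall distance| per state and runs
all pairwise rank-sum tests with Benjamini-Hochberg correction: on tissue
undergoing remodelling, caEC and R0 hug the wall, R1 is modestly displaced
and R2 is most distant.

## Composite DEG score and module scores

`composite_deg_score()` combines a fold change on normalized means,
`log2FC = log2((mu_a + 1)/(mu_b + 1))`, with the expressing-cell difference
in percentage points, `delta_pct`. The composite is
`S = sign(log2FC) * |log2FC * delta_pct|`: the magnitude multiplies the two
evidence terms while the sign follows the fold change. A raw product would
be symmetric under a group swap (both factors negate); carrying the
direction on the fold-change sign restores exact antisymmetry, and the two
definitions agree whenever the evidence terms point the same way, which is
the case for any gene worth selecting. The pseudocount of 1 bounds the
fold change at zero expression. Per-gene p-values come from two-sided
rank-sum tests with BH adjustment; `top_markers()` takes the top n genes by
S among FDR < 0.05, breaking ties by |log2FC| then gene id.

`module_score()` implements the standard bin-matched control construction:
genes are ranked by mean expression into 25 equal-frequency bins and each
signature gene draws 100 controls from its own bin (signature genes are
never controls), so the score - mean signature expression minus mean
control expression per cell, on log1p-normalized values - is centred at
zero for an exchangeable signature regardless of expression level. The
"endothelium-like" score of the pseudovascularization analysis is this
module score applied to the genes most enriched in maternal vascular
endothelium; its association with wall distance is summarised by Spearman
correlation (`score_vs_distance()`).

## The invasion model (iScore)

The iScore framework treats decidual depth as a supervised signal for
invasiveness. The pipeline:

1. **Exclusion and split.** Vessel-associated EVTs (endovascular and
   perivascular subtypes, plus any EVT within 200 px of a vessel wall) are
   excluded; remaining maternal-side EVTs are split 1:1 into training and
   test sets. The exclusion radius is a free parameter: 200 px (100 um)
   covers the perivascular niche where position reflects vessel tropism
   rather than interstitial invasion.
2. **Depth windows.** Training cells are sorted by depth (ties by cell id)
   and averaged in consecutive windows of k = 10 cells; a trailing
   remainder is dropped. Averaging after log1p-normalization reduces
   single-cell sparsity while preserving depth ordering.
3. **Penalized fit.** Window profiles are standardized with training
   statistics and regressed on window mean depth with the lasso;
   zero-variance features are dropped and recorded. The penalty is chosen
   by 5-fold cross-validation using the one-standard-error rule. With a
   few hundred windows and thousands of features the CV curve is typically
   flat near its minimum, and the raw CV-minimum choice is unstable - its
   selected support can include tens of spurious genes that change from
   fold assignment to fold assignment. The 1-SE rule picks the sparsest
   model statistically indistinguishable from the best, which stabilises
   the selected gene set; `one_se = FALSE` restores the CV minimum.
4. **Scoring.** The raw iScore of a cell is the coefficient-weighted sum of
   its z-scored selected-gene expression; the intercept is deliberately
   excluded because scores are normalized to mean 0, sd 1 within each
   tissue section, which absorbs it. By default cells are standardized
   with the training statistics (a cell at the training means scores
   exactly zero); `standardize = "independent"` z-scores within the scored
   data instead, which is what validation and external benchmarking use so
   that no training statistics touch the held-out data.
5. **Validation.** Spearman correlation between held-out single-cell
   iScores and observed depth. The model object records its training cell
   ids and `validate_model()` refuses overlapping test sets.

Positive coefficients mark genes whose expression rises with depth
(pro-invasive), negative coefficients the reverse. External matrices are
log1p-normalized and z-scored per gene within the external dataset before
scoring (`benchmark_iscore()`), and groups are compared by rank-sum test.

## Stromal adjacency and the DSC4 contrast

`assign_adjacency_groups()` groups EVTs by grid-tile adjacency to decidual
stromal cells (DSCs): cells are binned to 50 px tiles and two cells are
adjacent when their tiles are within Chebyshev distance 5, a reach of
about 125 um - inside the usual paracrine signalling range. EVTs with at
least one focal-subtype (DSC4) neighbour are `adjacent_focal` (the focal
label wins over mixed neighbourhoods, matching the plain meaning of
"adjacent to DSC4"); EVTs with only other DSC neighbours are
`adjacent_other`; EVTs with no DSC neighbour form the pool from which
depth-matched controls are drawn. Depth matching is stratified sampling on
100 px depth bins; the rank-sum p-value of the matched depths is reported
as a balance check and should be non-significant. `contrast_iscores()`
runs the two headline rank-sum contrasts (focal vs other, focal vs matched
control) with BH correction over that two-test family.

The depth-matched contrast is the load-bearing one: DSC4 concentrates in
superficial decidua where iScores are low for depth reasons alone, so an
unmatched comparison would mistake geography for regulation.

## Toggle-switch classification of regulatory edges

Signed TF-to-target coefficients (inferred upstream; network inference is
consumed as input) are filtered at |coefficient| > 0.1 - strictly, so an
edge at exactly the threshold is excluded - and classified by the lineage
of the transcription factor and the sign of the coefficient into
EVT/SCT activation/repression. Lineage TF sets come from
`select_lineage_tfs()`: TFs with FDR < 0.01 and positive composite score
in that lineage's DEG table. TFs significant in both lineages are flagged
shared and their target-set overlap is quantified by the Jaccard index.
`target_contrast()` compares per-gene mean expression of each category's
targets against a genome background of genes expressed in at least 1% of
the lineage's cells, excluding the targets themselves (the contrast is
targets versus non-targets; a flag restores the inclusive background).

## The synthetic tissue generator

Controlled-access data cannot ship with the package, so every stage is
exercised on synthetic sections with planted ground truth. The generator
is a pure function of (config, seed) and emulates:

* a sinusoid-perturbed interface polyline separating villous tissue
  (above) from decidua (below), digitized at 60 segments; all placement
  decisions interpolate the emitted polyline so compartment labels agree
  exactly with the signed distance field;
* circular vessels wholly inside the decidua with configurable clearance;
* EVT density decaying exponentially with depth (default scale 1,500 px,
  i.e. 750 um, giving both a superficial majority and a deep tail) plus a
  perivascular aggregation fraction (default 20% of interstitial EVTs
  within 300 px of a wall); endovascular and perivascular subtypes at the
  wall; DSC4 concentrated superficially (exponential scale 250 px) while
  other DSC subtypes are uniform; endothelial cells on vessel walls with
  state-dependent outward offsets (caEC/R0 5 px, R1 30 px, R2 120 px);
* negative-binomial counts (shared dispersion theta = 1.1, typical of
  shallow spatial protocols) over 3,000 genes with planted programmes: a
  40-gene invasion programme whose log-means change linearly with depth
  (slope magnitudes 0.7-1.0 per 1,000 px, half positive and half
  negative), a 40-gene endothelium-mimicry programme elevated by 0.8
  log-units at the vessel wall (100 px plateau, 100 px decay), PDE3A/VIM
  quadrant means for endothelial states, and - when enabled - a local
  suppression that moves the invasion programme of EVTs within 250 px of a
  DSC4 cell toward the non-invasive phenotype.

Three generator choices deserve their rationale:

* **Mixed-sign invasion slopes.** Half the planted genes fall with depth.
  This mirrors the pro-/anti-invasive coefficient structure of the fitted
  model, and it keeps per-cell library totals independent of depth: with
  one-signed slopes, library-size normalization leaks a depth trend into
  every background gene, which quietly corrupts feature selection.
* **Noise comparable to signal.** Lasso support recovery is only possible
  when the planted genes are not mutually redundant. Genes that share a
  depth signal with little independent noise are nearly collinear at the
  pseudobulk-window level, and no penalty value then selects more than a
  fraction of them - the path simply never contains the full programme.
  The default dispersion and baseline (about eight counts per cell for
  programme genes, where log1p is approximately linear in log-mean) give
  each gene enough independent information that the full programme is
  recoverable while held-out correlation remains high.
* **Suppression acts along the invasion axis.** The planted DSC4 effect
  shifts pro-invasive genes down and anti-invasive genes up by the same
  log-magnitude. A uniform downward shift of all programme genes would be
  orthogonal to the invasion axis under mixed-sign coefficients and
  therefore invisible to the iScore - and a suppressed phenotype that the
  score cannot see is not a suppression of invasiveness.

The generator does **not** emulate segmentation error, doublets, ambient
RNA, batch effects between sections, spatially varying capture efficiency,
cell-shape anisotropy, or any immune biology. Passing tests therefore
certify the statistical machinery against known truth, not robustness to
those artefacts of real data.

By default the suppression effect is disabled (`suppression_radius_px = 0`)
and is planted explicitly in the dedicated adjacency study: the suppression
term is a shared factor across the whole invasion programme, and leaving it
on in every simulation would confound studies - such as programme-recovery
experiments - that are not about it.

## Problem sizes and runtime choices

The test suite and the reproduction script use deliberately scaled study
sizes: default sections of 6,000 x 4,000 px with 4,000 EVTs and 3,000
genes for model recovery (ten independent seeds); 200 simulated null
sections for the calibration of the enrichment test and 50 replicates of a
62-vessel section for its power; a 48,000 px-wide sparse-stroma section
for the DSC4 contrast so that at least 300 EVTs populate each adjacency
group while depth-matched controls remain available; and 100 direct
simulations for the depth-confound null. These sizes put every Monte-Carlo
estimate comfortably inside its acceptance tolerance while keeping a full
run in minutes on one CPU.

## Known limitations

* Euclidean distances only; no geodesic or within-tissue path distances.
* Null-region sampling and annulus areas require circular (or convex
  polygonal) vessels; highly concave vessel outlines would need a
  polygon-buffering library.
* The quadrant median threshold assumes roughly balanced endothelial
  states in the analysed vessel set.
* The iScore is a linear readout; invasion programmes with strongly
  nonlinear depth dependence would be better served by the window stage
  feeding a nonlinear learner, which the window/score separation makes
  straightforward to swap in.
* Depth matching drops strata with an empty pool (with a warning); a
  focal group concentrated where every EVT has a stromal neighbour cannot
  be matched and the balance check will say so.
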