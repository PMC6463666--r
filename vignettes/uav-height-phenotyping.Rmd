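---
title: "From elevation rasters to QTL: plot-height phenotyping and its quantitative-genetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From elevation rasters to QTL: plot-height phenotyping and its quantitative-genetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Photogrammetry from a low-altitude UAV flight yields a digital surface
model (DSM): a raster of top-of-everything elevations at a few centimetres
per pixel. Plant height for a breeding plot is the difference between the
canopy surface and the ground beneath it, so two further surfaces are
needed: a digital terrain model (DTM) of the bare ground, and a rule for
turning the per-pixel plant height model (PHM = DSM − DTM) into one height
per plot. Both steps carry error, and the end use here is demanding:
plot heights feed heritability estimation, QTL interval mapping in a
doubled-haploid (DH) wheat population, and genomic prediction. The package
implements the full chain and, because the operational question is whether
height maps survive that chain, ships a synthetic-field generator with
exact ground truth at every stage.

## Terrain: control points and TIN interpolation

Wheat canopies at late stages are dense, so the ground is observed only in
alleys and bare patches. `sample_ground_elevations()` turns each
bare-ground polygon into three control points: the polygon centroid paired
with the **median** of its pixel elevations, and the pixel locations of the
**lowest** and **highest** elevations. The median guards against stray
vegetation pixels; the min/max pair spans the local relief inside each
zone. `interpolate_dtm()` then evaluates linear interpolation over the
Delaunay triangulation of the control points (a TIN) at every pixel of the
DSM grid. A TIN adds no curvature between data points, is exact on any
tilted plane, and needs no tuning — the reasons it was chosen over kriging
or spline surfaces, which are noted as an extension point. Outside the
convex hull of control points the nearest control point's elevation is
used, and a companion quality raster flags every extrapolated pixel.

Numerical details worth knowing: the triangulation (Bowyer–Watson
insertion, written in-package because no triangulation library is
available here) jitters the normalised coordinates by ~1e-8 of the field
diameter to break exact cocircularity of grid-aligned points; this
perturbs interpolated values far below sensor noise. Sensor noise on the
min/max control points is the dominant DTM error source: the extreme of a
few hundred pixels with 2 cm noise sits ~5 cm from the truth, but the min
and max of one polygon are nearly coincident with opposite biases, so
their local effect largely cancels and the default field recovers terrain
with ~3.5–4 cm RMSE.

## Height extraction: the upper canopy boundary

A naive plot mean of the PHM underestimates badly, because most pixels see
lower leaves and gaps rather than spike tips. The extraction rule instead
samples the upper canopy boundary:

1. the plot polygon is trimmed inward by 10% of its short side
   (`trim_plot()`), discarding the margin where neighbours overhang;
2. `n = 10` square windows of 7.5 cm (3×3 pixels at the default 2.5 cm
   GSD — about one spike) are placed uniformly at random inside the
   trimmed polygon, non-overlap enforced by rejection sampling;
3. each window contributes its maximum PHM value `t_i`;
4. readings more than 10 cm below the plot-wide top cannot be spike height
   and are rejected; the plot height is `H = (U + L) / 2` with `U`/`L` the
   highest/lowest accepted readings.

The window count mirrors the ten plants measured by hand per plot in the
protocol this emulates. Reading `U` and `L` across windows (rather than
inside a single window) is the central interpretive decision of the
implementation; the 10 cm tolerance and every count above are
`extraction_params()` fields. If every reading but one is rejected the
plot is flagged low-confidence rather than dropped, and a run aborts only
when ≥ 20% of plots fail outright. Negative PHM values are kept (clipping
would hide DTM bias from the diagnostics).

## What the synthetic field emulates — and what it does not

`sim_config()` defaults are the emulated trial: 198 DH lines plus the two
parents, 3 replicate blocks at each of 2 sites (600 plots of 1.3 m × 3 m
per site), 2.5 cm GSD, 2 cm sensor noise, 0.5 m of smooth terrain relief
(a tilted plane plus two low-frequency sinusoids; the choice of a smooth
analytic terrain is ours — gentle farmland, no model was prescribed).
The genetic architecture is two major QTL on chromosomes 4B and 4D
(19 cm allele substitution each, jointly ~60% of phenotypic variance —
the Rht-B1/Rht-D1 situation), a 6 cm minor locus on 6D, and a
marker-linked polygenic background of 100 cm² spread over a 21-chromosome
map (150 cM each, 2 cM marker spacing). Gametes recombine under Haldane's
map function with no interference — chosen over Kosambi because the
simulator needs no interference model and the scan uses the same
probabilities. Variances (σ²g = 100, σ²ge = 25, σ²ε = 36, site 25, all
cm²) put the line-mean SD near 18–20 cm and entry-mean heritability above
0.9, the regime of well-run wheat height trials.

Canopy texture is the one free knob with no field calibration: a fraction
`spike_fraction = 0.35` of plot pixels sit at canopy-top level minus a
half-normal deviate (`spike_sd = 0.03` m), the rest sample the lower
canopy at 45–90% of plant height. The one-sided spike deviate models
mixed pixels — a 2.5 cm pixel averages a spike tip with its surroundings,
so the photogrammetric surface can only sit below the true tip — and it is
what makes the extraction rule *under*-estimate systematically, the
documented behaviour of the real platform. A symmetric deviate would
instead make window maxima overshoot. The generator does **not** emulate
photogrammetric reconstruction (no camera poses, no spatially correlated
reconstruction error), lodging, row structure inside plots, or
classification error in the bare-ground polygons; passing tests therefore
say the chain is self-consistent at realistic noise levels, not that any
particular field will reach R² = 0.98.

## Validation and variance components

`regress_validate()` reports OLS of ground on UAV height, RMSE and mean
bias over plots matched by genotype × site × rep. `bias_by_elevation()`
splits plots at the median height, quantifying that tall canopies are
harder to measure. `anova_variance_components()` works on the exactly
balanced genotype × environment table and equates observed to expected
mean squares — σ²ε = MSE, σ²ge = (MS(GE) − MSE)/r, σ²g = (MS(G) −
MS(GE))/(re) — truncating negative solutions to zero with a flag. EMS was
chosen over REML because the design is balanced by construction (REML is
the natural extension for unbalanced field data). F ratios test genotype
and environment against the interaction and the interaction against the
residual. Heritability follows the published formula for this design,
`h² = σ²g / (σ²g + σ²ge/r + σ²ε/(re))`; dividing the interaction term by
the number of replicates rather than environments is unusual (the
textbook entry-mean form uses σ²ge/e), so the alternative is available
behind `convention = "standard"` and the default is the formula as
printed. With e = 2, r = 3 the two differ by little at high h².

## QTL scan and genomic prediction

The scan is inclusive composite interval mapping in regression
(Haley–Knott) form: `select_cofactors()` runs forward–backward stepwise
marker regression (entry/exit p = 0.001/0.002, cofactors capped at n/5),
then `icim_scan()` walks a 1 cM grid; at each position the phenotype is
adjusted for all cofactors except those within 10 cM (which would absorb
the locus being tested), the expected QTL genotype is computed from the
flanking DH marker genotypes under Haldane probabilities, and
`LOD = (n/2)·log10(RSS0/RSS1)` comes from the regression of the adjusted
means on that expectation. The full mixture-model EM of the published
ICIM software is deliberately simplified to its regression skeleton —
adequate for the two-genotype mixtures of a DH population. Peaks are
local maxima above LOD 2.5 with 1-LOD support intervals; maxima whose
intervals overlap or that sit within 20 cM are merged into the stronger
one (leftmost on ties), which suppresses the shoulder artifacts that the
cofactor-exclusion window boundary can create beside a strong QTL.
Reported per-peak PVE comes from the joint regression on the peak-nearest
markers (drop-one RSS increase over the total sum of squares), so the
PVEs of linked peaks do not double-count.

`fit_gblup()` is ridge-regression BLUP: markers recoded {0,1} → {−1,+1}
and column-centred, shrinkage λ = σ²ε/σ²g estimated by restricted maximum
likelihood through the eigendecomposition of XXᵀ (grid on log λ from −8
to 10 in 0.25 steps, then local refinement; a failed bracket falls back
to λ = p with a warning). The solution uses the dual (Woodbury) form
Xᵀ(XXᵀ + λI)⁻¹(y − μ̂), so the independent primal normal-equations solve
makes a genuine cross-check in the tests. Cross-validation accuracy is
the mean of per-fold correlations between observed and predicted line
means: a correlation pooled across folds is biased towards −√(k/n) under
a null phenotype (each test fold is anti-correlated with its own training
mean), so the fold-wise convention is used, with pooling retained only
for folds under 3 lines such as leave-one-out. The marker-exclusion
experiment reruns the cross-validation on identical fold partitions with
QTL-linked markers removed (support intervals ± 10 cM, or whole
chromosomes), so the reported drop is a paired difference free of
partition noise.

## Numerical choices and degenerate inputs

* Rasters are plain matrices with an affine georeference; files use the
  Esri ASCII grid format (text, GDAL/QGIS-readable) and polygons GeoJSON.
  PHM = DSM − DTM is computed only on identical grids — a mismatch is an
  error, never a silent resample — and elevations around 100 m share a
  binade, so the subtraction is exact in double precision and
  PHM + DTM reproduces the DSM bit for bit.
* Extraction: pixel membership is by pixel-centre containment; window
  placement is seeded per plot (`seed + 7·plot_index`), so runs are
  reproducible and plots independent.
* Interval scan: at marker positions the expected genotype collapses to
  the observed one, so the scan equals single-marker regression there;
  monomorphic expected genotypes give LOD 0 rather than NaN.
* Degenerate inputs are refused loudly: empty maps, QTL on absent
  chromosomes, < 3 or collinear control points, single-environment
  variance decomposition, zero-variance regressors, exclusions leaving
  < 10 markers.

## Problem sizes in the shipped tests

The unit suite runs reduced fields (12–30 lines, 3 chromosomes) chosen to
exercise every code path in seconds. The acceptance suite uses the full
emulated design where the property demands it: the 198 × 2 × 3 trial and
full rasters for terrain recovery (20 seeds) and height recovery, 500
phenotype seeds for variance-component calibration, 100 scan seeds per
effect size for QTL power, 50 paired repeats for the exclusion contrast,
and one complete pipeline run for the end-to-end concordance of UAV-based
and true-height genomic analyses.

## Known limitations

* The DSM is rendered per-pixel i.i.d.; real photogrammetric error is
  spatially correlated, which would inflate window maxima less
  independently than modelled.
* ICIM here is the regression form; LOD values near the detection
  threshold can differ slightly from mixture-likelihood implementations.
* The EMS path requires exact balance; unbalanced tables are rejected
  rather than approximated.
* `poly_shrink()` assumes convex plot polygons (true of rectangular
  plots; arbitrary concave plots would need a polygon-offset library).
* Booting-stage dynamics are available only as a growth factor on the
  genetic signal; no within-season growth curve is modelled.
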