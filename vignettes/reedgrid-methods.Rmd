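---
title: "Methods behind reedgrid: cellular reed-spread analysis and boosted-tree habitat modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind reedgrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reedgrid)
```

`reedgrid` analyses the occurrence and spread of the common reed
(*Phragmites australis*) on a raster cell model: static habitat predictors
(water depth, shore openness, distance to river outlets, coastal land
cover) explain *where* reed can establish, while the occupancy state of a
cell's neighborhood explains much of *when* it is colonized or abandoned,
because the dominant local dispersal mode is clonal rhizome growth. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## The raster data model

All layers are regular grids in projected meters with a top-left origin,
rows running south and columns east (`rgrid`). Missing cells are `NA`
internally and a declared nodata sentinel on disk (ESRI ASCII format, a
plain-text interchange format readable by every GIS). All layers of a site
must share origin, extent and cell size; operations verify alignment to
1e-6 m and refuse misaligned inputs rather than resampling silently.

Presence polygons are rasterized by the **cell-center rule**: a cell is
occupied iff its center lies inside (or on the boundary of) a polygon.
This rule is deterministic and, at a 2 m conversion cell size, the
partial-coverage ambiguity it ignores is negligible relative to patch
sizes. Rasterization conserves area to within one perimeter ring
(`|cells·cs² − area| ≤ perimeter·cs`), which the test suite checks on
random polygons.

Two patch shape metrics guide the choice of analysis cell size:

- the **depth index**, the mean distance from a polygon's interior points
  to the nearest perimeter point (`R/3` for a circle of radius `R`, `s/6`
  for a square of side `s`);
- the **maximum inscribed diameter**, twice the largest interior distance
  to the boundary (`2R`, resp. `s`).

No closed form exists for irregular patches, so both are computed on an
auxiliary raster at `min(0.5 m, width/20)` using exact point-to-segment
distances to the boundary; the inscribed-circle maximum is then refined on
a 10× finer local grid around the coarse argmax, keeping both metrics
within 2 % of the analytic values on test shapes. Degenerate (zero-area)
polygons yield zero metrics with a warning. The lower and upper quartiles
of inscribed diameters over the patches that appeared or vanished between
two snapshots bracket the sensible analysis cell sizes
(`choose_cell_size`).

## Predictor grids

**Distance to river outlets** is the plain Euclidean minimum over outlet
points, evaluated at cell centers; it acts as a proxy for nutrient-rich
sediment near river mouths.

**Shore openness** abstracts wave exposure as mean wave fetch: from each
water cell, rays are marched in `n_directions` (default 16) equally spaced
directions until they sample a land cell or reach `max_fetch` (default
10 000 m); openness is the mean fetch in meters, and `relative_openness()`
rescales by the cap. The literature describes fetch-based openness without
fixing the number of directions or a cap, so these are package defaults,
not a bit-match of any particular exposure product. Two numerical choices
matter: sample points sit half a step (step = cell/2) off cell boundaries,
which makes the openness map exactly invariant under 90° rotations of the
mask when `n_directions` is a multiple of 4; and the region beyond the
grid is treated as open water — a straight ray leaving the convex grid can
never re-enter it, so such rays are open to the cap. Land cells are
nodata.

**Land cover** (CORINE level-2 style integer codes) is extended offshore:
the analysis mask is the shoreline (land cells with a water 8-neighbor)
plus all water cells shallower than 3 m — the depth band that bounds reed
habitat — and each masked water cell receives the class of the nearest
land cell. Equidistant ties go to the smallest class code, a deterministic
convention. Depth is positive downward; land cells carry depth ≤ 0.

## The synthetic landscape and spread generator

Because delineated reed maps of the original survey areas are not publicly
deposited, the package validates every stage on synthetic sites with
recoverable ground truth (`make_site`, `simulate_spread`):

- coastline: a north–south elevation ramp plus Gaussian-smoothed noise
  (≈50 m correlation length), thresholded at zero; degenerate all-land or
  all-sea draws are resampled with an incremented seed (at most 10 times);
- bathymetry: 0.02 m of depth per meter of distance from shore plus smooth
  noise, clipped to ≥ 0.01 m on water (the 3 m analysis contour then sits
  ~150 m offshore, giving a realistic shallow band);
- openness from the fetch engine; outlets drawn on the shoreline; land
  cover as Voronoi regions of random seed cells with codes from the
  CORINE level-2 set {11, 12, 14, 21, 24, 31, 32}.

Occupancy year 0 seeds each masked cell independently with probability
`logit⁻¹(β₀ + f_depth(d) + f_open(o) + f_dist(r))`, where the `f` are
piecewise-linear log-odds responses with flat extrapolation. Each
subsequent year updates synchronously (classic cellular-automaton
semantics — the downstream transition analysis compares two snapshots and
is order-free):

- a clear cell colonizes with `logit⁻¹(logit(c₀) + g·k)`,
- an occupied cell disappears with `logit⁻¹(logit(e₀) − h·k)`,

with `k` the occupied count among the 8 Moore neighbors (center excluded,
matching the analysis' neighbor-count definition exactly — this is what
makes the programmed curves recoverable without an off-by-center bias).
Defaults `c₀ = 0.02, g = 0.55, e₀ = 0.25, h = 0.65` encode the observed
qualitative pattern: bare shore is rarely colonized without neighbors,
embedded cells almost never vanish, isolated stands often do. The
generator's neighborhood is fixed at 3×3 so that the analysis sweep over
windows up to 9×9 probes scale mismatch deliberately. The default
suitability responses make shallow (< 1 m), sheltered water near (but not
directly at) river outlets strongly suitable; the `"depth_dominant"`
preset steepens the depth response so that recoverability studies have an
unambiguous top-ranked variable.

What the generator does **not** emulate: seed-dispersal kernels and
long-distance colonization, wave mechanics, temporally varying land
cover, and the spatially autocorrelated *errors* of photo-interpreted
maps. Passing recovery tests therefore demonstrates that the estimators
are correct for the process they assume, not that real reed dynamics
follow that process.

## Growth accounting

Between two snapshots with areas `N₀` and `N` (hectares) separated by `t`
years, the intrinsic rate of natural increase solves `N = N₀·e^(rt)`:
`r = 100·ln(N/N₀)/t` % per year. Rates are reported to one decimal (full
precision is kept internally and available via `digits = Inf`); coverage
percentages are reported as integers, matching the conventional tabular
presentation. The identity `r(t₀,t₂) = (t₁·r(t₀,t₁) + t₂·r(t₁,t₂))/(t₁+t₂)`
(time-weighted chaining) and antisymmetry are property-tested. Areas can
be taken from rasters (`areal_cover`: occupied cells × cell area over the
analysis mask) or passed directly from printed tables.

## Neighborhood transition analysis

Fine presence grids are coarsened by the **majority-area rule**: a coarse
cell is occupied iff ≥ 50 % of its valid fine-cell area is occupied
(area-weighted for partial overlaps), which preserves areal cover in
expectation. Overlaying two snapshots yields the state-transition grid
(0→0, 0→1, 1→0, 1→1); the occupied-neighbor count uses a `w×w` window with
the center excluded, and cells whose window exits the grid or touches
nodata are excluded rather than zero-padded — zero padding would bias `k`
downward exactly where reed concentrates, along the coast. Cross-tabulation
gives, per `k`, `p_colonize(k) = n(0→1,k)/(n(0→0,k)+n(0→1,k))` and the
disappearance analog; `k` values with an empty denominator are reported as
missing, never imputed as zero, because sparse extreme neighbor counts are
exactly where such curves turn noisy. `run_multiscale` sweeps cell sizes ×
windows (default 4×4 = 16 tables).

## Conditioned Latin hypercube sampling

Model samples are drawn from the per-cell frame (one row per masked cell:
coordinates, occurrence, predictors) by conditioned LHS. "Maximally
stratified" is formalized as an explicit objective: for each continuous
variable (the three static predictors plus x and y), the frame is cut into
`n` equal-probability bins from its quantiles and the objective sums
`|count − 1|` over bins; for categorical variables (occurrence, land
cover) it sums the absolute deviation of sampled class counts from the
frame's proportions. A random subset is then improved by simulated
annealing with swap proposals and geometric cooling (factor 0.95, 10 000
iterations by default), with incremental objective updates so a proposal
costs O(variables). The sampler is deterministic under a fixed seed, warns
and drops constant variables, and never duplicates cells. On a uniform
one-dimensional frame the optimum — exactly one sample per bin — is
reached and tested.

## Boosted regression trees

The occurrence model is stagewise gradient boosting with Bernoulli
deviance, written from scratch (compiled tree core):

- intercept `F₀ = logit(prevalence)`;
- each stage draws a bag-fraction `bf` subsample without replacement,
  fits a regression tree with `tc` splits (grown best-first by largest
  squared-error improvement on the gradient residuals `y − p`), sets
  terminal values by a one-step Newton update `Σ(y−p)/Σp(1−p)`, and adds
  the tree shrunk by the learning rate `lr`;
- `tc` is interpreted as the number of splits (interaction depth), with a
  minimum of 10 observations per terminal node; split-gain ties break by
  lowest variable index, then lowest split point — fitting is
  bit-reproducible under a fixed seed;
- the categorical land-cover predictor is split by exhaustive subset
  search for ≤ 8 classes (one-vs-rest greedy ordering beyond that);
  classes unseen at prediction time inherit the parent-node value;
- defaults `bf = 0.75`, `lr = 0.005`, `tc = 10` — the combination that
  consistently performs well for this problem class — with candidate grids
  `lr ∈ {0.05, 0.01, 0.005, 0.001}`, `tc ∈ {3, 5, 7, 10, 20}`,
  `bf ∈ {0.25, 0.5, 0.75, 0.9}` available through `brt_params`.

The ensemble size is selected by occurrence-stratified ten-fold
cross-validation: trees are added in steps of 50 (up to 10 000) and the
size minimizing mean held-out deviance is kept; AUC and the Pearson
correlation between the held-out 0/1 response and the predicted
probability are reported at that size, both per fold (mean ± se) and
pooled — the pooled statistics remain defined in degenerate fold layouts
such as leave-one-out. Relative influence attributes each split's gain to
its variable, summed over the used trees and normalized to 100. On a small
stump fixture the ensemble's predictions correlate > 0.99 with an
independent reference gradient-boosting implementation; that library is a
cross-check in the tests only, never the implementation.

## Evaluation

AUC is computed by midranks (the normalized Mann–Whitney statistic), exact
under ties in O(n log n) and verified against O(n²) pair counting.
Suitability maps are dichotomized at the **minimized-difference
threshold**, the cutoff minimizing |sensitivity − specificity| over the
observed scores plus adjacent midpoints (the optimum always lies at an
observed cutpoint; midpoints stabilize the reported value), ties resolved
toward the lower threshold. In the transfer harness, the threshold is
computed on the *prediction* site's scores — the alternative (transferring
the training threshold) conflates calibration shift with discrimination
loss, and the harness is meant to compare discrimination. Interpolation is
evaluated on the training site's cells outside the training sample;
extrapolation on all masked cells of the other site; unseen land-cover
classes at prediction trigger a warning, not an error, and fall back to
parent-node values.

## Problem sizes and reproducibility

The validation suite uses deliberately modest sizes chosen for tight
feedback loops: synthetic sites of 100–160 cells per side (500–800 m at
5 m, or 200×200 cells at 3 m for the transition-recovery runs), LHS
samples of 1 500–2 000 rows, ensembles capped at 300–1 500 trees with
`lr = 0.01–0.05`, and 5–20 seeds per Monte-Carlo property. The
neighborhood recovery check pools three annual transitions over five
seeds and requires the empirical `P(0→1|k)` to sit within 3 Monte-Carlo
standard errors of the programmed logistic curve wherever the denominator
holds ≥ 200 cells; the boosted-tree recovery requires held-out AUC above
0.85 with depth top-ranked in at least 9 of 10 seeds, chance-level AUC on
signal-free responses, and higher interpolation than extrapolation AUC on
parameter-shifted site pairs in at least 8 of 10 seeds. One global seed
derives all stage seeds in `run_pipeline`, and re-running a configuration
reproduces the manifest hashes bit-for-bit.

## Known limitations

- The openness engine is a defined stand-in for fetch-based exposure
  products, not a reimplementation of any of them; absolute values depend
  on `max_fetch` and the ray count.
- No CRS handling: all inputs must already share one projected CRS in
  meters. No GeoTIFF I/O — grids interchange as ESRI ASCII text.
- The spread simulator is intentionally minimal (no seed dispersal,
  no wave damage, static land cover); it grounds method validation, not
  ecological forecasting.
- Suitability maps are relative habitat rankings, not absolute occurrence
  probabilities; extrapolation across strongly shifted environments
  degrades, which the transfer harness quantifies rather than hides.
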