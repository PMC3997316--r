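# reedgrid

Cellular analysis and boosted-tree habitat suitability modelling of coastal
reed (*Phragmites australis*) occurrence and spread.

The common reed is a clonal helophyte that has expanded strongly along
sheltered, shallow brackish coasts such as the northern Baltic. Its dynamics
mix two signals: **habitat suitability** — reed favors shallow water
(roughly < 1–2 m), sheltered shores, and the nutrient-rich vicinity of river
outlets — and a strong **close-range neighborhood effect**, because clonal
rhizome growth colonizes cells adjacent to existing stands and isolated
stands disappear more readily than embedded ones. `reedgrid` implements, on
a raster cell model, the full analysis chain a spatial ecologist needs to
quantify both signals and to build predictive occurrence maps:

- a light **grid engine**: polygon rasterization by the cell-center rule,
  patch shape metrics (depth index, maximum inscribed circle) that guide
  the choice of analysis cell size, ESRI ASCII grid and GeoJSON I/O;
- **predictor grids**: Euclidean distance to river outlets, wave-fetch
  shore openness (mean free-water ray length over `n` directions), and the
  offshore extension of coastal land-cover classes over the analysis mask
  (shoreline plus water shallower than 3 m);
- a **synthetic coastal landscape generator** with a programmed logistic
  suitability surface and neighbor-count-dependent colonization/extinction
  rules, so every downstream method can be validated against known truth;
- **growth accounting**: the intrinsic rate of natural increase `r` solving
  `N = N0 · e^(r t)`, reported in % per year between occupancy snapshots;
- **multi-scale neighborhood transition analysis**: state-transition grids
  (0→0, 0→1, 1→0, 1→1) cross-tabulated against occupied-neighbor counts
  for cell sizes and windows 3/5/7/9, yielding the conditional colonization
  probability `P(0→1 | k occupied neighbors)` and its disappearance analog;
- **conditioned Latin hypercube sampling** of the per-cell frame, maximally
  stratified over occurrence, each predictor and geographic space by
  simulated annealing;
- from-scratch **stochastic gradient boosted regression trees** with
  Bernoulli deviance (learning rate `lr`, tree complexity `tc` splits per
  tree, bag fraction `bf`), ten-fold cross-validated tree-count selection,
  relative variable influence, and JSON model serialization;
- **map evaluation**: rank-based AUC, the minimized-difference threshold
  (|sensitivity − specificity| minimal), confusion statistics, and an
  interpolation/extrapolation transfer harness producing suitability maps.

## Worked example

Growth accounting runs directly on published areal tables:

```r
library(reedgrid)
areas <- data.frame(site = "Kramppi", year = c(1962, 1977, 1995),
                    area_ha = c(2.58, 19.36, 17.86))
growth_table(areas)
#>      site year0 year1 N0_ha  N_ha r_pct_per_year
#> 1 Kramppi  1962  1995  2.58 17.86            5.9
#> 2 Kramppi  1962  1977  2.58 19.36           13.4
#> 3 Kramppi  1977  1995 19.36 17.86           -0.4
```

The reed cover grew at 13.4 %/yr in 1962–1977, shrank slightly afterwards,
and averaged 5.9 %/yr over the whole period.

A synthetic site exercises the whole modelling chain with known truth:

```r
site <- make_site(extent = c(600, 600), cell_size = 5, n_outlets = 2,
                  n_classes = 4, seed = 3)
site
#> <site_bundle> 120 x 120 cells @ 5 m, seed 3
#>   land fraction 0.36, mask cells 9819, outlets 2

series <- simulate_spread(site, spread_params(n_years = 3, seed = 7,
                                              preset = "depth_dominant"))
frame <- build_frame(site, series[[1]])
samp  <- draw_lhs(frame, 1500, seed = 2, iterations = 3000)
model <- fit_brt_cv(samp, brt_params(lr = 0.01, tc = 5, bf = 0.75,
                                     folds = 10, step = 50,
                                     max_trees = 1000, seed = 1))
model
#> <brt_model> 500 trees (lr=0.01, tc=5, bf=0.75), intercept -0.640
#>   relative influence: depth 84.7, openness 11.5, outlet_distance 2.8, landcover 0.9
#>   CV (10 folds): AUC 0.959 (se 0.002), cor 0.814 (se 0.006)
```

The cross-validated ensemble recovers the programmed structure: water depth
dominates the variable influence (the generator's steepest response) and
held-out AUC is 0.96. `predict(model, site)` returns the suitability map as
a grid, `write_esri_ascii()` saves it.

The neighborhood effect is quantified by conditional transition
proportions:

```r
tabs <- run_multiscale(series[[1]], series[[4]], cell_sizes = 5, windows = 3)
head(tabs[[1]][, c("k", "n00", "n01", "p_colonize", "p_disappear")], 5)
#>   k  n00 n01 p_colonize p_disappear
#> 1 0 4155 210 0.04810997  0.45614035
#> 2 1  494  51 0.09357798  0.36231884
#> 3 2  237  41 0.14748201  0.16304348
#> 4 3  161  60 0.27149321  0.06993007
#> 5 4   91  92 0.50273224  0.05676856
```

Colonization probability rises and disappearance probability falls with the
number of occupied neighbors — the close-range effect the simulator
programs and the analysis recovers. `plot_transition_curves(tabs)` draws
the panel figure (solid = colonization, open = disappearance).

`run_pipeline(default_config())` ties all stages into one reproducible run
with a JSON manifest; `inst/scripts/reedgrid` is a shell entry point over
it.

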