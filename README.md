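# pondscape

Circuit-theory connectivity of urban pond networks and odonate community
responses.

Urban ponds — constructed stormwater basins and remnant natural ponds — can
act as stepping stones for actively dispersing semi-aquatic insects such as
dragonflies (Anisoptera) and damselflies (Zygoptera), but only if the
surrounding land cover lets individuals move between them. `pondscape` is an
R package for ecologists and urban planners who want to quantify that:
it models landscape connectivity as electric current flowing through a
resistance-classified land-cover raster and links per-pond connectivity to
community responses.

## The model

Each raster cell is a node of an electrical network; adjacent cells
(8-neighbourhood, diagonals penalized by √2) are joined by conductances
`g = 1 / (mean(r_a, r_b) · d)`, where cell resistances come from a
three-level land-cover scheme (primary habitat = 1, usable matrix = 10,
hostile urban cover = 100). For a node pair (s, t), injecting unit current
and solving Kirchhoff's laws on the weighted graph Laplacian,

```
L v = e,  e = +1 at s, −1 at t,  v(t) = 0
```

gives per-cell current density `c_i = ½ Σ_j |g_ij (v_i − v_j)|` — an analog
of expected movement intensity. The map is averaged over all `choose(n, 2)`
pairs of `n` random perimeter nodes (50 nodes → 1225 pairs) placed on a
randomized, representative edge-correction buffer (default 15 km wide at the
study area's own low/medium/high ratio, 14.2% : 34.8% : 51.0%), then
log10-transformed.

Per pond, at a taxon-specific radius selected from flight-distance data
(900 m for dragonflies, 300 m for damselflies), the pipeline extracts mean
and SD of current and the number of neighbouring habitat points, and runs
the statistical battery: 12 Gaussian linear models ({abundance, Shannon
diversity, richness} × {mean current, neighbours} × suborder), screening of
uninformative parameters by log-likelihood improvement, Hellinger
transformation-based redundancy analysis (tb-RDA) with seeded permutation
tests (999 permutations, Ezekiel-adjusted R²), and Wilcoxon rank-sum
comparisons of pond types. A synthetic landscape/community generator makes
the whole pipeline testable without GIS downloads.

## Worked example

A complete synthetic run: a 60×60 urban mosaic at 10 m resolution, a 150 m
randomized buffer, 20 perimeter nodes, 12 stormwater + 5 natural ponds, and
analysis radii scaled to the landscape (150 m / 60 m).

```r
library(pondscape)

cfg <- pipeline_config(
  landscape = landscape_config(60, 60, seed = 1),
  n_stormwater = 12, n_natural = 5,
  buffer_width_m = 150, n_nodes = 20,
  scales = c(Anisoptera = 150, Zygoptera = 60),
  permutations = 999, seed = 1)
run <- run_pipeline(cfg)
print(run$battery)
```

```
model battery: 12 Gaussian models, 4 redundancy analyses
               response    predictor    slope r_squared  p_value
1  Anisoptera_abundance mean_current 673.0278   0.87310 4.06e-08
2  Anisoptera_abundance n_neighbours  29.8573   0.47142 2.33e-03
3    Anisoptera_shannon mean_current   1.6086   0.58871 3.25e-04
...
7   Zygoptera_abundance mean_current -55.9848   0.25733 3.77e-02
11   Zygoptera_richness mean_current  -2.7259   0.25483 3.88e-02

RDA summaries:
                    model r_squared adj_r_squared pseudo_f p_value permutations
1 Anisoptera_mean_current    0.1401       0.08281    2.445   0.005          999
2 Anisoptera_n_neighbours    0.1211       0.06249    2.066   0.017          999
3  Zygoptera_mean_current    0.0603      -0.00232    0.963   0.488          999
4  Zygoptera_n_neighbours    0.0883       0.02748    1.452   0.167          999
```

Dragonfly abundance and richness rise steeply with mean current (slopes are
per unit log10 current density; R² up to 0.87 here), damselfly responses are
weak or negative, and the dragonfly — but not damselfly — composition is
significantly constrained by connectivity: the structure the generator
encodes and the analysis is designed to detect. Comparing pond types:

```r
nat <- run$metrics$mean_current[run$metrics$scale_m == 150 & run$metrics$type == "natural"]
sw  <- run$metrics$mean_current[run$metrics$scale_m == 150 & run$metrics$type == "stormwater"]
wilcoxon_rank_sum(nat, sw)
#> natural vs stormwater mean current: W = 56, p = 0.00719 (normal approximation)
```

Natural ponds sit in better-connected surroundings than stormwater ponds,
and the two predictors are strongly correlated
(`predictor_correlation(...)` returns 0.74 at the dragonfly scale), which
is why the battery fits them in separate models.

Every function is usable on its own: `classify_resistance()`,
`add_random_buffer()`, `build_raster_graph()`, `solve_pair()`,
`mean_current_map()`, `extract_buffer_stats()`, `select_scale()`,
`tb_rda()` and friends all take and return plain R objects
(matrix-backed rasters, data.frames). See the methods vignette
(`vignettes/pond-connectivity-methods.Rmd`) for the modelling choices and
their rationale.

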