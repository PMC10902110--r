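---
title: "Methods: circuit-theory pond connectivity and odonate community models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circuit-theory pond connectivity and odonate community models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondscape)
```

## The model

`pondscape` treats an urban landscape as an electrical circuit. Each raster
cell is a node; adjacent cells are joined by resistors whose values come from
a land-cover classification: primary odonate habitat (wetlands, urban water
bodies) has resistance 1, land covers that provide resources without being
breeding habitat (crop/pasture, grassland, large rivers, rock barren,
sand/gravel, wooded area) resistance 10, and hostile urban covers that
impede movement and cause mortality (settlement, transportation) resistance
100. Injecting one ampere between a pair of focal nodes and solving
Kirchhoff's laws on the weighted graph Laplacian, $L v = e$, yields per-cell
current densities — the circuit-theory analogue of expected animal movement
intensity. Averaging the density maps over many random node pairs placed on
the map perimeter gives an omnidirectional connectivity surface: high mean
current marks corridors and stepping-stone chains, low current marks areas
walled off by hostile cover.

Around each pond the pipeline extracts three candidate predictors at a
taxon-specific radius: the mean and standard deviation of current within the
radius and the number of neighbouring habitat points (wetland/water patch
centroids plus stormwater facility locations). Community responses per pond
— estimated abundance, species richness, Shannon diversity (natural log) —
are regressed on each predictor with Gaussian linear models, and community
composition is tested with transformation-based redundancy analysis (tb-RDA):
Hellinger-transform the site-by-species counts, column-centre, constrain on
one predictor, and assess the constrained variance fraction by a seeded
permutation test. Pond types (constructed stormwater vs natural) are compared
with Wilcoxon rank-sum tests.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| cell size | 10 | m | fine enough to keep roads as barriers, coarse enough to solve city-scale maps |
| resistance values | 1 / 10 / 100 | — | an order of magnitude per habitat-quality class; simple three-level schemes validate well across taxa |
| buffer width | 15 000 | m | an edge-correction margin > 20% of the study frame so map edges do not inflate resistance |
| buffer ratio | 0.142 / 0.348 / 0.510 | — | low/medium/high share matching the study area, so the margin is representative |
| perimeter nodes | 50 | — | gives `choose(50, 2) = 1225` pair solves, enough for a stable mean map |
| neighbourhood | 8 | — | diagonal movement allowed; diagonal conductances carry a $\sqrt 2$ distance penalty |
| scales | 900 / 300 | m | maximum mean daily flight distance per suborder, rounded to the nearest 100 m |
| permutations | 999 | — | permutation p resolution of 0.001 with the $(x+1)/(B+1)$ convention |

## Numerical choices

* **Conductance rule.** An edge between cells $a$ and $b$ has
  $g = 1 / (\bar r \cdot d)$ with $\bar r$ the average of the two cell
  resistances and $d \in \{1, \sqrt 2\}$ the centre-to-centre distance in
  cell units. Average-resistance coupling is the default rule of the
  canonical raster circuit solvers; it is stated explicitly here because
  results depend on it.
* **Grounding and solver.** The target node is fixed at 0 V and the reduced
  Laplacian solved by sparse Cholesky factorization (the grounded system is
  symmetric positive definite). Every solve is verified against a relative
  residual bound of 1e-8; a violated bound (disconnected terminals,
  ill-conditioning) is an error, not a warning. For the mean map, one
  factorization grounded at a fixed non-node cell is reused for all pairs;
  potentials are shifted per pair, which changes nothing downstream because
  only potential differences enter the currents.
* **Pair set.** All `choose(n, 2)` unordered node pairs are solved. An
  alternative mode pairing each node with its eight nearest node neighbours
  is provided (`pair_mode = "nearest"`), but all-pairs is the default: with
  50 nodes it is exactly the 1225-pair design, and the "8 neighbours"
  setting of the underlying solver refers to raster-cell adjacency.
* **log10 transform.** Raw mean current is non-negative and strongly
  right-skewed; the map is log10-transformed by default after flooring at
  1e-12 (configurable, recorded in the map's metadata). Buffer statistics
  are therefore means of log-current unless the transform is disabled, and
  the metrics table records which was used.
* **Zonal statistics.** A cell belongs to a pond's buffer when its centre
  lies within the radius (inclusive boundary) — the common zonal-statistics
  default, chosen because it is deterministic and exactly testable by
  brute-force enumeration. The SD is the sample SD ($n-1$). The focal
  pond's own water cells are not masked; neighbour counting excludes points
  within half a cell of the focal point.
* **Scale selection** rounds half-up to the nearest 100 m (base R's
  `round()` is half-even, which would be surprising here).
* **Screening threshold.** An added parameter is uninformative when it
  improves the log-likelihood by less than 1.92 — the point at which one
  extra parameter stops improving AIC. The threshold is exposed as an
  argument; several variants of the rule exist in the literature and this
  is the most common operationalization.
* **RDA internals.** With a single constraint the fitted values reduce to
  per-species projections on the centred predictor, so the constrained
  $R^2$, Ezekiel-adjusted $R^2 = 1-(1-R^2)\frac{n-1}{n-m-1}$ and pseudo-F
  have closed forms; the implementation is cross-checked in the test suite
  against an independent ordination library to 1e-10. Permutations shuffle
  site rows of the predictor under a caller-supplied seed and the p-value
  uses $(x+1)/(B+1)$, so p can never be 0. Species scores are covariances
  of the centred (transformed) species columns with the standardized
  constraining axis.
* **Wilcoxon tests** use exact enumeration when the combined n is at most
  12 with no ties, otherwise the normal approximation with midranks, tie
  correction and continuity correction; the method used is recorded.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
any particular city's geography. Landscapes are built in three passes:
random border-to-border 1-cell-wide polylines for roads, seeded ring-wise
region growing for wetland clusters (~300-cell patches by default) and
pond-like water bodies (~1 ha), and an exact-count random fill for the
remaining matrix classes. Largest-remainder apportionment of cell counts
makes empirical class proportions converge to the configured mixture (the
default mixture reproduces the 14.2/34.8/51.0 resistance ratio). Natural
ponds are placed on water/wetland cells adjacent to wetland clusters;
stormwater ponds in 5×5 windows with at least 30% settlement.

Communities are negative-binomial counts with a log link on standardized
(z-scored) connectivity: all non-indicator dragonflies share one slope
(default 0.8), damselflies share a weakly negative slope (default −0.15),
and exactly one dragonfly — the indicator species — gets a larger slope
(default 1.5) plus a natural-pond boost, concentrating it at
well-connected natural ponds. Counts are emitted per survey visit (two by
default) and aggregated by sum (configurable to max, since "estimated
abundance" can be defined either way over repeat visits). Connectivity is
standardized before entering the generator so slopes are comparable across
landscapes. The negative binomial is a modelling convenience — the
distribution of real pond counts is unknown — and the Poisson limit is
recovered as the dispersion parameter grows, which the tests exercise.

What passing tests show: the solver is exact against dense linear algebra,
the buffer construction hits its target ratio, inference is calibrated
under the generator's null, and configured effects are recoverable at
realistic sample sizes. What they do not show: anything about detection
error, spatial autocorrelation of real communities, pond-level habitat
covariates (plant structure, water quality), or the true functional form
linking connectivity to counts — real data can and do deviate from the
generator in all of these ways.

## Problem sizes

The test suite and the acceptance script run on sizes chosen to exercise
every code path while completing in minutes on one core: dense-oracle
comparisons on grids up to 200 cells; buffer-ratio checks on a 200×200
study area with a 15-cell margin; calibration with 1000 (slope tests) and
500 (permutation tests, 999 permutations each) null replicates at 49 ponds
— the Monte-Carlo standard error of a 5% rejection rate is then below 1 pp —
and effect recovery with 100 replicates of 200 ponds. The end-to-end
demonstration pipeline uses a 60×60 study grid, a 150 m buffer and 20
perimeter nodes, with analysis radii scaled to that landscape (150/60 m).
Full-size runs (15 km buffer at 10 m resolution) use the same code paths
and are limited only by memory and patience.

## Known limitations

* No coordinate reference system handling: all inputs must already share a
  projected metric system. Raster I/O is ESRI ASCII grid only.
* The buffer is a rectangular frame, not a geodesic annulus; only its width
  and resistance ratio matter for edge correction.
* Only single-constraint RDA is implemented (the analysis design fits each
  predictor separately because mean current and neighbour counts are highly
  correlated); multi-constraint ordination should use a dedicated
  ordination package.
* The GLM battery is ordinary least squares on count-derived responses,
  mirroring the analysis design it implements; residual diagnostics
  (skewness, variance-trend test) are reported so users can judge whether a
  count GLM would serve them better.
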