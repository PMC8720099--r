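---
title: "Methods: geodiversity compound indices versus environmental predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geodiversity compound indices versus environmental predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package operationalises

Geodiversity — the spatial variability of abiotic conditions and resources —
has been proposed as an easy-to-measure surrogate for biodiversity in
conservation planning: if many abiotic "stages" are present, many actors
should be able to occupy them. `geobiodiv` implements the quantitative
machinery needed to test that idea on a regional elevational gradient: it
builds a compound geodiversity index from classified environmental rasters,
standardizes taxon Shannon diversity across unequally sampled plots, fits
generalized additive models (GAMs) to both the index and the underlying
plot-level environmental values, and partitions the explained deviance of the
environmental model among climate, habitat and soil predictor groups.

Because the motivating field data are not openly deposited, the package
ships a synthetic-landscape generator with known ground truth. Everything
downstream of the generator is the same code a user would run on real
rasters, plot tables and abundance matrices.

## The compound geodiversity index

For each selected environmental variable (one each from the climate, habitat
and soil groups):

1. **Classification.** All finite raster cells are partitioned into at most
   `k = 5` classes by Fisher's optimal partitioning: the contiguous
   partition of the sorted values minimising the total within-class sum of
   squared deviations. The package computes the exact optimum by dynamic
   programming (divide-and-conquer over the distinct values, which is valid
   because the SSD cost satisfies the quadrangle inequality), not a
   heuristic. Intervals are right-closed: a value equal to a boundary falls
   into the lower class.
2. **Neighbourhood extraction.** The cell containing the plot (polygon plots
   use their centroid) plus all adjacent cells — nine pixels for an interior
   plot — are extracted from the classified grid, and class frequencies are
   tabulated. Each class is treated like a species whose abundance is its
   pixel frequency.
3. **Spatial diversity.** Shannon entropy `H = -sum(p_i log p_i)` (natural
   log) of those class frequencies.

The compound index is `G = sum_j H_j` over the selected variables, mirroring
multi-taxon analyses that sum per-taxon diversities. With `k = 5` classes
and nine pixels, each `H_j` is bounded by `log 5`, so `G <= 3 log 5 ≈ 4.83`.

Design choices a user can revisit:

* Breaks are computed over the raster's full finite extent; a mask argument
  is intentionally absent — restrict the raster before classifying if a
  study-area mask is needed.
* Truncated neighbourhoods (grid edges, nodata) renormalise proportions over
  the available cells and set a `truncated` flag; `strict = TRUE` errors
  instead.
* Each variable is processed on its own grid with a 3 x 3 *cell* window
  regardless of the physical cell size, reproducing the scale mismatch that
  mixed-resolution geodiversity studies accept.

## Standardized taxon diversity

Plots differ in sampling depth, so raw plug-in Shannon entropy is biased
low, and unequally so. The package standardizes by estimating the
*asymptotic* Shannon diversity — the value at complete sample coverage —
from each plot's abundance vector, using the singleton/doubleton-based
estimator: sample coverage
`C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`, and entropy

```
H_hat = sum_{X_i <= n-1} (X_i/n) sum_{k=X_i}^{n-1} 1/k
      + (f1/n) (1-A)^{1-n} [-log A - sum_{r=1}^{n-1} (1-A)^r / r]
```

with `A = 2 f2 / ((n-1) f1 + 2 f2)` when doubletons exist,
`A = 2 / ((n-1)(f1-1) + 2)` when `f2 = 0, f1 > 1`, and no correction when
`f1 <= 1` with `f2 = 0`. Only the asymptotic endpoint is implemented — no
rarefaction curves — because the comparison standardizes every plot to
complete coverage.

The default reported scale is the Hill number `exp(H_hat)` ("effective
species"); raw entropy in nats is available via `scale = "entropy"`. The
literature being emulated does not say which scale its reported diversities
are on; the effective-species magnitudes of its fitted intercepts motivated
the default, and both scales are exposed.

A numerical note: the unseen-species correction is evaluated through the
tail-sum identity `(f1/n) sum_{m>=1} (1-A)^m / (n+m-1)` whenever the leading
power `(1-A)^{1-n}` would overflow; the two forms are algebraically equal.

## Models and the variance partition

All models are Gaussian identity-link GAMs with one penalized cubic
regression spline per predictor, basis size 4 — so each term's effective
degrees of freedom (edf) can vary between 1 (exactly linear; the penalty
null space) and 3 — and smoothing chosen by generalized cross-validation
(GCV), via `mgcv`. Explained deviance is `1 - RSS/RSS_null`. AIC and
adjusted R² are taken from the fitted `mgcv` object (effective df as the
parameter count, the usual GAM convention).

Predictor selection follows two rules: (i) where one variable has several
statistics (mean, maximum, sd of temperature), the statistic whose
univariate GAM has the lowest AIC is chosen, ties breaking by name; (ii) if
any pair of the chosen climate/habitat/soil triple has `|Pearson r| > 0.6`,
the combination is replaced by the best-AIC combination of candidates that
passes the rule. Habitat and soil variables default to configuration rather
than an automated scan, because their choice in comparable field studies is
knowledge-guided.

The three-group variance partition fits the seven subset GAMs (three
univariate, three bivariate, one trivariate) and combines their explained
deviances `D(S)` by inclusion-exclusion into three pure, three
pairwise-shared and one triple-shared fraction. For comparability, subset
models are fitted with each term's smoothing parameter frozen at the value
estimated in the full three-predictor model (the default; re-estimation per
subset is available via `freeze = "none"` — the freezing of "model
parameters" is an interpretation, and freezing smoothing parameters is the
strictest reading that keeps the subset models nested). Shared fractions
can legitimately be negative (suppression); they are reported as-is, never
truncated to zero, and the seven components sum to the full model's
deviance exactly by construction.

Soil surfaces in the generator — and the helper `stepwise_linear()` /
`filter_soil_models()` — mirror the auxiliary soil-mapping step of such
studies: bidirectional AIC stepwise multiple regression from an
intercept-only model, retaining only models with adjusted R² above 0.45.

## The synthetic study system

`scenario_config()` defaults describe a tropical-mountain gradient:

* elevation 1000–3000 m over a 60 x 90 grid of 30 m cells; plots (default
  60, matching the upper range of per-response plot counts in comparable
  field campaigns) stratified along the gradient and jittered, kept 1.5
  cells from edges so neighbourhoods are complete;
* mean temperature follows a lapse rate of 0.68 °C per 100 m centred at
  15.89 °C, chosen so the plot-level spread (~3.9 °C) matches the emulated
  system; companion rasters (maximum and seasonal-sd temperature, humidity,
  NDVI, TPI) and soil surfaces (pH, phosphorus, organic-layer depth) are
  calibrated to the same system's means and spreads, with soil responding
  linearly to temperature/TPI plus noise and soil–climate correlations held
  near |r| ≈ 0.55 — below the collinearity rule, as in the predictor sets
  such studies end up using;
* temperature carries microclimatic roughness whose amplitude itself varies
  smoothly in space. This matters for the *heterogeneity-driven* regime:
  with purely smooth surfaces the local 3 x 3 standard deviation is nearly
  constant and the regime would be degenerate;
* true Shannon entropy per plot is affine in the standardized driver value
  (condition mode) or in the driver's local 3 x 3 sd (heterogeneity mode),
  clamped to the feasible band; `effect_size` is in nats per driver sd,
  default 1. Communities are multinomial draws (default 200 individuals)
  from log-normal rank-abundance profiles whose shape is tuned by bisection
  until the profile entropy matches the target to 1e-6. Ecosystem-function
  values are affine in the same driver plus Gaussian noise (sd 5 response
  units around a base of 50);
* all randomness flows from one master seed through named substreams
  (rasters, plots, communities, functions), so bundles regenerate
  byte-identically.

What the generator does *not* emulate: real radiometry or sensor noise,
Andean topography, spatial autocorrelation of community composition between
plots, detection error, and plot-count imbalance between responses. Passing
tests on these landscapes therefore demonstrate that the pipeline recovers
known structure under idealised sampling, not that any field conclusion is
reproduced.

## What the simulations show (and their sizes)

With the default landscape (60 plots, 60 x 90 cells — sizes chosen so a
single comparison runs in about a second):

* **Condition-driven regime**: the three-predictor environmental model
  out-explains the univariate compound-index model in essentially all
  seeds; the index carries almost no signal because class membership within
  a 3 x 3 window varies little along a smooth gradient.
* **Heterogeneity-driven regime**: the index gains real explanatory power
  and its deficit relative to the environmental model shrinks strongly
  (median gap moves from about -0.95 to about -0.13 in explained deviance),
  but the environmental model typically keeps an edge: plot-level values
  become more dispersed where heterogeneity is high, so the smooths can read
  part of the same signal, and the 5-class global classification quantizes
  local variability coarsely. This asymmetry is itself a known critique of
  compound indices.
* **Null regime** (`effect_size = 0`): the univariate index model almost
  always shows near-zero deviance. The three-predictor model, however,
  averages ~0.1 explained deviance at n = 60 even on pure noise: a model
  with three smooths carries roughly five effective df (~0.08 expected
  deviance) and GCV's sampling variability adds more. Small-sample
  optimism of GCV-chosen GAMs is a real limitation of this model class at
  realistic plot counts, and the package reports it rather than hiding it.

## Numerical conventions and degenerate inputs

* Fisher breaks with fewer distinct values than classes return one class per
  distinct value; DP ties break toward the earliest split.
* A point exactly on a shared cell edge belongs to the cell with the larger
  row/column index; polygon extraction uses the cell-centre containment
  rule.
* Entropy of a single class/species is 0; empty or all-zero abundance
  vectors are errors, not zeros.
* An entropy target of exactly 0 returns the degenerate single-species
  profile (reachable only in the infinite-shape limit).
* AIC ties in selection break alphabetically; this is documented behaviour,
  not chance.
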