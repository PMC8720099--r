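# geobiodiv

Can a single *compound geodiversity index* — the summed spatial diversity of
classified environmental rasters around a plot — stand in for the
environmental variables themselves when predicting species diversity and
ecosystem functions along an elevational gradient? `geobiodiv` implements
the full quantitative machinery needed to ask that question on any set of
rasters, plots and abundance tables, and ships a synthetic
tropical-mountain landscape generator with known ground truth so the whole
pipeline is testable end to end without field data.

The package is written tidyverse-style: per-plot tables go in and come out
as tibbles, fitted objects have `tidy()`/`glance()` methods, and result
types have `autoplot()` methods.

## What it computes

**Compound geodiversity index.** For each selected environmental raster
(one per climate/habitat/soil group): Fisher's optimal (natural-breaks)
classification into k = 5 classes — the exact within-class
sum-of-squares optimum by dynamic programming — then, per plot, the class
frequencies of the 3 × 3 pixel neighbourhood (nine pixels), their Shannon
entropy H_j = −Σ p_i ln p_i, and the compound index G = Σ_j H_j.

**Standardized taxon diversity.** Plug-in Shannon entropy is biased by
sampling depth, so plots are standardized to complete sample coverage with
the singleton/doubleton asymptotic estimator: coverage
Ĉ = 1 − (f₁/n)·((n−1)f₁ / ((n−1)f₁ + 2f₂)) and the asymptotic entropy Ĥ
(observed part plus an unseen-species correction), reported by default on
the Hill-number scale exp(Ĥ) ("effective species").

**Models.** Gaussian GAMs (via `mgcv`) with cubic regression splines of
1–3 effective degrees of freedom per predictor, smoothing by GCV; explained
deviance 1 − RSS/RSS₀; AIC choice among climate statistics; the |r| > 0.6
collinearity rule; bidirectional stepwise linear models for soil surfaces
with the 45 % retention rule; and a three-set variance partition of the full
model's explained deviance into 7 pure/shared fractions by
inclusion–exclusion over the seven subset GAMs, with smoothing parameters
frozen from the full model (negative shared fractions are reported as-is).

## Worked example

```r
library(geobiodiv)

cfg  <- scenario_config(seed = 42)        # condition-driven gradient, 60 plots
land <- generate_landscape(cfg)
res  <- run_study(land)
tidy(res)
#> # A tibble: 2 × 9
#>   response  climate   habitat soil       env_deviance geodiv_deviance ...
#> 1 diversity temp_mean ndvi    phosphorus        0.987          0.0924
#> 2 function  temp_mean ndvi    phosphorus        0.924          0.0939
```

True diversity in this scenario responds to mean temperature. The pipeline
selects mean temperature among the climate statistics by AIC, fits the
three-predictor environmental GAM (explained deviance 0.99) and the
univariate GAM on the compound index built from the *same* three rasters
(0.09): the environmental variables carry the signal, the summed-entropy
index does not — the headline contrast this package exists to probe. The
variance partition attributes the explained deviance mostly to climate:

```r
tidy(res$vp[[1]])
#> 1 pure_climate           0.757
#> 4 shared_climate_habitat 0.168
#> ...                      (7 fractions, summing exactly to the full deviance)
```

Per-plot diversity standardization is available directly:

```r
asymptotic_shannon(c(8, 5, 3, 2, 1, 1))
#>       n s_obs    f1    f2 h_obs coverage h_asym d_asym
#>      20     6     2     1  1.53    0.905   1.72   5.60
```

`autoplot(res)` draws the paired explained-deviance bars;
`autoplot(res$vp[[1]])` the partition; `plot_raster()` any raster surface.

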