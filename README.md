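# hylai — assessing hybrid LAI retrieval workflows

`hylai` is an R package for scientists who build *hybrid* retrieval
workflows for forest Leaf Area Index (LAI): a canopy radiative-transfer
model (RTM) is run forward to simulate the band reflectances of a sampled
parameter space, Gaussian noise is added to the simulated bands, a
machine-learning regression algorithm (MLRA) learns the inverse
band-to-LAI mapping, and the fitted model inverts real (here: synthetic)
multispectral satellite observations. Such workflows hide many design
decisions — which RTM, how much and which kind of noise, whether to give
the learner the sun angle, which regressor — and this package measures how
much each decision matters by running the **full factorial grid** of

```
{free, prior} x {TURBID, GEOM} x sigma_AI {0,.05,.1,.2} x sigma_MI {0,.05,.1,.2,.3}
             x {without, with SZA} x {OLS, MLP, RT, SVR, KRR, GPR}  =  960 realisations
```

and scoring every realisation against an independent field reference.

The pieces, each usable on its own:

* **Sensors** — Sentinel-2A MSI / Landsat 7 ETM+ / Landsat 8 OLI band sets,
  Gaussian spectral response functions (FWHM = band width), band
  convolution, overlap-weighted plot reflectance extraction.
* **RTM surrogates** — two structurally contrasting canopy reflectance
  models behind a pluggable interface: a homogeneous turbid medium
  (`BRF = rho_inf + (rho_soil - rho_inf) e^{-(G/cos th_s + G) LAI}`) and a
  crown-explicit scene with Poisson crown cover and sun-angle shadowing.
* **Training databases** — Latin hypercube sampling over free or
  prior-constrained ranges, 30% barren injection, and the two-component
  noise model `rho' = rho + rho e_MI + e_AI`.
* **MLRAs** — OLS, random forest, single-hidden-layer perceptron, SVR,
  kernel ridge and Gaussian-process regression under one seeded
  fit/predict contract with cross-validated tuning.
* **Emulator** — per-band regression surrogate of an RTM, winner chosen by
  5-fold CV RMSE.
* **Sobol sensitivity** — Saltelli designs and Jansen total-effect
  indices, normalised per band.
* **Field reference** — TLS hinge-angle gap fractions
  (`PAI = -1.1 ln P_gap`), litter-trap seasonal LAI
  (`mass * SLA * 1e-4 / area`), per-plot TLS calibration
  (`LAI_i = (PAI_i - min PAI)/max PAI * LAI_LT`) and the RMSE / R² / bias
  scoring used throughout.
* **Synthetic world** — a five-plot deciduous forest year with known truth
  (double-logistic phenology, senescing leaf chemistry, cloud-thinned
  observation calendars, noisy TLS and litter records), so the entire
  pipeline is testable offline.

## Worked example

Build a synthetic year, derive the validation reference from its TLS and
litter records, and run a small 8-cell feature grid:

```r
library(hylai)
library(dplyr)

world <- build_world(seed = 1)          # GEOM truth, 5% observation noise
world
#> <synth_world> 5 plots, truth RTM GEOM
#>   250 usable plot-observations across 3 sensors; 140 TLS records; 175 litter records

reference <- build_reference(world)$series

grid <- build_grid(feature_domains(
  prior = "free", rtm = c("TURBID", "GEOM"), sigma_ai = c(0, 0.05),
  sigma_mi = 0, sza = FALSE, mlra = c("OLS", "RT")
))
results <- run_grid(grid, world, reference,
                    grid_config(n_train = 500, n_test = 100, seed = 1))

feature_ensemble_stats(results, "sigma_ai")
#> # A tibble: 2 x 6
#>   feature  delta_rmse level     n median_rmse    iqr
#>   <chr>         <dbl> <chr> <int>       <dbl>  <dbl>
#> 1 sigma_ai       4.99 0         4        6.20 28.6
#> 2 sigma_ai       0    0.05      4        1.22  0.319

best_report(results)$best |>
  select(id, rtm, sigma_ai, mlra, test_rmse, val_rmse, val_r2, val_bias)
#> # A tibble: 1 x 8
#>   id    rtm    sigma_ai mlra  test_rmse val_rmse val_r2 val_bias
#>   <chr> <chr>     <dbl> <chr>     <dbl>    <dbl>  <dbl>    <dbl>
#> 1 r0002 TURBID        0 RT         1.65    0.992  0.761    0.460
```

Reading the numbers: without additive training noise the ensemble median
validation RMSE is 6.2 m² m⁻² with an enormous spread (the IQR of 28.6
comes from linear and kernel inversions collapsing on clean simulated
spectra), while 5% additive noise pulls the median to 1.22 m² m⁻² and
removes the catastrophic tail — noise regularises the inverse mapping and
bridges the structural mismatch between the turbid training model and the
crown-explicit truth. The best single realisation here reaches RMSE
0.99 m² m⁻² and explains 76% of the reference variance, with a +0.46 m² m⁻²
mean bias driven by the saturation of the surrogate's bands at high LAI
(see the methods vignette for why that floor exists).

Plot helpers: `autoplot()` on a sensitivity result or reference series,
`plot_grid_rmse(results, "mlra")`, `plot_realisation_series()`.

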