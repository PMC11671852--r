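# firerecov

Per-pixel estimation of post-fire vegetation recovery rates from satellite
greenness (EVI) time series, for fire ecologists and remote-sensing analysts
studying recurrent fires in Mediterranean-type ecosystems.

## The method

Monthly EVI is normalized against each pixel's ideal seasonal cycle — the
*Gorgeous Year* GY(m), the maximum EVI observed in calendar month *m* over the
record — giving a loss-of-greenness series

    y(t) = EVI(t) − GY(month(t)),   y ∈ [−1, 0].

Assuming the recovery rate is proportional to the remaining deficit,
dy/dt = −b·y, the post-fire deficit decays as

    y(t) = a e^(−b t),

where *a* (the post-fire minimum of *y*) measures fire severity and *b*
(month⁻¹) the recovery rate; 1/*b* is the characteristic recovery time at
which about half the relative recovery is reached. *b* is the negative slope
of the regression of ln(−y) on time, fitted over 2–5-year windows after the
minimum and screened at adjusted r² ≥ 0.25. Severity is compared across
pixels as a_REL = |a| / GY_MEAN.

Around the fit, the package implements the full analysis chain: gap filling
and FFT/LOESS pre-processing of 16-day composites, burn-date-uncertainty and
fire-season filtering of burned-area records, selection of twice-burned
pixels (two in-season fires ≥ 4 years apart), Wilcoxon signed-rank tests of
b_DIFF = b₂ − b₁, IQR-based contrast groups, bivariate (a_REL, b) kernel
densities with quantile-regression envelopes at τ = 0.01/0.99, pre-fire-state
binning, and seasonal standardized climate anomalies over the four post-fire
quarters. A synthetic-scene generator with a truth ledger makes every stage
testable against known answers.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
20 × 20 scene (all outputs under `results/`):

```sh
Rscript analysis/01_simulate_scene.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_fire_history.R
Rscript analysis/04_recovery_fits.R
Rscript analysis/05_modulation.R
Rscript analysis/06_climate.R
Rscript analysis/07_validation_experiments.R
```

Stage 4 prints, for this scene:

```
fits: 800 events, 800 valid (adj r2 >= 0.25)
median fitted b: 0.0653 month^-1 (characteristic time 15.3 months)
  BL  median b = 0.0660 month^-1, 1/b = 15.2 months (n = 238)
  NL  median b = 0.0621 month^-1, 1/b = 16.1 months (n = 174)
```

i.e. a median recovery rate of about 0.065 month⁻¹, a characteristic
recovery time of ~15 months, and per-land-cover medians — the same summary
statistics one would report for a real cohort. Stage 7 validates the
estimator against the generator's truth ledger:

```
noiseless: max rel err b = 3.52e-15, a = 1.39e-16 (n = 4)
noisy (sd 0.02): median rel err 4.9%, CI coverage 92.4% (n = 500)
injected +0.005/month: median b_DIFF = 0.00531, Wilcoxon p = 6.28e-26
```

A minimal interactive session:

```r
library(firerecov)
scene   <- simulate_scene(sim_config(grid_rows = 10, grid_cols = 10, seed = 1))
monthly <- preprocess_cube(scene$evi)
gy      <- compute_gorgeous_year(monthly)
y       <- loss_series(monthly, gy)[, 3, 3]        # one pixel's deficit
fire    <- scene$ledger$events$month_index[scene$ledger$events$pixel == 23][1]
sev     <- locate_severity(y, fire)
fit_recovery(y, sev$t0, sev$a, gy_mean = gy$gy_mean[3, 3])
```

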