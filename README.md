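# stemflux

Tools for analysing high-resolution point-dendrometer records of tree stems.
Point dendrometers resolve micrometre-scale radius changes at sub-hourly
cadence; mounted in parallel over the living bark and on the xylem of the
same stem they separate the water-related shrinking and swelling of the
elastic inner bark (living phloem, cambium, parenchyma) from the much
stiffer xylem, and so make the radial water exchange between these tissues
observable. `stemflux` implements the full processing chain from raw 30-min
records to coupling statistics, plus a mechanistic stem-hydraulics simulator
that provides known ground truth for validating every stage.

## What the package computes

Given per-tree over-bark and on-xylem radius records and co-located
microclimate records (air temperature T, relative humidity RH, solar
radiation SR, precipitation P, soil water content SWC), the pipeline:

1. derives vapour pressure deficit by the Magnus form,
   VPD = 0.6108 · exp(17.27 T / (T + 237.3)) · (1 − RH/100) kPa;
2. removes thermal-expansion artifacts (over-bark sensor: 0.2 µm °C⁻¹;
   xylem sensor with its steel mounting screw: 1.08 µm °C⁻¹);
3. decomposes inner-bark variation as over-bark minus xylem, and averages
   trees with per-timestamp standard errors;
4. reduces traces to daily metrics (mean, max, min, amplitude, clock times
   of extrema, day-to-day mean change) and climate to daily aggregates;
5. detrends daily series with a hard-cutoff FFT low-pass filter
   (mirror-padded; default cutoffs 10 and 25 days) to isolate residual,
   weather-driven fluctuations;
6. quantifies coupling and environmental control: Spearman rank
   correlations (tie-aware, t-approximation p-values), forward stepwise
   regression with backward checks (partial-F entry/removal at 0.05/0.10),
   a logarithmic fit of daily xylem amplitude against daily maximum VPD
   (amplitude = a + b·ln(VPDmax)), and the inner-bark-behind-xylem lag by
   cross-correlation with parabolic refinement.

The simulator treats the stem as a transpiration-driven passive hydraulic
system: a quasi-steady xylem node fed from the soil through resistance
r_soil and coupled to an elastic storage pool (capacitance c_stor) through
exchange resistance r_stor. Transpiration E = g_max · s(SR) · VPD /
(1 + VPD/vpd_sat) pulls the xylem water potential down during the day;
storage discharges into the xylem with time constant τ = r_stor · c_stor,
which makes inner-bark shrinkage lag xylem shrinkage by about τ. Potentials
map to radii through tissue elasticities (default eps_b/eps_x = 10), with
Gompertz seasonal growth, thermal artifacts, sensor noise and logger gaps
added on top.

## Worked example

Simulate a four-tree stand over two growing seasons and run the whole
analysis:

```r
library(stemflux)
res <- run_pipeline(run_config(out_dir = "stemflux-demo", seed = 42,
  simulate = list(weather = list(n_days = 548), n_trees = 4)))
print(res$report)
#> <coupling_report>
#>   residual coupling: rho = 0.995 (p = 0, n = 365)
#>   inner-bark lag behind xylem: 1.68 h
#>   bark:xylem amplitude ratio: 9.00
#>   amplitude ~ ln(VPDmax): R^2 = 0.804 (linear 0.776)
print(res$report$stepwise_models$Xyl_min)
#> <stepwise_model> t_max + swc_mean + rh_min + t_mean; adj R^2 = 0.920; F(4, 360) = 1046.03; n = 365
```

Reading the numbers: the detrended daily means of xylem and inner bark are
almost perfectly rank-correlated (ρ = 0.995) because in the simulator the
two tissues are tied by one water-potential gradient; inner-bark extrema
trail xylem extrema by ~1.7 h, close to the configured storage time
constant τ = 2 h (a first-order storage responds with a phase lag slightly
below τ under diurnal forcing); the inner-bark daily amplitude is ~9× the
xylem amplitude, the elasticity ratio of 10 shrunk by the storage low-pass;
and the saturating canopy conductance makes the logarithmic amplitude-VPD
fit beat the linear one. The stepwise model recovers the atmospheric
drivers (temperature, humidity) plus soil water as predictors of the daily
xylem minimum, with the same sign pattern (e.g. Xyl_min vs T_max ρ = −0.86,
vs SWC positive) expected of a transpiration-driven stem.

The bundle written to `out_dir` contains `climate.csv`, `dendro.csv`,
`daily_radius.csv`, `daily_climate.csv`, `table1.csv` (growing-season
climate summary), `residuals.csv`, `table2.csv` (correlation matrix),
`table3.csv` (stepwise models), `fig6_fits.csv` (amplitude fits),
`coupling_report.json`, `truth.json` and `manifest.json`. To analyse real
deposited data instead, point `run_config(input = list(dendro_csv = ...,
climate_csv = ..., col_map = ...))` at the files; a `col_map` block remaps
foreign column names, and `preprocess = list(skip_thermal = TRUE)` skips
the thermal correction when the deposit is already corrected.

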