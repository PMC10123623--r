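# laurdanspec

Analysis of steady-state Laurdan emission spectra from lipid membranes:
generalized polarization, two-band asymmetric log-normal decomposition
(individual and global fits), and relaxed/nonrelaxed population fractions
tracked along a hydration or cholesterol condition axis.

Laurdan's emission red-shifts when interfacial water reorients around the
excited probe (dipolar relaxation), so a spectrum from a fluid bilayer can
be modeled as two interconverting populations: a short-wavelength band
(nonrelaxed environment, ~427–430 nm) and a long-wavelength band (relaxed,
hydrated environment, ~475–482 nm). The package is written for membrane
biophysicists who measure emission spectra of supported bilayers or
vesicles across a condition series — relative humidity (RH), cholesterol
molar fraction x_Chol — and want reproducible, tested numbers for:

* **GP** = (I₄₄₀ − I₄₉₀)/(I₄₄₀ + I₄₉₀), with intensities averaged over a
  5-point (~2 nm) window, reported per condition as mean ± SD over
  replicate spots;
* **band decomposition** into Siano–Metzler log-normal bands
  I(ν) = Iₘ·exp[−(ln2/ln²ρ)·ln²((a−ν)/(a−νₘ))] in wavenumber space,
  with physically-bounded least squares (asymmetry cap ρ ≤ 1.5 as a hard
  constraint) and R² reporting;
* **global fits** sharing the two band peak positions across all
  conditions of a series, the estimator used for population-fraction
  trajectories;
* **fractions** = analytic band areas as a percentage of the total
  fitted emission.

A calibrated synthetic-data generator (`generate_spectra()`) emulates
dehydration and cholesterol series — two fixed band templates mixed by a
per-condition relaxed fraction, with replicate brightness jitter and
additive noise — so every stage of the pipeline is testable without
experimental data.

## Worked example

```r
library(laurdanspec)

# a noise-free dehydration series: 11 conditions from bulk hydration
# (coded RH = 100) down to 0% RH
report <- run_pipeline(list(
  simulate = list(preset = "dehydration", spots = 1, noise = FALSE),
  gp = list(min_spots = 1)))

subset(report$gp_trajectory, condition %in% c(100, 40, 0))
#>    condition_kind condition    mean_gp sd_gp n_spots
#> 1       hydration       100 -0.1972123     0       1
#> 7       hydration        40  0.4039743     0       1
#> 11      hydration         0  0.6202479     0       1

report$global_fit
#> <global_fit> 11 conditions (hydration axis)
#>   shared peaks: short 23419.2 cm^-1 (427.0 nm), long 21052.6 cm^-1 (475.0 nm)
#>   R^2 range: 1.00000 - 1.00000

subset(report$fractions, condition %in% c(100, 0))
#>    condition fraction_long fraction_short
#> 1        100            79             21
#> 11         0            18             82
```

Read: at full hydration GP is negative (disordered, hydrated bilayer) and
79% of the emission comes from the relaxed (long-wavelength) population;
at 0% RH GP reaches 0.62 (gel-like, water-depleted) and the relaxed
population has dropped to 18%, the plateau value below 20% RH. The global
fit locates the two band peaks at 427 and 475 nm and describes every
spectrum essentially perfectly (R² = 1 for noise-free input; > 0.993 is
the quality floor for realistic data).

Spectra move in and out of the package as long-format CSV/TSV
(`condition_kind, condition_value, spot, wavelength_nm, intensity`) via
`read_spectra()` / `write_spectra()`; `run_pipeline()` also accepts a YAML
configuration and writes CSV/JSON reports plus a run log.

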