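---
title: "Quantifying membrane hydration from Laurdan emission spectra"
author: "laurdanspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane hydration from Laurdan emission spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laurdanspec)
```

## The problem and the model

Laurdan is a solvatochromic probe that inserts into lipid bilayers near the
glycerol backbone. On excitation its dipole moment increases sharply; if
polar groups — chiefly interfacial water — can reorient around the excited
probe within its fluorescence lifetime, the emitted photon loses energy and
the emission red-shifts ("dipolar relaxation"). In the simplest useful
picture the steady-state emission of Laurdan in a fluid, single-phase
bilayer is a superposition of exactly two contributions:

* a **short-wavelength band** from probes whose environment did *not*
  relax (ordered, dehydrated surroundings), and
* a **long-wavelength band** from probes in a readily relaxing
  (hydrated, disordered) environment.

Two summary statistics track the balance between these populations along an
experimental condition axis such as the relative humidity (RH) over a
solid-supported bilayer, or the cholesterol molar fraction $x_{Chol}$:

1. **Generalized polarization**,
   $GP = (I_{440} - I_{490})/(I_{440} + I_{490})$, a ratiometric,
   scale-invariant index in $[-1, 1]$, with $I_\lambda$ averaged over a
   small window (five grid points, about 2 nm) around 440 and 490 nm to
   suppress shot noise.
2. **Band-area population fractions** from decomposing each spectrum into
   two asymmetric log-normal bands and integrating them.

### The asymmetric log-normal band

Each band is a Siano–Metzler log-normal in wavenumber
$\nu = 10^7/\lambda$ (cm$^{-1}$ for $\lambda$ in nm), with four primary
parameters: peak intensity $I_m$, peak position $\nu_m$, and the two
half-intensity positions $\nu_{max} > \nu_m > \nu_{min}$. Writing the
asymmetry $\rho = (\nu_m - \nu_{min})/(\nu_{max} - \nu_m)$, the FWHM
$H = \nu_{max} - \nu_{min}$ and the limiting wavenumber
$a = \nu_m + H\rho/(\rho^2 - 1)$,

$$I(\nu) = I_m \exp\!\left[-\frac{\ln 2}{\ln^2 \rho}\,
  \ln^2\!\frac{a - \nu}{a - \nu_m}\right],$$

zero beyond $a$, and the Gaussian of the same peak and FWHM in the limit
$\rho \to 1$ (handled as an explicit branch; a continuity test pins the
two branches together). The definition guarantees $I(\nu_m) = I_m$ and
$I(\nu_{max}) = I(\nu_{min}) = I_m/2$, and these identities are exactly
what the test suite uses to pin the functional convention. The band area
has the closed form (substitution $u = \ln((a-\nu)/(a-\nu_m))$):

$$A = I_m\,(a - \nu_m)\,\ln\rho\,\sqrt{\pi/\ln 2}\;
  e^{\ln^2\rho/(4\ln 2)},$$

cross-checked against adaptive quadrature to $10^{-8}$ relative error.
Population fractions are always computed from these analytic areas, so
`fraction_long + fraction_short = 100` holds to machine precision.

## Fitting strategy

Fits run in wavenumber space on the intensities as measured (no Jacobian
factor: the model describes the recorded counts, and applying the
$\lambda^2/10^7$ correction is exposed separately via
`to_wavenumber(jacobian = TRUE)` for workflows that need conserved
integrals). Each band is parameterized for optimization as
$(I_m, \nu_m, H, \rho)$; $\nu_{max}, \nu_{min}$ are derived. This makes
every physical constraint a box bound handled natively by the bounded
Levenberg–Marquardt optimizer (`minpack.lm::nls.lm`):

| parameter | default bounds | why |
|---|---|---|
| $\nu_m$ (short band) | $10^7/450$ – $10^7/410$ cm$^{-1}$ | brackets nonrelaxed Laurdan peaks (~427–430 nm) |
| $\nu_m$ (long band) | $10^7/510$ – $10^7/455$ cm$^{-1}$ | brackets relaxed peaks (~475–482 nm) |
| $H$ | 800 – 4000 cm$^{-1}$ | physically meaningful emission bandwidths |
| $\rho$ | 0.5 – 1.5 | the asymmetry cap: the lower half-width may not exceed 1.5× the upper |
| $I_m$ | 0 – 10×max intensity | nonnegativity |

Because $\rho \le 1.5$ is a *bound on a fitted parameter*, no returned fit
can violate the asymmetry cap — it is a hard guarantee, not a post-hoc
filter. The two $\nu_m$ windows do not overlap, so the short/long labels
cannot swap during optimization; bands are nevertheless relabeled by peak
position after every fit.

**Starting values and restarts.** `initial_guess()` places the bands at
$10^7/430$ and $10^7/480$ cm$^{-1}$ with a common width taken from the
spectrum's overall width at half maximum and $\rho = 1$. Least-squares
surfaces for overlapping-band mixtures have local minima, so
`fit_individual()` runs a deterministic multi-start: the initial guess,
four width/asymmetry variants, and a scan combining canonical and
data-driven peak positions (the intensity argmax inside each $\nu_m$
window, with a local half-width estimate). The first start whose residual
sum of squares falls below $10^{-7}$ of the spectrum's total sum of
squares — an essentially exact fit — wins; otherwise all starts run and
the lowest-residual solution is kept. Each start has an iteration budget
of 1024; non-convergence is flagged in the result, never hidden. Fits
whose peaks approach within 200 cm$^{-1}$ are flagged `degenerate`.

**Global fits.** `fit_global()` fits all conditions of a series jointly,
with the two peak positions $\nu_m$ shared across conditions and
$(I_m, H, \rho)$ free per condition; the residual is the unweighted
concatenation of the per-condition residuals. Starting values are the
means of the individual-fit parameters, which is the conventional choice
for global analysis. Peak-position stability across a hydration or
cholesterol series is a physical property of the two-state
interconversion, and sharing $\nu_m$ is also what makes the fraction
trajectory statistically well behaved (see *Identifiability*, below).

**Goodness of fit** is the coefficient of determination
$R^2 = 1 - SS_{res}/SS_{tot}$; values above 0.993 indicate that the
two-band model describes a spectrum essentially completely.

## The synthetic-data generator

No experimental spectra ship with the package, so `generate_spectra()`
provides a forward model of exactly the structure the analysis assumes:
for each condition with relaxed fraction $f$,

$$S(\nu) \propto f\,\frac{L(\nu)}{A_L} + (1 - f)\,\frac{B(\nu)}{A_B},$$

with fixed band templates $L$ (long/relaxed) and $B$ (short/nonrelaxed)
*area-normalized before mixing*, so $f$ is by construction the long band's
true area fraction — the same quantity the decomposition reports. The
mixture is scaled to a nominal 10^4 counts at its peak; each replicate
"spot" receives a multiplicative brightness factor
$\mathcal{N}(1, 0.05)$ (replicate spectra of real samples differ mainly
in overall intensity) and additive Gaussian noise with
$\sigma = 1\%$ of the condition's peak (comparable replicate scatter to
GP standard deviations of ±0.03–0.04). Negative excursions in the far
tails are truncated at zero, since measured counts are nonnegative; the
truncation adds a small positive pedestal (~0.4 $\sigma$) where the
signal is near zero, a deliberate, documented feature of the noise model.
One seeded RNG stream per set makes output bit-reproducible, and the
global RNG state is restored afterwards. A *truth record* stores every
generating parameter for recovery tests.

### Calibrated presets

Three presets define the shipped condition series. Their band templates
are fixed across conditions (peak positions of real series shift
negligibly compared to the band separation) and were calibrated once —
`inst/scripts/calibrate-presets.R` reproduces the computation — so that
the noise-free pipeline lands on the reference endpoint values; the
constants are committed, never searched at run time.

* **dehydration**: conditions bulk (coded RH = 100), 95, 80, 70, 60, 50,
  40, 30, 20, 10, 0% RH; peaks 475/427 nm; FWHM 3000/2380 cm$^{-1}$;
  $\rho = 1.2$ for both bands (emission bands tail toward long
  wavelength). Fraction trajectory: 0.79 at bulk, linear in RH down to
  0.18 at 20% RH, constant below (the plateau). Endpoints: bulk
  $GP = -0.20 < 0$, $GP(0\% RH) = 0.620$.
* **cholesterol**: $x_{Chol}$ = 0, 0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 0.6;
  peaks 482/430 nm, same widths; fraction linear from 0.79 to the
  calibrated endpoint 0.32 at $x_{Chol} = 0.6$, giving
  $GP(x_{Chol}=0.6) = 0.385$.
* **phase_separated_ld**: dehydration templates with a trajectory that
  declines to 0.42 at 50% RH, holds a plateau to 20% RH, then declines
  slightly to 0.36 — the qualitative signature of the liquid-disordered
  region of a phase-separated membrane, where the condition response
  stalls over mid humidities.

Only the printed endpoints anchor the trajectories; intermediate values
are linear interpolations by design, not digitized curves. The widths,
the common $\rho = 1.2$, and the 5% / 1% noise levels are the package's
own realistic choices where no reference value exists.

The default wavelength grid is 380–640 nm at 0.4 nm. The range is chosen
so that both bands are covered down to 1% of their peak intensity — the
generator refuses grids that truncate a band's support above that level —
and the spacing makes the five-point GP window span about 2 nm.

## What passing tests do and do not show

The generator emulates the *statistical* structure of a dehydration or
cholesterol series: two fixed bands, interconverting populations,
replicate brightness jitter, additive noise. It does not emulate vibronic
structure, wavelength-dependent instrument response, baseline drift,
cosmic rays, phase coexistence (spectra are always single-phase
mixtures), or any photophysics beyond the two-state picture. Recovery
tests therefore validate the *pipeline's inverse problem* — that the
implementation faithfully inverts its own forward model under realistic
noise — not the adequacy of the two-state model for any particular
membrane.

### Identifiability

Two practical limits of the decomposition are worth knowing, both mapped
out quantitatively during development:

* **Free peak positions are expensive.** With all eight parameters free,
  the Cramér–Rao bound on the fraction estimate at 1% additive noise is
  5–8 percentage points per spectrum (worst at extreme fractions):
  heavily overlapped bands trade width, asymmetry and position against
  each other at nearly constant residual. Averaging the default ten
  replicate spots reduces this to ~2 pp, and the global fit — which pins
  the two shared $\nu_m$ with information from the whole series —
  collapses it to well under 1 pp. This is why the pipeline reports
  fraction trajectories from the global fit, with individual fits serving
  as model validation and starting values.
* **Exact parameter recovery needs the two-state family.** For
  noise-free spectra generated from the preset templates, the fit
  recovers every band parameter to better than $10^{-3}$ relative.
  For *arbitrary* band pairs crammed into the bound windows, local
  minima can reproduce a spectrum to $R^2 > 0.99999$ with parameters
  displaced by several percent; no local least-squares method can
  distinguish such solutions, and the suite asserts the residual floor
  ($R^2 \ge 0.993$) rather than parameter identity there.

### Numerical choices

* $\rho$ within $10^{-8}$ of 1 takes the Gaussian branch, avoiding the
  removable singularity in $a$; a test pins continuity across the switch.
* Shared-grid checks are exact; resampling is only ever explicit
  (`resample_spectrum()`), so acquisition problems cannot be hidden by
  silent interpolation.
* FFT smoothing (`fft_smooth()`, default cutoff 0.1 of Nyquist) is for
  display, mirroring how presentation figures are prepared; GP and fits
  consume raw or spot-averaged spectra. GP windows of even width put the
  extra sample on the shorter-wavelength side, making the window
  deterministic.
* Optimizer tolerances: `ftol = ptol = 1e-12`, iteration budget 1024 per
  start. Cost convergence that tight is cheap for 8–70 parameter
  problems and removes tolerance effects from round-trip tests.
* Pipeline reports contain no timestamps, so a rerun with the same
  configuration and seed reproduces every output file byte for byte; the
  run log records the package version, seed and an MD5 hash of the
  canonicalized configuration.

### Problem sizes used by the shipped checks

The test suite and the acceptance script exercise: 20 random-model
noiseless fits; 1000 random GP spectra; the full noise-free dehydration
(11 conditions) and cholesterol (8 conditions) series with individual and
global fits; a noisy ensemble of 11 conditions × 10 spots fitted
per-spot; and a 100-condition × 10-spot recovery study analysed with
spot-averaged individual fits plus global fits over 10-condition series.
These sizes give stable statistics for every quantity checked while
keeping a full run to a few minutes on one core.

## Known limitations

* Two bands only: no model selection, no third population, no
  liquid-ordered domain spectra, no vibronic fine structure.
* The fraction trajectories between calibrated endpoints are linear by
  construction; real trajectories curve.
* Additive-noise truncation at zero slightly biases far-tail
  intensities upward; at the default noise level the effect on global-fit
  fractions is negligible but it is visible in single-spectrum fits.
* GP's link to the fraction is monotone for fixed band shapes (a tested
  property) but not linear; GP and fractions are complementary, not
  interchangeable.

## A minimal session

```{r example, eval = FALSE}
cfg <- generator_config("dehydration", spots = 10, seed = 42)
report <- run_pipeline(list(simulate = cfg), out_dir = "deh_run")
report$gp_trajectory      # mean ± SD GP per RH
report$fractions          # relaxed/nonrelaxed percentages per RH
report$global_fit         # shared band peaks, per-condition R^2
```
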