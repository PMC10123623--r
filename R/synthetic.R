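## Calibrated preset constants.
##
## Band templates are fixed across conditions within a preset (peak
## positions of real Laurdan series shift negligibly with hydration or
## cholesterol content) and were calibrated once — see
## inst/scripts/calibrate-presets.R — so that the noise-free pipeline
## reproduces the reference endpoint values:
##   dehydration: GP(0% RH) = 0.62, bulk GP < 0, fraction_long 79% (bulk)
##     -> 18% (plateau at and below 20% RH)
##   cholesterol: GP(x_Chol = 0.6) = 0.38, fraction_long 79% -> 32%
## Widths/asymmetries are in cm^-1 / dimensionless; peaks at 475/427 nm
## (dehydration) and 482/430 nm (cholesterol).
.presets <- list(
  dehydration = list(
    condition_kind = "hydration",
    conditions = c(100, 95, 80, 70, 60, 50, 40, 30, 20, 10, 0),
    peak_long_nm = 475, peak_short_nm = 427,
    fwhm_long = 3000, fwhm_short = 2380,
    rho_long = 1.2, rho_short = 1.2,
    fraction = function(v) {
      ifelse(v <= 20, 0.18, 0.18 + (0.79 - 0.18) * (v - 20) / 80)
    },
    range = c(0, 100)),
  cholesterol = list(
    condition_kind = "cholesterol",
    conditions = c(0, 0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 0.6),
    peak_long_nm = 482, peak_short_nm = 430,
    fwhm_long = 3000, fwhm_short = 2380,
    rho_long = 1.2, rho_short = 1.2,
    fraction = function(v) 0.79 - (0.79 - 0.32) * v / 0.6,
    range = c(0, 0.6)),
  ## liquid-disordered region of a phase-separated membrane: the decline
  ## stalls between 50 and 20% RH, then resumes slightly
  phase_separated_ld = list(
    condition_kind = "hydration",
    conditions = c(100, 95, 80, 70, 60, 50, 40, 30, 20, 10, 0),
    peak_long_nm = 475, peak_short_nm = 427,
    fwhm_long = 3000, fwhm_short = 2380,
    rho_long = 1.2, rho_short = 1.2,
    fraction = function(v) {
      ifelse(v >= 50, 0.42 + (0.79 - 0.42) * (v - 50) / 50,
             ifelse(v >= 20, 0.42, 0.36 + (0.42 - 0.36) * v / 20))
    },
    range = c(0, 100))
)

#' Relaxed-population fraction prescribed by a preset
#'
#' The per-condition fraction of emission carried by the long-wavelength
#' (relaxed) band in each shipped preset. The dehydration preset decreases
#' linearly from 0.79 at bulk hydration (condition value 100) to 0.18 at
#' 20% relative humidity and stays on that plateau below; the cholesterol
#' preset decreases linearly and more shallowly from 0.79 at x_Chol = 0 to
#' 0.32 at x_Chol = 0.6; the phase-separated L_d preset declines, holds a
#' plateau between 50 and 20% RH, then declines slightly further.
#'
#' @param preset `"dehydration"`, `"cholesterol"`, or
#'   `"phase_separated_ld"`.
#' @param condition Numeric condition value(s) within the preset's range
#'   (RH in %, bulk = 100, or cholesterol molar fraction).
#' @return Fraction(s) in \[0, 1\].
#' @export
#' @examples
#' fraction_trajectory("dehydration", c(100, 20, 0))
fraction_trajectory <- function(preset, condition) {
  p <- .presets[[preset]]
  if (is.null(p)) stop("fraction_trajectory: unknown preset '", preset, "'",
                       call. = FALSE)
  if (any(condition < p$range[1] | condition > p$range[2]))
    stop(sprintf("fraction_trajectory: condition out of range [%g, %g]",
                 p$range[1], p$range[2]), call. = FALSE)
  p$fraction(condition)
}

#' Band templates of a shipped preset
#'
#' @param preset Preset name.
#' @return A [two_band_model] with unit peak intensities.
#' @export
preset_templates <- function(preset) {
  p <- .presets[[preset]]
  if (is.null(p)) stop("preset_templates: unknown preset '", preset, "'",
                       call. = FALSE)
  two_band_model(
    log_normal_band_hr(1, 1e7 / p$peak_short_nm, p$fwhm_short, p$rho_short),
    log_normal_band_hr(1, 1e7 / p$peak_long_nm, p$fwhm_long, p$rho_long))
}

#' Configuration for the synthetic spectrum generator
#'
#' Describes a synthetic Laurdan series: a condition axis, two fixed band
#' templates, a relaxed-fraction trajectory, the wavelength grid, replicate
#' count, noise model and seed. The shipped presets fill every field;
#' `preset = "custom"` requires `conditions`, `band_long`, `band_short` and
#' `fraction_long` explicitly.
#'
#' @param preset `"dehydration"`, `"cholesterol"`, `"phase_separated_ld"`,
#'   or `"custom"`.
#' @param conditions Ordered condition values; preset default if `NULL`.
#' @param band_long,band_short [log_normal_band] templates (shape only;
#'   their areas are normalized away before mixing).
#' @param fraction_long Function mapping condition value to the relaxed
#'   fraction in \[0, 1\], or a numeric vector parallel to `conditions`.
#' @param grid Wavelength grid in nm. Default `seq(380, 640, by = 0.4)`,
#'   wide enough to cover both bands' support above 1% of peak.
#' @param spots Replicate spectra per condition. Default 10.
#' @param noise Logical master switch. `FALSE` produces noiseless spectra.
#' @param noise_additive Additive Gaussian sigma as a fraction of the
#'   condition's peak intensity. Default 0.01.
#' @param noise_brightness Multiplicative spot-to-spot brightness jitter
#'   sigma (spot intensities in real series differ mainly in overall
#'   brightness). Default 0.05.
#' @param peak_counts Nominal peak intensity in counts. Default 1e4.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(preset = c("dehydration", "cholesterol",
                                        "phase_separated_ld", "custom"),
                             conditions = NULL, band_long = NULL,
                             band_short = NULL, fraction_long = NULL,
                             grid = seq(380, 640, by = 0.4), spots = 10,
                             noise = TRUE, noise_additive = 0.01,
                             noise_brightness = 0.05, peak_counts = 1e4,
                             seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    if (is.null(conditions) || is.null(band_long) || is.null(band_short) ||
        is.null(fraction_long))
      stop("generator_config: custom preset needs conditions, bands and fraction_long",
           call. = FALSE)
    condition_kind <- "custom"
  } else {
    p <- .presets[[preset]]
    condition_kind <- p$condition_kind
    conditions <- conditions %||% p$conditions
    tmpl <- preset_templates(preset)
    band_long <- band_long %||% tmpl$band_long
    band_short <- band_short %||% tmpl$band_short
    fraction_long <- fraction_long %||% p$fraction
  }
  if (is.numeric(fraction_long)) {
    if (length(fraction_long) != length(conditions))
      stop("generator_config: fraction_long vector must match conditions",
           call. = FALSE)
    fr <- fraction_long
    fraction_long <- function(v) fr[match(v, conditions)]
  }
  fvals <- fraction_long(conditions)
  if (any(!is.finite(fvals)) || any(fvals < 0 | fvals > 1))
    stop("generator_config: fraction_long must lie in [0, 1] at every condition",
         call. = FALSE)
  if (band_short$nu_m <= band_long$nu_m)
    stop("generator_config: band_short must peak at higher wavenumber", call. = FALSE)
  structure(list(preset = preset, condition_kind = condition_kind,
                 conditions = as.numeric(conditions),
                 band_long = band_long, band_short = band_short,
                 fraction_long = fraction_long, grid = as.numeric(grid),
                 spots = as.integer(spots), noise = isTRUE(noise),
                 noise_additive = noise_additive,
                 noise_brightness = noise_brightness,
                 peak_counts = peak_counts, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic Laurdan spectrum set
#'
#' Forward model of the two-state analysis: for each condition, the
#' noiseless spectrum is
#' `f * L(nu) + (1 - f) * S(nu)` with `L` and `S` the area-normalized long
#' and short band templates and `f` the condition's relaxed fraction, so
#' that `f` equals the long band's true area fraction exactly. The mixture
#' is scaled to `peak_counts` at its maximum; each replicate spot gets a
#' multiplicative brightness factor `N(1, noise_brightness)` and additive
#' Gaussian noise with sigma `noise_additive * peak_counts` (truncated at
#' zero, since measured counts are nonnegative).
#'
#' @param config A [generator_config].
#' @return A list with `set` (a [spectrum_set]) and `truth`, a record of
#'   every generating parameter (per-condition fractions, band templates,
#'   noise settings, seed) for recovery tests.
#' @export
#' @examples
#' sim <- generate_spectra(generator_config("dehydration", spots = 2,
#'                                          noise = FALSE))
#' sim$set
generate_spectra <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  nu <- 1e7 / config$grid
  l <- eval_band(config$band_long, nu) / band_area(config$band_long)
  s <- eval_band(config$band_short, nu) / band_area(config$band_short)
  support_ok <- function(band) {
    peak_val <- band$i_max
    vals <- eval_band(band, nu)
    # grid must reach below 1% of peak on both flanks of each band
    vals[1L] < 0.01 * peak_val && vals[length(vals)] < 0.01 * peak_val
  }
  if (!support_ok(config$band_long) || !support_ok(config$band_short))
    stop("generate_spectra: grid does not cover both bands' support above 1% of peak",
         call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  fvals <- config$fraction_long(config$conditions)
  spectra <- list()
  truth_frac <- data.frame(condition = config$conditions,
                           fraction_long = fvals)
  for (i in seq_along(config$conditions)) {
    f <- fvals[i]
    base <- f * l + (1 - f) * s
    base <- base / max(base) * config$peak_counts
    for (j in seq_len(config$spots)) {
      if (config$noise) {
        bright <- rnorm(1, 1, config$noise_brightness)
        bright <- max(bright, 0.1)   # brightness cannot go nonpositive
        y <- bright * base +
          rnorm(length(base), 0, config$noise_additive * config$peak_counts)
        y <- pmax(y, 0)
      } else {
        y <- base
      }
      spectra[[length(spectra) + 1L]] <- spectrum(
        config$grid, y, config$condition_kind, config$conditions[i],
        spot = as.character(j),
        meta = list(seed = config$seed, preset = config$preset))
    }
  }
  set <- spectrum_set(spectra, config$condition_kind, config$conditions)
  truth <- list(preset = config$preset,
                condition_kind = config$condition_kind,
                fractions = truth_frac,
                band_long = config$band_long, band_short = config$band_short,
                grid_range = range(config$grid),
                grid_step = config$grid[2] - config$grid[1],
                spots = config$spots, noise = config$noise,
                noise_additive = config$noise_additive,
                noise_brightness = config$noise_brightness,
                peak_counts = config$peak_counts, seed = config$seed)
  list(set = set, truth = truth)
}
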