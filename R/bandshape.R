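#' Asymmetric log-normal emission band (Siano-Metzler form)
#'
#' One emission band parameterized, in wavenumber space, by its peak
#' intensity `i_max`, peak position `nu_m`, and the two half-intensity
#' positions `nu_max` (upper) and `nu_min` (lower), all in cm^-1. Derived
#' quantities are the asymmetry `rho = (nu_m - nu_min)/(nu_max - nu_m)`, the
#' full width at half maximum `H = nu_max - nu_min`, and (for `rho != 1`)
#' the limiting wavenumber `a = nu_m + H * rho / (rho^2 - 1)` beyond which
#' the band is identically zero. `rho = 1` is the Gaussian limit; `rho > 1`
#' gives a band skewed toward low wavenumber (long wavelength), the usual
#' shape of emission bands.
#'
#' @param i_max Peak intensity, > 0.
#' @param nu_m Peak position in cm^-1.
#' @param nu_max,nu_min Upper and lower half-intensity positions in cm^-1;
#'   must satisfy `nu_min < nu_m < nu_max`.
#' @return An object of class `log_normal_band`.
#' @seealso [log_normal_band_hr()] for the (FWHM, asymmetry)
#'   parameterization; [eval_band()], [band_area()].
#' @export
#' @examples
#' b <- log_normal_band(1, 21000, 21800, 19800)  # rho = 1.5
#' band_rho(b)
#' eval_band(b, 21000)  # i_max at the peak
log_normal_band <- function(i_max, nu_m, nu_max, nu_min) {
  if (!(i_max > 0)) stop("log_normal_band: i_max must be positive", call. = FALSE)
  if (!(nu_min < nu_m && nu_m < nu_max))
    stop("log_normal_band: requires nu_min < nu_m < nu_max", call. = FALSE)
  structure(list(i_max = unname(i_max), nu_m = unname(nu_m),
                 nu_max = unname(nu_max), nu_min = unname(nu_min)),
            class = "log_normal_band")
}

#' @describeIn log_normal_band Construct a band from FWHM `H` (cm^-1) and
#'   asymmetry `rho`; `nu_max = nu_m + H/(1 + rho)`,
#'   `nu_min = nu_m - H * rho/(1 + rho)`.
#' @param H Full width at half maximum in cm^-1, > 0.
#' @param rho Asymmetry ratio, > 0.
#' @export
log_normal_band_hr <- function(i_max, nu_m, H, rho) {
  if (!(H > 0)) stop("log_normal_band_hr: H must be positive", call. = FALSE)
  if (!(rho > 0)) stop("log_normal_band_hr: rho must be positive", call. = FALSE)
  log_normal_band(i_max, nu_m,
                  nu_max = nu_m + H / (1 + rho),
                  nu_min = nu_m - H * rho / (1 + rho))
}

#' @describeIn log_normal_band Asymmetry `(nu_m - nu_min)/(nu_max - nu_m)`.
#' @param band A `log_normal_band`.
#' @export
band_rho <- function(band) (band$nu_m - band$nu_min) / (band$nu_max - band$nu_m)

#' @describeIn log_normal_band FWHM `nu_max - nu_min` in cm^-1.
#' @export
band_fwhm <- function(band) band$nu_max - band$nu_min

#' @describeIn log_normal_band Limiting wavenumber `a` (cm^-1); `NA` in the
#'   Gaussian limit `rho = 1`, where no cutoff exists.
#' @export
band_limit <- function(band) {
  rho <- band_rho(band)
  if (rho == 1) return(NA_real_)
  band$nu_m + band_fwhm(band) * rho / (rho^2 - 1)
}

#' @describeIn log_normal_band Peak position expressed in nm.
#' @export
band_peak_nm <- function(band) 1e7 / band$nu_m

#' @export
print.log_normal_band <- function(x, ...) {
  cat(sprintf(
    "<log_normal_band> i_max=%.4g, nu_m=%.1f cm^-1 (%.1f nm), H=%.0f cm^-1, rho=%.3f\n",
    x$i_max, x$nu_m, band_peak_nm(x), band_fwhm(x), band_rho(x)))
  invisible(x)
}

# rho treated as Gaussian when |rho - 1| < this; keeps the removable
# singularity in `a` out of floating-point trouble while staying continuous
.RHO_GAUSS_EPS <- 1e-8

#' Evaluate a log-normal band on a wavenumber grid
#'
#' For `rho != 1`:
#' `I(nu) = i_max * exp(-(ln 2 / ln^2 rho) * ln^2((a - nu)/(a - nu_m)))`
#' where the argument of the logarithm is positive, and 0 beyond the
#' limiting wavenumber `a`. For `rho = 1` the band is the Gaussian with peak
#' `nu_m` and FWHM `H`. By construction `I(nu_m) = i_max` and
#' `I(nu_max) = I(nu_min) = i_max / 2`.
#'
#' @param band A [log_normal_band].
#' @param nu Wavenumber(s) in cm^-1 (vectorized).
#' @return Intensities, same length as `nu`.
#' @export
eval_band <- function(band, nu) {
  stopifnot(inherits(band, "log_normal_band"))
  rho <- band_rho(band)
  H <- band_fwhm(band)
  if (abs(rho - 1) < .RHO_GAUSS_EPS)
    return(band$i_max * exp(-4 * log(2) * ((nu - band$nu_m) / H)^2))
  a <- band_limit(band)
  arg <- (a - nu) / (a - band$nu_m)
  out <- numeric(length(nu))
  ok <- arg > 0
  out[ok] <- band$i_max *
    exp(-(log(2) / log(rho)^2) * log(arg[ok])^2)
  out
}

#' Integrated area of a log-normal band
#'
#' The closed form follows from the substitution
#' `u = ln((a - nu)/(a - nu_m))`, which reduces the integral to a Gaussian
#' one: `area = i_max * (a - nu_m) * ln(rho) * sqrt(pi/ln 2) *
#' exp(ln^2 rho / (4 ln 2))` for `rho != 1`, and the Gaussian area
#' `i_max * (H/2) * sqrt(pi/ln 2)` in the limit `rho = 1`. The quadrature
#' method integrates [eval_band()] adaptively over the band's support and is
#' retained as an internal cross-check.
#'
#' @param band A [log_normal_band].
#' @param method `"analytic"` (default) or `"quadrature"`.
#' @return Area in counts * cm^-1.
#' @export
band_area <- function(band, method = c("analytic", "quadrature")) {
  method <- match.arg(method)
  stopifnot(inherits(band, "log_normal_band"))
  rho <- band_rho(band)
  H <- band_fwhm(band)
  if (method == "analytic") {
    if (abs(rho - 1) < .RHO_GAUSS_EPS)
      return(band$i_max * H / 2 * sqrt(pi / log(2)))
    a <- band_limit(band)
    # (a - nu_m) and ln(rho) share sign, so the product is positive
    return(band$i_max * (a - band$nu_m) * log(rho) * sqrt(pi / log(2)) *
             exp(log(rho)^2 / (4 * log(2))))
  }
  int <- integrate(function(nu) eval_band(band, nu),
                   lower = band$nu_m - 30 * H, upper = band$nu_m + 30 * H,
                   rel.tol = 1e-10, subdivisions = 4000L)
  int$value
}

#' Two-band spectral model
#'
#' The two-state Laurdan emission model: a short-wavelength band
#' (`band_short`, higher `nu_m`; probes in a nonrelaxed environment) plus a
#' long-wavelength band (`band_long`, lower `nu_m`; probes in a
#' dipolar-relaxed environment). Labels are assigned by peak position, so
#' arguments may be given in either order.
#'
#' @param band_a,band_b Two [log_normal_band] objects with distinct `nu_m`.
#' @return An object of class `two_band_model` with elements `band_short`
#'   and `band_long`.
#' @export
two_band_model <- function(band_a, band_b) {
  stopifnot(inherits(band_a, "log_normal_band"),
            inherits(band_b, "log_normal_band"))
  if (band_a$nu_m == band_b$nu_m)
    stop("two_band_model: bands must have distinct peak positions", call. = FALSE)
  if (band_a$nu_m > band_b$nu_m) {
    bs <- band_a; bl <- band_b
  } else {
    bs <- band_b; bl <- band_a
  }
  structure(list(band_short = bs, band_long = bl), class = "two_band_model")
}

#' @export
print.two_band_model <- function(x, ...) {
  cat("<two_band_model>\n  short (nonrelaxed): ")
  print(x$band_short)
  cat("  long (relaxed):     ")
  print(x$band_long)
  invisible(x)
}

#' Evaluate a two-band model on a wavelength grid
#'
#' Sums both bands at `nu = 1e7 / lambda` and returns the model spectrum on
#' the given wavelength grid.
#'
#' @param model A [two_band_model].
#' @param grid Wavelength grid in nm, strictly increasing.
#' @param condition_kind,condition_value,spot Metadata for the returned
#'   spectrum.
#' @return A [spectrum].
#' @export
model_spectrum <- function(model, grid, condition_kind = "custom",
                           condition_value = NA_real_, spot = "model") {
  stopifnot(inherits(model, "two_band_model"))
  nu <- 1e7 / grid
  int <- eval_band(model$band_short, nu) + eval_band(model$band_long, nu)
  spectrum(grid, int, condition_kind, condition_value, spot)
}
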