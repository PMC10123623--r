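#' Construct a single emission spectrum
#'
#' A `spectrum` holds one emission trace on a strictly increasing coordinate
#' grid together with its condition metadata. The native axis is wavelength
#' in nm; [to_wavenumber()] converts to cm^-1.
#'
#' @param wavelength Numeric vector, strictly increasing, all positive.
#'   Interpreted in nm when `axis = "wavelength"`, cm^-1 when
#'   `axis = "wavenumber"`.
#' @param intensity Numeric vector of nonnegative intensities (counts,
#'   arbitrary units), same length as `wavelength`.
#' @param condition_kind One of `"hydration"`, `"cholesterol"`, `"custom"`.
#' @param condition_value Numeric condition value (relative humidity in %,
#'   with bulk immersion coded as 100, or cholesterol molar fraction).
#' @param spot Replicate (spot) identifier; coerced to character.
#' @param meta Named list of free-form annotations.
#' @param axis Coordinate axis of `wavelength`: `"wavelength"` (nm, default)
#'   or `"wavenumber"` (cm^-1).
#' @return An object of class `spectrum`.
#' @export
#' @examples
#' sp <- spectrum(seq(400, 600, 10), rep(1, 21), "hydration", 100, spot = "1")
#' sp
spectrum <- function(wavelength, intensity,
                     condition_kind = "custom", condition_value = NA_real_,
                     spot = "1", meta = list(),
                     axis = c("wavelength", "wavenumber")) {
  axis <- match.arg(axis)
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  obj <- structure(
    list(wavelength = wavelength, intensity = intensity,
         condition_kind = as.character(condition_kind),
         condition_value = as.numeric(condition_value),
         spot = as.character(spot), meta = meta, axis = axis),
    class = "spectrum")
  validate_spectrum(obj)
  obj
}

validate_spectrum <- function(x) {
  if (length(x$wavelength) != length(x$intensity))
    stop("spectrum: wavelength and intensity lengths differ (",
         length(x$wavelength), " vs ", length(x$intensity), ")", call. = FALSE)
  if (any(!is.finite(x$wavelength)) || any(x$wavelength <= 0))
    stop("spectrum: coordinate grid must be finite and positive", call. = FALSE)
  if (any(diff(x$wavelength) <= 0))
    stop("spectrum: coordinate grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(x$intensity)))
    stop("spectrum: intensities must be finite", call. = FALSE)
  if (any(x$intensity < 0)) {
    i <- which(x$intensity < 0)[1L]
    stop(sprintf(
      "spectrum: negative intensity at condition=%s, spot=%s, coordinate=%g",
      format(x$condition_value), x$spot, x$wavelength[i]), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$axis == "wavelength") "nm" else "cm^-1"
  cat(sprintf("<spectrum> %d points, %s %.4g-%.4g %s\n",
              length(x$wavelength), x$axis,
              min(x$wavelength), max(x$wavelength), unit))
  cat(sprintf("  condition: %s = %s, spot: %s\n",
              x$condition_kind, format(x$condition_value), x$spot))
  invisible(x)
}

#' Construct a set of spectra sharing one grid
#'
#' A `spectrum_set` is an ordered collection of [spectrum] objects indexed by
#' `(condition_value, spot)`. All members must share an identical coordinate
#' grid (use [resample_spectrum()] first if they do not), and every
#' `(condition, spot)` pair must be unique.
#'
#' @param spectra List of `spectrum` objects.
#' @param condition_kind Axis kind; taken from the first spectrum if missing.
#' @param conditions Ordered condition values defining the axis; defaults to
#'   the unique condition values in order of first appearance.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, condition_kind = NULL, conditions = NULL) {
  if (!length(spectra)) {
    return(structure(list(spectra = list(),
                          condition_kind = condition_kind %||% "custom",
                          conditions = numeric(0)),
                     class = "spectrum_set"))
  }
  lapply(spectra, function(s) {
    if (!inherits(s, "spectrum")) stop("spectrum_set: members must be spectrum objects")
    validate_spectrum(s)
  })
  grid <- spectra[[1L]]$wavelength
  for (s in spectra[-1L]) {
    if (length(s$wavelength) != length(grid) || any(s$wavelength != grid))
      stop("spectrum_set: all spectra must share an identical grid; ",
           "resample_spectrum() converts to a reference grid explicitly",
           call. = FALSE)
  }
  keys <- vapply(spectra, function(s)
    paste(format(s$condition_value, digits = 15), s$spot, sep = "\r"), "")
  if (anyDuplicated(keys)) {
    d <- spectra[[which(duplicated(keys))[1L]]]
    stop(sprintf("spectrum_set: duplicate (condition=%s, spot=%s)",
                 format(d$condition_value), d$spot), call. = FALSE)
  }
  condition_kind <- condition_kind %||% spectra[[1L]]$condition_kind
  vals <- vapply(spectra, `[[`, 0, "condition_value")
  conditions <- conditions %||% unique(vals)
  structure(list(spectra = spectra, condition_kind = condition_kind,
                 conditions = as.numeric(conditions)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra, axis kind '%s', %d conditions\n",
              length(x$spectra), x$condition_kind, length(x$conditions)))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the spectra of one condition from a set
#'
#' @param set A [spectrum_set].
#' @param condition Numeric condition value (matched exactly).
#' @return List of `spectrum` objects (possibly empty).
#' @export
condition_spectra <- function(set, condition) {
  stopifnot(inherits(set, "spectrum_set"))
  Filter(function(s) isTRUE(s$condition_value == condition), set$spectra)
}

#' Convert a spectrum between wavelength (nm) and wavenumber (cm^-1)
#'
#' The coordinate transform is nu = 1e7 / lambda. The transformed grid is
#' re-sorted ascending. By default intensities are carried over unchanged,
#' which is how measured emission intensities are conventionally fitted;
#' setting `jacobian = TRUE` multiplies intensities by the derivative of the
#' transform (lambda^2 / 1e7 going to wavenumber) so that the integrated
#' signal is conserved.
#'
#' @param x A [spectrum].
#' @param jacobian Apply the Jacobian intensity correction? Default `FALSE`.
#' @return A `spectrum` on the transformed axis.
#' @export
#' @examples
#' sp <- spectrum(c(400, 500), c(1, 1))
#' to_wavenumber(sp)$wavelength  # 20000, 25000 cm^-1
to_wavenumber <- function(x, jacobian = FALSE) {
  stopifnot(inherits(x, "spectrum"))
  if (x$axis == "wavenumber") return(x)
  nu <- 1e7 / x$wavelength
  int <- if (jacobian) x$intensity * x$wavelength^2 / 1e7 else x$intensity
  o <- order(nu)
  spectrum(nu[o], int[o], x$condition_kind, x$condition_value, x$spot,
           x$meta, axis = "wavenumber")
}

#' @rdname to_wavenumber
#' @export
to_wavelength <- function(x, jacobian = FALSE) {
  stopifnot(inherits(x, "spectrum"))
  if (x$axis == "wavelength") return(x)
  lam <- 1e7 / x$wavelength
  int <- if (jacobian) x$intensity * x$wavelength^2 / 1e7 else x$intensity
  o <- order(lam)
  spectrum(lam[o], int[o], x$condition_kind, x$condition_value, x$spot,
           x$meta, axis = "wavelength")
}

#' Resample a spectrum onto a reference grid by linear interpolation
#'
#' Shared-grid checks in this package are exact by design, so resampling is
#' never performed silently; call this helper explicitly when combining
#' acquisitions with different grids.
#'
#' @param x A [spectrum].
#' @param grid Target coordinate grid (same axis as `x`), strictly increasing,
#'   contained within the range of `x`.
#' @return A `spectrum` on `grid`.
#' @export
resample_spectrum <- function(x, grid) {
  stopifnot(inherits(x, "spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(x$wavelength) || max(grid) > max(x$wavelength))
    stop("resample_spectrum: target grid extends beyond the spectrum's range",
         call. = FALSE)
  int <- approx(x$wavelength, x$intensity, xout = grid)$y
  spectrum(grid, int, x$condition_kind, x$condition_value, x$spot, x$meta,
           axis = x$axis)
}
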