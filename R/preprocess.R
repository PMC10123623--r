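#' Low-pass smooth a spectrum with an FFT filter
#'
#' Discrete-Fourier-transforms the intensities, zeroes every frequency
#' component above `cutoff_fraction` of the Nyquist frequency, and inverse
#' transforms. Used for display only (as in presentation figures); fits and
#' GP are computed on unsmoothed data unless explicitly configured otherwise.
#'
#' @param x A [spectrum] on a uniform grid with at least 8 points.
#' @param cutoff_fraction Fraction of the Nyquist frequency to retain, in
#'   (0, 1]. Default 0.1.
#' @return The smoothed `spectrum`.
#' @export
fft_smooth <- function(x, cutoff_fraction = 0.1) {
  stopifnot(inherits(x, "spectrum"))
  n <- length(x$wavelength)
  if (n < 8) stop("fft_smooth: need at least 8 points", call. = FALSE)
  steps <- diff(x$wavelength)
  if (max(steps) - min(steps) > 1e-8 * mean(steps))
    stop("fft_smooth: grid is not uniform; resample_spectrum() to a uniform grid first",
         call. = FALSE)
  if (!is.numeric(cutoff_fraction) || length(cutoff_fraction) != 1L ||
      cutoff_fraction <= 0 || cutoff_fraction > 1)
    stop("fft_smooth: cutoff_fraction must lie in (0, 1]", call. = FALSE)
  co <- fft(x$intensity)
  k <- seq_len(n) - 1L               # DFT bin indices 0..n-1
  kfold <- pmin(k, n - k)            # distance from DC; Nyquist at n/2
  co[kfold > cutoff_fraction * (n / 2)] <- 0+0i
  sm <- Re(fft(co, inverse = TRUE)) / n
  out <- x
  out$intensity <- pmax(sm, 0)       # ringing can dip microscopically below 0
  validate_spectrum(out)
  out
}

#' Normalize a spectrum to unit peak intensity
#'
#' @param x A [spectrum] with a positive maximum intensity.
#' @return The `spectrum` scaled so `max(intensity) == 1`.
#' @export
normalize_max <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  m <- max(x$intensity)
  if (m <= 0) stop("normalize_max: spectrum has no positive intensity", call. = FALSE)
  x$intensity <- x$intensity / m
  x
}

#' Average replicate (spot) spectra of one condition
#'
#' Computes the unweighted pointwise mean over the replicate spectra of one
#' condition, the input expected by the spectral fits (which in this workflow
#' operate on spectra averaged from at least five spots).
#'
#' @param set A [spectrum_set].
#' @param condition Numeric condition value present in `set`.
#' @param min_spots Minimum number of replicates required. Default 5.
#' @return A `spectrum` tagged with the condition and `spot = "mean"`.
#' @export
average_spots <- function(set, condition, min_spots = 5) {
  stopifnot(inherits(set, "spectrum_set"))
  reps <- condition_spectra(set, condition)
  if (length(reps) < min_spots)
    stop(sprintf("average_spots: condition %s has %d < %d replicates",
                 format(condition), length(reps), min_spots), call. = FALSE)
  mat <- vapply(reps, `[[`, numeric(length(reps[[1L]]$wavelength)), "intensity")
  spectrum(reps[[1L]]$wavelength, rowMeans(mat),
           set$condition_kind, condition, spot = "mean",
           meta = list(n_spots = length(reps)), axis = reps[[1L]]$axis)
}
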