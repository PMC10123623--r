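# Shared fixtures: all synthetic, built in code.

default_grid <- seq(380, 640, by = 0.4)

# one random valid band inside the given windows
rand_band <- function(nu_m_window, fwhm_range = c(1500, 3500),
                      rho_range = c(0.6, 1.45), i_range = c(0.5, 10)) {
  log_normal_band_hr(
    i_max = runif(1, i_range[1], i_range[2]),
    nu_m = runif(1, nu_m_window[1], nu_m_window[2]),
    H = runif(1, fwhm_range[1], fwhm_range[2]),
    rho = runif(1, rho_range[1], rho_range[2]))
}

# a random two-band model strictly inside the default fit bounds
rand_two_band_model <- function() {
  b <- fit_bounds()
  shrink <- function(w, f = 0.1) w + c(1, -1) * f * diff(w)
  two_band_model(
    rand_band(shrink(b$nu_m_short)),
    rand_band(shrink(b$nu_m_long)))
}

# flat-topped spectrum with chosen window intensities at 440 and 490 nm
two_level_spectrum <- function(i440, i490, grid = seq(400, 600, by = 0.5)) {
  ints <- rep(0, length(grid))
  ints[abs(grid - 440) <= 5] <- i440
  ints[abs(grid - 490) <= 5] <- i490
  spectrum(grid, ints)
}

# small spectrum set: `spots` replicates of given intensity rows
replicate_set <- function(intensities, condition = 1, spots = nrow(intensities),
                          grid = seq_len(ncol(intensities)) + 400,
                          kind = "custom") {
  sp <- lapply(seq_len(spots), function(j)
    spectrum(grid, intensities[j, ], kind, condition, spot = as.character(j)))
  spectrum_set(sp, kind)
}
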