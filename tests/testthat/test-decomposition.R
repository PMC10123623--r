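test_that("r_squared implements the coefficient of determination", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_lt(r_squared(obs, rev(obs)), 0)  # worse than the mean
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  s1 <- spectrum(c(400, 410), c(1, 2))
  s2 <- spectrum(c(400, 411), c(1, 2))
  expect_error(r_squared(s1, s2), "same grid")
})

test_that("initial guess is valid, in-bounds, and lands near true peaks", {
  b <- fit_bounds()
  sim <- generate_spectra(generator_config("dehydration", spots = 1,
                                           noise = FALSE))
  for (cond in c(100, 0)) {
    sp <- condition_spectra(sim$set, cond)[[1]]
    g <- initial_guess(sp)
    expect_lte(band_rho(g$band_short), b$rho[2])
    expect_lte(band_rho(g$band_long), b$rho[2])
    expect_lt(abs(g$band_short$nu_m - 1e7 / 427), 1000)
    expect_lt(abs(g$band_long$nu_m - 1e7 / 475), 1000)
  }
  # a pure single-band input still yields two valid in-bounds starting bands
  lone <- log_normal_band_hr(5, 1e7 / 475, 3000, 1.2)
  grid <- default_grid
  sp1 <- spectrum(grid, eval_band(lone, 1e7 / grid))
  g1 <- initial_guess(sp1)
  expect_s3_class(g1, "two_band_model")
  expect_true(g1$band_short$nu_m >= b$nu_m_short[1] &&
                g1$band_short$nu_m <= b$nu_m_short[2])
  # spectra missing a peak window are rejected
  expect_error(initial_guess(spectrum(seq(460, 600, 0.5), rep(1, 281))),
               "peak windows")
})

test_that("noiseless generator spectra are recovered parameter by parameter", {
  # generator round trip: the noise-free forward model must be inverted
  # exactly, including each band's four primary parameters
  grid <- default_grid
  nu <- 1e7 / grid
  for (preset in c("dehydration", "cholesterol")) {
    tmpl <- preset_templates(preset)
    a_l <- band_area(tmpl$band_long)
    a_s <- band_area(tmpl$band_short)
    for (f in c(0.18, 0.5, 0.79)) {
      mix <- f * eval_band(tmpl$band_long, nu) / a_l +
        (1 - f) * eval_band(tmpl$band_short, nu) / a_s
      sc <- 1e4 / max(mix)
      truth <- two_band_model(
        log_normal_band_hr(sc * (1 - f) / a_s, tmpl$band_short$nu_m,
                           band_fwhm(tmpl$band_short), band_rho(tmpl$band_short)),
        log_normal_band_hr(sc * f / a_l, tmpl$band_long$nu_m,
                           band_fwhm(tmpl$band_long), band_rho(tmpl$band_long)))
      fit <- fit_individual(spectrum(grid, sc * mix))
      expect_true(fit$converged)
      expect_gte(fit$r2, 0.999)
      for (side in c("band_short", "band_long")) {
        tb <- truth[[side]]; fb <- fit$model[[side]]
        expect_equal(fb$i_max, tb$i_max, tolerance = 1e-3)
        expect_equal(fb$nu_m, tb$nu_m, tolerance = 1e-3)
        expect_equal(fb$nu_max, tb$nu_max, tolerance = 1e-3)
        expect_equal(fb$nu_min, tb$nu_min, tolerance = 1e-3)
      }
      # label stability: short band peaks above long band, always
      expect_gt(fit$model$band_short$nu_m, fit$model$band_long$nu_m)
      # analytic fraction conservation
      expect_equal(fit$fraction_long + fit$fraction_short, 100,
                   tolerance = 1e-9)
      expect_equal(fit$fraction_long, 100 * f, tolerance = 1e-3)
    }
  }
})

test_that("degenerate and pathological inputs are flagged or rejected", {
  grid <- seq(400, 600, 0.5)
  expect_error(fit_individual(spectrum(grid, rep(3, length(grid)))),
               "degenerate|constant")
  # zero-iteration fit: R^2 of the data mean is 0 by definition
  sp <- two_level_spectrum(2, 1)
  expect_equal(r_squared(sp$intensity, rep(mean(sp$intensity),
                                           length(sp$intensity))), 0)
})

test_that("bounded least squares agrees with a dense grid search oracle", {
  # one free parameter, three observations; oracle = brute-force grid
  x <- c(0.5, 1, 2)
  y <- c(1.9, 1.4, 0.62)
  resid1 <- function(p) y - 2 * exp(-p * x)
  grid_p <- seq(0.01, 3, by = 1e-4)
  rss <- vapply(grid_p, function(p) sum(resid1(p)^2), 0)
  oracle <- grid_p[which.min(rss)]
  fit <- laurdanspec:::ls_fit(resid1, par = 1, lower = 0.01, upper = 3)
  expect_equal(fit$par, oracle, tolerance = 1e-3)

  # unconstrained optimum outside the box: both methods pin the bound
  resid2 <- function(p) y - p * exp(-x)  # optimum near p = 2.9 unbounded
  best_free <- sum(y * exp(-x)) / sum(exp(-2 * x))
  ub <- best_free - 0.5
  rss2 <- vapply(grid_p, function(p) sum(resid2(p)^2), 0)
  oracle2 <- grid_p[grid_p <= ub][which.min(rss2[grid_p <= ub])]
  fit2 <- laurdanspec:::ls_fit(resid2, par = 1, lower = 0.01, upper = ub)
  expect_equal(fit2$par, oracle2, tolerance = 1e-3)
  expect_equal(fit2$par, ub, tolerance = 1e-6)
})

test_that("fits never violate the asymmetry cap or bound windows", {
  sim <- generate_spectra(generator_config("dehydration", spots = 2,
                                           seed = 9))
  b <- fit_bounds()
  for (sp in sim$set$spectra[seq(1, 22, by = 3)]) {
    fit <- fit_individual(sp)
    for (side in c("band_short", "band_long")) {
      expect_lte(band_rho(fit$model[[side]]), b$rho[2] + 1e-9)
      expect_gte(band_rho(fit$model[[side]]), b$rho[1] - 1e-9)
      expect_lte(band_fwhm(fit$model[[side]]), b$fwhm[2] + 1e-6)
    }
    expect_true(fit$model$band_short$nu_m >= b$nu_m_short[1] - 1e-6)
    expect_true(fit$model$band_long$nu_m <= b$nu_m_long[2] + 1e-6)
  }
})

test_that("noisy spectra recover peak positions and fractions within spec", {
  # 20 conditions, 10 spots each at 1% additive noise, analysed the way
  # the pipeline does: spot-averaged individual fits for peak positions,
  # global fit (shared peaks) for the fraction trajectory. The full
  # 100-condition check runs in the acceptance suite.
  tmpl <- preset_templates("dehydration")
  n_cond <- 20
  set.seed(17)
  fracs <- runif(n_cond, 0.18, 0.79)
  cfg <- generator_config("custom", conditions = seq_len(n_cond),
                          band_long = tmpl$band_long,
                          band_short = tmpl$band_short,
                          fraction_long = fracs, spots = 10,
                          noise = TRUE, seed = 99)
  sim <- generate_spectra(cfg)
  fits <- lapply(seq_len(n_cond), function(i)
    fit_individual(average_spots(sim$set, i, min_spots = 10)))
  nm_s <- vapply(fits, function(f) f$model$band_short$nu_m, 0)
  nm_l <- vapply(fits, function(f) f$model$band_long$nu_m, 0)
  expect_lt(abs(mean(nm_s) - tmpl$band_short$nu_m), 30)
  expect_lt(abs(mean(nm_l) - tmpl$band_long$nu_m), 30)

  gf <- fit_global(sim$set, min_spots = 10)
  expect_lt(abs(gf$nu_m_short - tmpl$band_short$nu_m), 20)
  expect_lt(abs(gf$nu_m_long - tmpl$band_long$nu_m), 20)
  expect_lt(sqrt(mean((gf$fractions$fraction_long - 100 * fracs)^2)), 2)
})

test_that("global fit shares peak positions and matches individual fits", {
  sim <- generate_spectra(generator_config("dehydration", spots = 1,
                                           noise = FALSE))
  # single-condition reduction: shared peaks equal the individual fit's
  one <- spectrum_set(condition_spectra(sim$set, 60), "hydration")
  gi <- fit_individual(one$spectra[[1]])
  gg <- fit_global(one)
  expect_equal(gg$nu_m_short, gi$model$band_short$nu_m, tolerance = 1e-5)
  expect_equal(gg$nu_m_long, gi$model$band_long$nu_m, tolerance = 1e-5)

  # full series generated with truly shared peaks
  gf <- fit_global(sim$set)
  expect_true(gf$converged)
  expect_lt(abs(gf$nu_m_short - 1e7 / 427), 20)
  expect_lt(abs(gf$nu_m_long - 1e7 / 475), 20)
  # every per-condition model carries exactly the shared peaks
  for (f in gf$fits) {
    expect_equal(f$model$band_short$nu_m, gf$nu_m_short)
    expect_equal(f$model$band_long$nu_m, gf$nu_m_long)
  }
  # per-condition quality does not collapse relative to individual fits
  ind_r2 <- vapply(gf$individual_fits, `[[`, 0, "r2")
  expect_true(all(gf$r2 >= ind_r2 - 0.005))
  # fraction trajectory from the global fit tracks the generator's truth
  expect_equal(gf$fractions$fraction_long,
               100 * sim$truth$fractions$fraction_long, tolerance = 1e-3)
})

test_that("population fractions respect boundary cases", {
  short <- log_normal_band_hr(2, 1e7 / 427, 2380, 1.2)
  long <- log_normal_band_hr(2 * band_area(short) /
                               band_area(log_normal_band_hr(2, 1e7 / 475, 2380, 1.2)),
                             1e7 / 475, 2380, 1.2)
  # equal-area construction: areas match, so the split is 50/50
  expect_equal(band_area(long), band_area(short), tolerance = 1e-12)
  grid <- default_grid
  fit <- fit_individual(model_spectrum(two_band_model(short, long), grid))
  expect_equal(fit$fraction_long, 50, tolerance = 0.1)

  # near-zero short band: all area in the long band
  tiny_short <- log_normal_band_hr(1e-9, 1e7 / 427, 2380, 1.2)
  fit2 <- fit_individual(model_spectrum(two_band_model(tiny_short,
                                                       log_normal_band_hr(3, 1e7 / 475, 3000, 1.2)),
                                        grid))
  expect_gte(fit2$fraction_long, 99)
  df <- population_fractions(fit2)
  expect_equal(df$fraction_long + df$fraction_short, 100)
})
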