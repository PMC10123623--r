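test_that("preset fraction trajectories hit their documented anchors", {
  # dehydration: 0.79 at bulk, plateau of 0.18 at and below 20% RH
  expect_equal(fraction_trajectory("dehydration", 100), 0.79)
  expect_equal(fraction_trajectory("dehydration", 20), 0.18)
  expect_equal(fraction_trajectory("dehydration", 10),
               fraction_trajectory("dehydration", 0))
  dh <- fraction_trajectory("dehydration", c(100, 95, 80, 50, 20, 10, 0))
  expect_true(all(diff(dh) <= 0))  # monotone non-increasing

  # cholesterol: shallower monotone decline to the calibrated endpoint
  ch <- fraction_trajectory("cholesterol", c(0, 0.1, 0.3, 0.6))
  expect_equal(ch[1], 0.79)
  expect_equal(ch[4], 0.32)
  expect_true(all(diff(ch) < 0))

  # phase-separated L_d: plateau between 50 and 20% RH, then slight decline
  ps <- fraction_trajectory("phase_separated_ld", c(100, 80, 50, 40, 30, 20, 10, 0))
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps[3], ps[6])          # flat across 50-20
  expect_lt(ps[8], ps[6])             # resumes below 20

  for (p in c("dehydration", "phase_separated_ld"))
    expect_true(all(fraction_trajectory(p, c(0, 100)) >= 0 &
                      fraction_trajectory(p, c(0, 100)) <= 1))
  expect_error(fraction_trajectory("nope", 1), "unknown preset")
  expect_error(fraction_trajectory("cholesterol", 0.9), "out of range")
})

test_that("generation is deterministic in the seed and leaves the RNG alone", {
  cfg <- generator_config("dehydration", spots = 3, seed = 7)
  a <- generate_spectra(cfg)
  set.seed(123)
  before <- .Random.seed
  b <- generate_spectra(cfg)
  expect_identical(before, .Random.seed)  # global RNG state restored
  expect_identical(a$set, b$set)
  c2 <- generate_spectra(generator_config("dehydration", spots = 3, seed = 8))
  expect_false(identical(a$set, c2$set))
})

test_that("generated sets carry the documented structure", {
  sim <- generate_spectra(generator_config("dehydration", spots = 2, seed = 1))
  expect_equal(sim$set$conditions, c(100, 95, 80, 70, 60, 50, 40, 30, 20, 10, 0))
  expect_length(sim$set, 22L)
  expect_equal(sim$set$condition_kind, "hydration")
  ch <- generate_spectra(generator_config("cholesterol", spots = 1, seed = 1))
  expect_equal(ch$set$conditions, c(0, 0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 0.6))
  # all intensities nonnegative despite additive noise (truncation)
  expect_true(all(vapply(sim$set$spectra,
                         function(s) all(s$intensity >= 0), TRUE)))
})

test_that("truth record stores every generating parameter exactly", {
  cfg <- generator_config("cholesterol", spots = 4, seed = 31,
                          noise_additive = 0.02, noise_brightness = 0.07)
  sim <- generate_spectra(cfg)
  tr <- sim$truth
  expect_equal(tr$fractions$fraction_long,
               fraction_trajectory("cholesterol", cfg$conditions))
  expect_identical(tr$band_long, cfg$band_long)
  expect_identical(tr$band_short, cfg$band_short)
  expect_equal(tr$seed, 31L)
  expect_equal(tr$spots, 4L)
  expect_equal(tr$noise_additive, 0.02)
  expect_equal(tr$noise_brightness, 0.07)
  expect_equal(tr$grid_range, range(cfg$grid))
})

test_that("the generator's mixing fraction is an exact area fraction", {
  # noise off: decomposition must return the generator's fraction_long
  # within 0.5 percentage points at every condition
  sim <- generate_spectra(generator_config("dehydration", spots = 1,
                                           noise = FALSE))
  for (i in seq_along(sim$set$conditions)) {
    cond <- sim$set$conditions[i]
    fit <- fit_individual(condition_spectra(sim$set, cond)[[1]])
    expect_lt(abs(fit$fraction_long -
                    100 * sim$truth$fractions$fraction_long[i]), 0.5)
  }
  # pure long band edge case
  tmpl <- preset_templates("dehydration")
  pure <- generate_spectra(generator_config(
    "custom", conditions = 1, band_long = tmpl$band_long,
    band_short = tmpl$band_short, fraction_long = 1, spots = 1,
    noise = FALSE))
  f1 <- fit_individual(pure$set$spectra[[1]])
  expect_gte(f1$fraction_long, 99)
})

test_that("configuration contracts are enforced", {
  tmpl <- preset_templates("dehydration")
  expect_error(generator_config("custom", conditions = 1:3), "custom preset")
  expect_error(generator_config("custom", conditions = 1:2,
                                band_long = tmpl$band_long,
                                band_short = tmpl$band_short,
                                fraction_long = c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(generator_config("custom", conditions = 1,
                                band_long = tmpl$band_short,
                                band_short = tmpl$band_long,
                                fraction_long = 0.5), "higher wavenumber")
  # grid too narrow to hold both bands' support above 1% of peak
  cfg <- generator_config("dehydration", grid = seq(440, 520, 0.4))
  expect_error(generate_spectra(cfg), "support")
})
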