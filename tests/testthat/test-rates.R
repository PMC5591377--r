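test_that("gross photosynthesis is net plus dark respiration", {
  expect_equal(gross_photosynthesis(13, 19), 32)
  expect_equal(gross_photosynthesis(31, 19), 50)
  expect_equal(gross_photosynthesis(0, 7), 7)
  expect_equal(gross_photosynthesis(4.8, 6.8), 11.6)  # volumetric inputs too
  expect_error(gross_photosynthesis(13, -1), "magnitude")
})

test_that("carbon fixation converts gross O2 through the photosynthetic quotient", {
  expect_equal(carbon_fixation(32, 1.2), 320.3, tolerance = 1e-3)
  expect_equal(carbon_fixation(0, 1.2), 0)
  expect_equal(carbon_fixation(50, 1.2), 500.5, tolerance = 1e-3)
  expect_error(carbon_fixation(-1), ">= 0")
  expect_error(carbon_fixation(10, 0), "positive")
})

test_that("respiration-to-gross ratio matches the reported budget", {
  expect_equal(resp_to_gross_ratio(19, 50), 0.38)
  expect_equal(resp_to_gross_ratio(7, 7), 1)
  expect_equal(resp_to_gross_ratio(19, 32), 0.594, tolerance = 1e-3)
  expect_error(resp_to_gross_ratio(19, 0), "positive")
})

test_that("a constant trace gives a zero light-dark shift rate", {
  tr <- o2_trace(0:60, rep(480, 61), dark_onset_s = 10)
  expect_equal(light_dark_shift_rate(tr), 0)
})

test_that("the shift estimator recovers the generating local gross within 5%", {
  spec <- sphere_scenario(noise_sd = 0)
  sched <- light_schedule(c(0, 60), c(60, 240), c(4.8, -6.8))
  tr <- generate_ld_trace(spec, sched)
  truth <- 4.8 + 6.8  # local gross: production stops, respiration continues
  est <- light_dark_shift_rate(tr)
  expect_equal(est, truth, tolerance = 0.05)
  # longer windows are biased low by diffusive resupply
  est_long <- light_dark_shift_rate(tr, window_s = c(2, 60))
  expect_lt(est_long, est)
})

test_that("shift windows outside the trace raise an error", {
  tr <- o2_trace(0:30, rep(480, 31), dark_onset_s = 25)
  expect_error(light_dark_shift_rate(tr, window_s = c(10, 40)),
               "fewer than 3")
  expect_error(light_dark_shift_rate(o2_trace(0:30, rep(480, 31))),
               "dark onset")
})

test_that("the assembled rate table reproduces the reported budget within rounding", {
  spec <- study_scenario(noise_sd = 0)
  dark <- generate_profile(spec, 0)
  lights <- list(generate_profile(spec, 170), generate_profile(spec, 320))
  tab <- build_rate_table(dark, lights, spec$geometry, spec$medium, spec$model)
  expect_s3_class(tab, "rate_table")
  expect_equal(tab$light_ue, c(0, 170, 320))
  expect_equal(round(tab$dark_resp_nmol_h[1]), 19)
  expect_equal(tab$vol_dark_resp_umol_cm3_h[1], 6.8, tolerance = 0.02)
  expect_equal(round(tab$net_nmol_h[2:3]), c(13, 31))
  expect_equal(tab$vol_net_umol_cm3_h[2:3], c(4.8, 11), tolerance = 0.02)
  expect_equal(round(tab$gross_nmol_h[2:3]), c(32, 50))
  expect_equal(tab$vol_gross_umol_cm3_h[2:3], c(11.6, 18), tolerance = 0.03)
  expect_equal(tab$carbon_fix_ng_h[2:3], c(320, 500), tolerance = 0.03)
  # internal identities hold exactly in unrounded arithmetic
  expect_equal(tab$gross_nmol_h[2:3],
               tab$net_nmol_h[2:3] + tab$dark_resp_nmol_h[1])
  expect_equal(tab$vol_gross_umol_cm3_h,
               tab$gross_nmol_h / spec$geometry$volume_mm3)
  expect_equal(tab$carbon_fix_ng_h[2:3],
               tab$gross_nmol_h[2:3] / 1.2 * 12.011)
})

test_that("a missing dark profile yields a flagged partial table", {
  spec <- study_scenario(noise_sd = 0)
  lights <- list(generate_profile(spec, 170))
  expect_warning(
    tab <- build_rate_table(NULL, lights, spec$geometry, spec$medium,
                            spec$model),
    "partial")
  expect_true(is.na(tab$gross_nmol_h[2]))
  expect_false(is.na(tab$net_nmol_h[2]))
})

test_that("end-to-end synthetic recovery stays within 5% per cell", {
  spec <- study_scenario(noise_sd = 2, seed = 11)
  dark <- generate_profile(spec, 0)
  lights <- list(generate_profile(spec, 170), generate_profile(spec, 320))
  tab <- build_rate_table(dark, lights, spec$geometry, spec$medium, spec$model)
  expect_equal(tab$dark_resp_nmol_h[1], 19.04, tolerance = 0.05)
  expect_equal(tab$net_nmol_h[2:3], c(13.44, 30.8), tolerance = 0.05)
  expect_equal(tab$gross_nmol_h[2:3], c(32.48, 49.84), tolerance = 0.05)
})
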