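test_that("profile CSV writing and reading round-trip bit-identically", {
  spec <- study_scenario(noise_sd = 2, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  prof <- generate_profile(spec, 170, path = path)
  back <- read_profile(path)
  expect_equal(back$data, prof$data)
  expect_equal(back$surface_depth_um, prof$surface_depth_um)
  expect_equal(back$light_ue, 170)
  expect_equal(back$temperature_c, 24)
  # second write of the same generated profile is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_profile(generate_profile(spec, 170), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed profiles are rejected with the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# surface_depth_um=100", "depth_um,o2_umol_l",
               "0,210", "50,oops", "100,205"), path)
  expect_error(read_profile(path), "row 2")
  writeLines(c("# surface_depth_um=100", "depth_um,o2_umol_l",
               "0,210", "50,208", "50,205", "100,200"), path)
  expect_error(read_profile(path), "increasing")
  writeLines(c("depth_um,o2_umol_l", "0,210", "50,208"), path)
  expect_error(read_profile(path), "surface_depth_um")
  writeLines(c("# surface_depth_um=9000", "depth_um,o2_umol_l",
               "0,210", "50,208", "100,200"), path)
  expect_error(read_profile(path), "outside")
})

test_that("trace CSV round-trips with its dark onset", {
  tr <- o2_trace(0:20, 500 - 3 * (0:20), dark_onset_s = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$data, tr$data)
  expect_equal(back$dark_onset_s, 5)
})

test_that("a flat external profile yields zero flux", {
  prof <- radial_profile(seq(0, 3000, 50), rep(210, 61),
                         surface_depth_um = 2000)
  f <- whole_aggregate_flux(prof, sphere_geometry(), study_medium())
  expect_equal(f$flux_nmol_h, 0)
})

test_that("too few external points raise an estimation error", {
  prof <- radial_profile(c(1900, 1950, 2000, 2100), c(200, 195, 190, 100),
                         surface_depth_um = 2000)
  expect_error(whole_aggregate_flux(prof, sphere_geometry(), study_medium()),
               "external points")
})

test_that("the radial flux estimator recovers noise-free generating totals within 2%", {
  spec <- study_scenario(noise_sd = 0)
  truths <- c("0" = -19.04, "170" = 13.44, "320" = 30.8)
  printed <- c("0" = -19, "170" = 13, "320" = 31)
  for (lvl in names(truths)) {
    prof <- generate_profile(spec, as.numeric(lvl))
    f <- whole_aggregate_flux(prof, spec$geometry, spec$medium)
    expect_equal(f$flux_nmol_h, truths[[lvl]], tolerance = 0.02)
    expect_equal(round(f$flux_nmol_h), printed[[lvl]])
  }
})

test_that("flux sign follows the profile shape: uptake negative, efflux positive", {
  spec <- study_scenario(noise_sd = 0)
  dark <- generate_profile(spec, 0)
  lit <- generate_profile(spec, 320)
  expect_lt(whole_aggregate_flux(dark, spec$geometry, spec$medium)$flux_nmol_h, 0)
  expect_gt(whole_aggregate_flux(lit, spec$geometry, spec$medium)$flux_nmol_h, 0)
  # O2 rises away from a respiring aggregate and falls away from a producing one
  h <- dark$surface_depth_um - dark$data$depth_um
  ext <- h > 0 & h <= 1000
  expect_gt(stats::cor(h[ext], dark$data$o2_umol_l[ext]), 0)
  expect_lt(stats::cor(h[ext], lit$data$o2_umol_l[ext]), 0)
})

test_that("noisy replicate fluxes are unbiased and their CIs cover the truth", {
  truth <- 13.44
  est <- se_cover <- numeric(30)
  for (s in 1:30) {
    sp <- study_scenario(noise_sd = 2, seed = s)
    f <- whole_aggregate_flux(generate_profile(sp, 170), sp$geometry, sp$medium)
    est[s] <- f$flux_nmol_h
    se_cover[s] <- f$ci_nmol_h[1] <= truth && truth <= f$ci_nmol_h[2]
  }
  expect_equal(mean(est), truth, tolerance = 0.05)
  expect_gte(mean(se_cover), 0.9)
})

test_that("the planar Fick estimator runs and keeps the uptake sign", {
  spec <- study_scenario(noise_sd = 0)
  dark <- generate_profile(spec, 0)
  f <- whole_aggregate_flux(dark, spec$geometry, spec$medium,
                            method = "planar", window_um = c(50, 300))
  expect_lt(f$flux_nmol_h, 0)
  # planar geometry understates the spherical supply; same order of magnitude
  expect_gt(abs(f$flux_nmol_h), 5)
  expect_lt(abs(f$flux_nmol_h), 19.04)
})
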