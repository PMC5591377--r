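test_that("zero reaction gives a uniform profile at the ambient concentration", {
  sol <- solve_steady(sphere_geometry(), 0, study_medium())
  expect_equal(sol$profile$o2_umol_l,
               rep(study_medium()$c_sat, nrow(sol$profile)))
  expect_false(sol$core_anoxic)
  expect_equal(core_concentration(sol), study_medium()$c_sat)
})

test_that("the critical respiration rate zeroes the core concentration exactly", {
  for (dbl in c(Inf, 500)) {
    mod <- model_params(dbl_um = dbl)
    qc <- critical_respiration(sphere_geometry(), study_medium(), mod)
    sol <- solve_steady(sphere_geometry(), -qc, study_medium(), mod)
    expect_equal(core_concentration(sol), 0, tolerance = 1e-9)
    expect_false(sol$core_anoxic)
  }
})

test_that("numerical surface flux balances the total reaction (default geometry)", {
  med <- study_medium()
  for (q in c(-2, 3.5)) {
    sol <- solve_steady(sphere_geometry(), q, med, n = 2000)
    R <- sphere_geometry()$radius_cm
    pr <- sol$profile
    # radial flux by numerical differentiation just inside the surface must
    # equal the reaction enclosed within that radius
    i_in <- which(pr$radius_cm <= R)
    i2 <- i_in[length(i_in)]
    r_mid <- mean(pr$radius_cm[c(i2 - 1, i2)])
    dcdr <- diff(pr$o2_umol_l[c(i2 - 1, i2)]) / diff(pr$radius_cm[c(i2 - 1, i2)])
    d_theta_h <- 0.95 * med$d_w * 3600
    efflux <- -4 * pi * r_mid^2 * d_theta_h * dcdr       # nmol/h outward
    enclosed <- q * 4 / 3 * pi * r_mid^3 * 1000          # nmol/h within r_mid
    expect_equal(efflux, enclosed, tolerance = 1e-3)
  }
})

test_that("the solution is linear in the reaction rate", {
  med <- study_medium()
  base <- solve_steady(sphere_geometry(), 1.5, med)$profile$o2_umol_l
  for (a in c(0.5, 2)) {
    scaled <- solve_steady(sphere_geometry(), a * 1.5, med)$profile$o2_umol_l
    expect_equal(scaled - med$c_sat, a * (base - med$c_sat), tolerance = 1e-9)
  }
})

test_that("finite boundary layers converge to the stagnant and Dirichlet limits", {
  med <- study_medium()
  g <- sphere_geometry()
  r <- seq(0, 0.085, length.out = 50)
  stag <- berryflux:::.steady_o2(r, g, 3, med, model_params())
  wide <- berryflux:::.steady_o2(r, g, 3, med, model_params(dbl_um = 1e7))
  expect_equal(wide, stag, tolerance = 1e-4)
  thin <- berryflux:::.steady_o2(0.085, g, 3, med, model_params(dbl_um = 1e-3))
  expect_equal(thin, med$c_sat, tolerance = 1e-4)
})

test_that("critical respiration scales as the closed form predicts", {
  med <- study_medium()
  g <- sphere_geometry()
  qc <- critical_respiration(g, med)
  # linear in the ambient concentration
  med2 <- medium_properties(24, 35, c_sat = 2 * med$c_sat)
  expect_equal(critical_respiration(g, med2), 2 * qc, tolerance = 1e-12)
  med0 <- medium_properties(24, 35, c_sat = 1e-12)
  expect_lt(critical_respiration(g, med0), 1e-10)
  # doubling the radius quarters the threshold
  g2 <- aggregate_geometry(3.4)
  expect_equal(critical_respiration(g2, med), qc / 4, tolerance = 1e-12)
  # increasing D_w, theta, or shrinking the DBL raises it
  med_hot <- medium_properties(27, 35, c_sat = med$c_sat)
  expect_gt(critical_respiration(g, med_hot), qc)
  expect_gt(critical_respiration(g, med, model_params(theta = 1)), qc)
  expect_gt(critical_respiration(g, med, model_params(dbl_um = 300)), qc)
})

test_that("supersaturation and anoxia flags follow the reaction sign", {
  med <- study_medium()
  sol_p <- solve_steady(sphere_geometry(), 11, med)
  expect_gt(core_concentration(sol_p), med$c_sat)
  # uniform production at the 320 uE volumetric rate: core excess ~516 umol/L
  expect_equal(core_concentration(sol_p) - med$c_sat, 516.4, tolerance = 1e-3)
  expect_warning(
    sol_n <- solve_steady(study_geometry(), -6.8, med),
    "anoxic")
  expect_true(sol_n$core_anoxic)
  expect_true(all(sol_n$profile$o2_umol_l >= 0))
  expect_equal(core_concentration(sol_n), 0)
})
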