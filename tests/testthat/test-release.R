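test_that("sampling-replacement correction follows the running-sum formula", {
  p <- release_profile(times = c(1, 2), concentrations = c(10, 10),
                       volume = 50, sample_volume = 1, area = 1.33, dose = 1e6)
  cr <- cumulative_release(p)
  expect_equal(cr$concentration_corrected, c(10, 10.2))
  expect_equal(cr$cumulative_mg, c(500, 510))

  # V_s = 0: correction vanishes entirely
  p0 <- release_profile(1:6, c(1, 2, 3, 4, 5, 6) / 10, sample_volume = 0,
                        dose = 100)
  expect_equal(cumulative_release(p0)$cumulative_mg, (1:6) / 10 * 50)

  expect_error(release_profile(1:3, c(1, -2, 3)), "negative concentration")
  expect_error(release_profile(c(0, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(release_profile(1:3, c(3, 2, 1), volume = 1, sample_volume = 2),
               "volume")
})

test_that("corrected cumulative release inverts the withdrawal simulation exactly", {
  for (vs in c(0, 1, 2.5)) {
    prof <- simulate_release(k = 0.45, Qinf = 8, times = 1:6, sample_volume = vs,
                             noise_cv = 0, shape = 1)
    cr <- cumulative_release(prof)
    expect_equal(cr$cumulative_mg, attr(prof, "true_release")$released_mg,
                 tolerance = 1e-12)
  }
})

test_that("release flux is cumulative-at-end per area, linear in concentration, dose-bounded", {
  prof <- simulate_release(k = 0.4, Qinf = 2.1, noise_cv = 0, shape = 1)
  cr <- cumulative_release(prof)
  expect_equal(release_flux(prof), cr$cumulative_mg[6] / 1.33)

  # 1.9152 mg over 1.33 cm2 -> 1.44 mg/cm2
  k <- solve_release_rate(1.44, Qinf = 2.2, area = 1.33, t_end = 6)
  prof2 <- simulate_release(k = k, Qinf = 2.2, noise_cv = 0, shape = 1)
  expect_equal(release_flux(prof2), 1.44, tolerance = 1e-9)

  # linearity in concentrations
  p1 <- release_profile(1:4, c(0.1, 0.2, 0.25, 0.28), dose = 100)
  p3 <- release_profile(1:4, 3 * c(0.1, 0.2, 0.25, 0.28), dose = 100)
  expect_equal(release_flux(p3), 3 * release_flux(p1))
  expect_equal(release_flux(release_profile(1:3, c(0, 0, 0))), 0)

  # mass conservation across many simulated settings
  for (s in 1:25) {
    prof <- simulate_release(k = 0.3 + 0.05 * s %% 5, Qinf = 1 + 0.3 * s,
                             dose = 10, noise_cv = 0.05, shape = 0.72, seed = s)
    cum <- suppressWarnings(cumulative_release(prof))
    expect_lte(max(cum$cumulative_mg), 10 * (1 + 0.2))  # dose + noise headroom
    expect_lte(release_flux(prof), 10 / 1.33 * 1.2)
  }
})

test_that("slope-based flux is available behind the method flag", {
  p <- release_profile(1:4, c(0.1, 0.2, 0.3, 0.4), sample_volume = 0, dose = 100)
  # exactly linear cumulative: slope = 5 mg/h over 1.33 cm2
  expect_equal(release_flux(p, method = "slope"), 5 / 1.33)
})

test_that("first-order fitting round-trips noiseless data and beats wrong models", {
  t <- 1:6
  q <- 8 * (1 - exp(-0.5 * t))
  f <- fit_kinetics(t, q, dose = 10, model = "first_order")
  expect_equal(f$Qinf, 8, tolerance = 1e-6)
  expect_equal(f$k, 0.5, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  # agrees with the log-linearized route at known Qinf
  expect_equal(loglinear_first_order_k(t, q, 8), 0.5, tolerance = 1e-9)

  lin <- 0.8 * t
  expect_equal(fit_kinetics(t, lin, dose = 10, "zero_order")$r2, 1)
  expect_lt(fit_kinetics(t, lin, dose = 10, "first_order")$r2, 1)
  hig <- 2 * sqrt(t)
  expect_equal(fit_kinetics(t, hig, dose = 100, "higuchi")$r2, 1, tolerance = 1e-12)

  expect_error(fit_kinetics(1:2, c(1, 2), dose = 10), "3 time points")
  expect_error(fit_kinetics(t, q * 10, dose = 10), "exceeds the dose")
})

test_that("calibrated noisy simulations keep first-order r2 in the reported range", {
  r2 <- vapply(1:100, function(s) {
    prof <- simulate_release(k = 0.4, Qinf = 2.17, shape = 0.72,
                             noise_cv = 0.01, seed = s)
    cum <- suppressWarnings(cumulative_release(prof))
    fit_kinetics(cum$time_h, cum$cumulative_mg, dose = 10, "first_order")$r2
  }, numeric(1))
  expect_gte(mean(r2 >= 0.9615 & r2 <= 0.9908), 0.90)
})
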