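# Baseline correction and the two-pass Hertz fit on single curves.

test_that("virtual-deflection correction recovers the injected slope", {
  for (s in c(0, 0.05, -0.08)) {
    fc <- noiseless_curve(slope = s)
    cor <- correct_virtual_deflection(fc)
    expect_equal(cor$baseline$slope, s, tolerance = 1e-8)
    pre <- cor$z < fc$truth$z0
    expect_true(all(abs(cor$force[pre]) < 1e-6))
    expect_identical(cor$baseline$status, "ok")
  }
  # noisy slope recovery within 1%
  fc <- simulate_force_curve(1e4, Inf, baseline_slope = 0.5, noise_sd = 3,
                             n_points = 2048, seed = 3)
  cor <- correct_virtual_deflection(fc)
  expect_equal(cor$baseline$slope, 0.5, tolerance = 0.01)
})

test_that("baseline window overlapping contact is flagged no_baseline", {
  fc <- noiseless_curve()
  # shift the window deep into the contact branch
  cor <- correct_virtual_deflection(fc, baseline_fraction = 0.9)
  expect_identical(cor$baseline$status, "no_baseline")
  expect_identical(fit_hertz_linearized(cor)$status, "no_baseline")
})

test_that("degenerate flat curve is an input error", {
  fc <- noiseless_curve()
  fc$z <- rep(1, length(fc$z))
  expect_error(correct_virtual_deflection(fc), "zero variance")
})

test_that("linearized fit recovers modulus and contact point exactly when noiseless", {
  for (e in c(1e3, 5e3, 1e4, 5e4)) {
    fc <- noiseless_curve(e_pa = e)
    fit <- fit_hertz_linearized(correct_virtual_deflection(fc))
    expect_identical(fit$status, "ok")
    expect_equal(fit$apparent_modulus, e, tolerance = 0.005)
    expect_lt(abs(fit$contact_point_z0 - fc$truth$z0), 2)
  }
})

test_that("zero-force and pure-noise curves give no_contact", {
  fc <- noiseless_curve()
  fc$force[] <- 0
  expect_identical(fit_hertz_linearized(correct_virtual_deflection(fc))$status,
                   "no_contact")
  fc2 <- noiseless_curve()
  fc2$force <- with(list(), {set.seed(1); rnorm(length(fc2$force), 0, 5)})
  fit2 <- fit_hertz_linearized(correct_virtual_deflection(fc2))
  expect_identical(fit2$status, "no_contact")
})

test_that("force scaling by c scales the fitted modulus by c at fixed z0", {
  fc <- noiseless_curve()
  fit1 <- fit_hertz_linearized(correct_virtual_deflection(fc))
  sc <- fc
  sc$force <- fc$force * 2
  # rescale the probe spring constant too so s = z - F/k is unchanged
  sc$probe <- probe_params(spring_constant = fc$probe$spring_constant * 2,
                           trigger_force = 800)
  fit2 <- fit_hertz_linearized(correct_virtual_deflection(sc))
  expect_equal(fit2$apparent_modulus / fit1$apparent_modulus, 2,
               tolerance = 1e-6)
  expect_equal(fit2$contact_point_z0, fit1$contact_point_z0, tolerance = 0.1)
})

test_that("bottom-effect refit removes the thin-sample bias", {
  fc <- noiseless_curve(e_pa = 1e4, h = 0.5)
  cor <- correct_virtual_deflection(fc)
  pass1 <- fit_hertz_linearized(cor)
  expect_gt(pass1$apparent_modulus, 1.1e4)  # naive fit overestimates
  pass2 <- fit_bottom_effect(cor, h = 0.5, first_pass = pass1)
  expect_identical(pass2$status, "ok")
  expect_equal(pass2$apparent_modulus, 1e4, tolerance = 0.05)
})

test_that("bottom-effect fit at large h agrees with the linearized fit", {
  for (h in c(100, 500, Inf)) {
    fc <- noiseless_curve(e_pa = 8e3, h = h)
    cor <- correct_virtual_deflection(fc)
    p1 <- fit_hertz_linearized(cor)
    p2 <- fit_bottom_effect(cor, h = h, first_pass = p1)
    expect_equal(p2$apparent_modulus, p1$apparent_modulus, tolerance = 0.005)
  }
})

test_that("doubling the true modulus doubles the corrected fit", {
  f1 <- fit_bottom_effect(correct_virtual_deflection(
    noiseless_curve(1e4, h = 1)), h = 1)
  f2 <- fit_bottom_effect(correct_virtual_deflection(
    noiseless_curve(2e4, h = 1)), h = 1)
  expect_equal(f2$apparent_modulus / f1$apparent_modulus, 2, tolerance = 0.01)
})

test_that("pass-1 apparent modulus grows monotonically as the sample thins", {
  hs <- c(Inf, 5, 2, 1, 0.5, 0.3)
  e1 <- vapply(hs, function(h) {
    fit_hertz_linearized(correct_virtual_deflection(
      noiseless_curve(1e4, h = h)))$apparent_modulus
  }, numeric(1))
  expect_true(all(diff(e1) >= -1e-6 * e1[-1]))  # non-decreasing
})

test_that("hertz_fit methods are coherent", {
  fc <- simulate_force_curve(1e4, Inf, noise_sd = 5, seed = 2)
  fit <- fit_hertz_linearized(correct_virtual_deflection(fc))
  expect_named(coef(fit), c("apparent_modulus_pa", "contact_point_z0_nm"))
  expect_length(fitted(fit), fit$n_fit_points)
  expect_equal(sqrt(mean(residuals(fit)^2)), fit$fit_rmse, tolerance = 0.2)
  expect_output(print(fit), "apparent modulus")
  expect_equal(predict(fit, delta = 100),
               hertz_force(100, fit$apparent_modulus, fit$probe))
})
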