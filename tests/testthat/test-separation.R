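test_that("tail fit recovers a pure exponential and a constant exactly", {
  grid <- (0:540) / 12
  cv <- pet_curve(grid, 8 * exp(-0.07 * grid))
  fit <- fit_tail(cv, window = c(5, 45), family = "exp1")
  expect_true(fit$converged)
  expect_equal(unname(fit$coef["a1"]), 8, tolerance = 1e-6)
  expect_equal(unname(fit$coef["b1"]), -0.07, tolerance = 1e-6)

  cst <- pet_curve(grid, rep(4.2, length(grid)))
  cfit <- fit_tail(cst, window = c(5, 45), family = "exp1")
  expect_true(cfit$converged)
  expect_identical(unname(cfit$coef), c(4.2, 0))
})

test_that("extrapolation substitutes the fitted model and extends closed forms", {
  grid <- (0:540) / 12
  cv <- pet_curve(grid, 8 * exp(-0.07 * grid))
  fit <- fit_tail(cv, window = c(5, 45), family = "exp1")
  inside <- extrapolate(fit, c(10, 20, 40))
  expect_equal(inside$values, 8 * exp(-0.07 * c(10, 20, 40)), tolerance = 1e-5)
  out <- extrapolate(fit, 90)
  expect_equal(out$values, fit$coef[["a1"]] * exp(fit$coef[["b1"]] * 90))

  cst <- fit_tail(pet_curve(grid, rep(4.2, length(grid))), c(5, 45), "exp1")
  expect_equal(extrapolate(cst, c(60, 90))$values, c(4.2, 4.2))

  bad <- fit_tail(pet_curve(grid, 8 * exp(-0.07 * grid)),
                  window = c(0, 1), family = "exp1")
  expect_false(bad$converged)
  expect_error(extrapolate(bad, 90), "non-converged")
})

test_that("kinetic refit extrapolates a noiseless TAC within 2% at 60-90 min", {
  # bound reflects the systematic limit of exponential-tail AIF extrapolation
  # under a Hill-type parent-fraction decline (the AIF tail flattens
  # sub-exponentially); see the methods vignette
  dual <- fixture_noiseless_dual(c("HAR", "DASB"), stagger = 45)
  sep <- separate(dual)
  expect_identical(sep$status, "ok")
  truth <- dual$provenance$first
  for (r in ROI_NAMES) {
    ext <- sep$ext_first$tacs[[r]]
    for (tq in c(60, 75, 90)) {
      i <- which(abs(ext$times - tq) < 1e-9)
      expect_lt(abs(ext$values[i] - truth$tacs[[r]]$values[i]) /
                  truth$tacs[[r]]$values[i], 0.02)
    }
  }
})

test_that("subtraction with oracle extrapolation recovers the second tracer", {
  dual <- fixture_noiseless_dual(c("DASB", "HAR"), stagger = 45)
  sep <- separate(dual, separation_config(extrapolation = "oracle"))
  truth <- dual$provenance$second
  k <- round(45 * 12)
  for (r in ROI_NAMES) {
    est <- sep$est_second$tacs[[r]]
    expect_equal(est$values[1:k], rep(0, k))
    late <- (k + 1):length(est$times)
    expect_lt(max(abs(est$values[late] - truth$tacs[[r]]$values[late - k])),
              1e-9)
  }
  expect_identical(sep$est_second$aif$tracer_label, "HAR")
  expect_equal(sep$est_second$aif$injection_time, 45)
})

test_that("attributing everything to the first tracer leaves nothing", {
  dual <- fixture_noiseless_dual(c("HAR", "DASB"), stagger = 45)
  ext <- list(aif = dual$aif, tacs = dual$tacs)
  sep <- estimate_second(dual, ext)
  expect_equal(sep$est_second$aif$values, rep(0, length(dual$aif$times)))
  expect_true(all(vapply(sep$est_second$tacs,
                         function(cv) all(cv$values == 0), logical(1))))
})

test_that("conservation: dual = extrapolated first + estimated second + clip", {
  coh <- fixture_cohort(1)
  cfg <- cohort_config()
  s1 <- generate_single_scan(coh[[1]], "HAR", cfg, seed = 21)
  s2 <- generate_single_scan(coh[[1]], "DASB", cfg, seed = 22)
  dual <- build_dual_measurement(resample_scan(s1), resample_scan(s2),
                                 dual_protocol("HAR", "DASB", 45))
  sep <- separate(dual)
  expect_equal(dual$aif$values,
               sep$ext_first$aif$values + sep$est_second$aif$values +
                 sep$clip$aif)
  for (r in ROI_NAMES) {
    expect_equal(dual$tacs[[r]]$values,
                 sep$ext_first$tacs[[r]]$values +
                   sep$est_second$tacs[[r]]$values + sep$clip[[r]])
  }
  expect_true(all(sep$clipped_integral >= 0))
})

test_that("separation rejects a simultaneous protocol and flags short staggers", {
  d0 <- fixture_noiseless_dual(c("HAR", "DASB"), stagger = 0)
  expect_error(separate(d0), "stagger 0")

  coh <- fixture_cohort(1)
  cfg <- cohort_config()
  s1 <- generate_single_scan(coh[[1]], "DASB", cfg, seed = 31)
  s2 <- generate_single_scan(coh[[1]], "HAR", cfg, seed = 32)
  d15 <- build_dual_measurement(resample_scan(s1), resample_scan(s2),
                                dual_protocol("DASB", "HAR", 15))
  sep <- separate(d15)
  expect_identical(sep$status, "failed_separation")
  expect_s3_class(sep$diagnostics$table, "data.frame")
})
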