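test_that("running integral is exact for constants/linears and tracks quadrature", {
  tt <- seq(0, 10, by = 0.5)
  cst <- cumulative_integral(pet_curve(tt, rep(1, length(tt))))
  expect_equal(cst$values, tt)
  lin <- cumulative_integral(pet_curve(tt, 2 * tt))
  expect_equal(lin$values, tt^2)
  expect_error(cumulative_integral(pet_curve(1, 5)), "2 samples")

  inp <- fixture_input_curve(duration = 90)
  ci <- cumulative_integral(inp)
  # independent oracle: adaptive quadrature of the analytic input function
  # (smooth beyond the appearance delay t0 = 0.5)
  m <- fixture_input_model(); pf <- fixture_pf_model()
  f <- function(t) {
    vapply(t, function(ti) eval_input_function(m, ti)$values, numeric(1)) *
      eval_parent_fraction(pf, t)
  }
  oracle <- integrate(f, 0.5, 90, subdivisions = 2000L, rel.tol = 1e-9)$value
  expect_lt(abs(ci$values[length(ci$values)] - oracle) / oracle, 0.001)
})

test_that("Logan slope is exact for proportional curves and scale-invariant", {
  inp <- resample_uniform(fixture_input_curve(), duration = 90)
  tac <- pet_curve(inp$times, 3.7 * inp$values, kind = "TAC")
  fit <- logan_vt(tac, inp, t_star = 30)
  expect_equal(fit$vt, 3.7, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-7)
  expect_equal(fit$r2_linear, 1, tolerance = 1e-12)

  scaled <- logan_vt(pet_curve(inp$times, 5 * tac$values, kind = "TAC"),
                     pet_curve(inp$times, 5 * inp$values, kind = "input"),
                     t_star = 30)
  expect_equal(scaled$vt, fit$vt, tolerance = 1e-9)
})

test_that("Logan V_T matches the analytic value on noiseless compartment models", {
  inp <- fixture_input_curve(duration = 90)
  m1 <- tissue_model("1TCM", K1 = 0.5, k2 = 0.25)
  tac <- tissue_tac(m1, inp)
  fit <- logan_vt(tac, inp, t_star = 30)
  expect_lt(abs(fit$vt - 2.0) / 2.0, 0.02)

  errs <- vapply(list(fixture_fast_model(), fixture_slow_model()), function(m) {
    f <- logan_vt(tissue_tac(m, inp), inp, t_star = 30)
    (f$vt - analytic_vt(m)) / analytic_vt(m)
  }, numeric(1))
  expect_true(all(abs(errs) < 0.05))
  # finite t* biases Logan V_T downward, visibly so for slow equilibration
  expect_lt(errs[2], 0)
})

test_that("Logan preconditions are enforced", {
  inp <- resample_uniform(fixture_input_curve(), duration = 40)
  tac <- pet_curve(inp$times, 2 * inp$values, kind = "TAC")
  expect_error(logan_vt(tac, inp, t_star = 30), "15 min")
  neg <- pet_curve(inp$times, inp$values - max(inp$values) / 2, kind = "TAC")
  expect_error(logan_vt(neg, inp, t_star = 20), "non-positive")
})

test_that("condition table is complete and collapses correctly when exact", {
  coh <- fixture_cohort(1)
  dual <- fixture_noiseless_dual(c("HAR", "DASB"), subject = coh[[1]])
  sep <- separate(dual, separation_config(extrapolation = "oracle"))
  rs1 <- dual$provenance$first
  rs2 <- dual$provenance$second
  vt <- quantify_conditions(rs1, rs2, sep)

  expect_identical(sort(unique(vt$condition)), c("est", "single45", "single90"))
  expect_equal(nrow(vt), 13 * 5)   # 2 tracers x 2 single conditions + est
  expect_true(all(vt$vt > 0))

  # oracle separation makes the est condition the 45-min single measurement
  est <- vt[vt$condition == "est", ]
  s45 <- vt[vt$condition == "single45" & vt$tracer == "DASB", ]
  m <- merge(est, s45, by = "roi")
  expect_equal(m$vt.x, m$vt.y, tolerance = 1e-6)

  # truncation changes the fast tracer's V_T little on noiseless data
  h45 <- vt[vt$condition == "single45" & vt$tracer == "HAR", ]
  h90 <- vt[vt$condition == "single90" & vt$tracer == "HAR", ]
  mh <- merge(h45, h90, by = "roi")
  expect_true(all(abs(mh$vt.x - mh$vt.y) / mh$vt.y < 0.05))
})
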