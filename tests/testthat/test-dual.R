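test_that("uniform resampling is exact on grid-aligned and linear data", {
  grid <- (0:1080) / 12
  cv <- pet_curve(grid, sin(grid / 10) + 2)
  expect_equal(resample_uniform(cv, duration = 90)$values, cv$values)

  lin <- pet_curve(0:90, 2 * (0:90))
  rs <- resample_uniform(lin, duration = 90)
  expect_equal(rs$values, 2 * rs$times)
  expect_error(resample_uniform(pet_curve(1, 1)), "2 samples")
})

test_that("resampling a framed TAC preserves the trapezoid integral", {
  coh <- fixture_cohort(1)
  scan <- generate_single_scan(coh[[1]], "DASB", cohort_config(), seed = 9)
  framed <- scan$tacs$THA
  rs <- resample_uniform(framed, duration = 90)
  int_frames <- sum(diff(framed$times) *
                      (framed$values[-1] + framed$values[-length(framed$times)]) / 2)
  int_rs <- sum(diff(rs$times) * (rs$values[-1] + rs$values[-length(rs$times)]) / 2)
  # compare on the frames' span (the resampled grid extends it by edge-holding)
  span <- range(framed$times)
  keep <- rs$times >= span[1] & rs$times <= span[2]
  int_rs_span <- sum(diff(rs$times[keep]) *
                       (rs$values[keep][-1] + rs$values[keep][-sum(keep)]) / 2)
  expect_lt(abs(int_rs_span - int_frames) / int_frames, 0.005)
})

test_that("dual summation shifts the second tracer by whole grid nodes", {
  grid <- (0:1080) / 12
  first <- pet_curve(grid, 10 * exp(-0.05 * grid), tracer_label = "A")
  # a TAC-like second curve: zero at its own injection, then uptake/washout
  second <- pet_curve(grid, 5 * (1 - exp(-grid)) * exp(-0.02 * grid),
                      tracer_label = "B")

  p0 <- dual_protocol("A", "B", stagger = 0)
  expect_equal(simulate_dual(first, second, p0)$values,
               first$values + second$values)

  p45 <- dual_protocol("A", "B", stagger = 45)
  zero <- pet_curve(grid, rep(0, length(grid)), tracer_label = "B")
  expect_equal(simulate_dual(first, zero, p45)$values, first$values)

  dual <- simulate_dual(first, second, p45)
  k <- round(45 * 12)
  expect_equal(dual$values[1:k], first$values[1:k])
  expect_equal(dual$values[(k + 1):length(grid)],
               first$values[(k + 1):length(grid)] +
                 second$values[1:(length(grid) - k)])
  # integral additivity on the grid
  tz <- function(t, v) sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
  lhs <- tz(grid, dual$values)
  rhs <- tz(grid, first$values) + tz(grid[grid <= 45 + 1e-9],
                                     second$values[grid <= 45 + 1e-9])
  expect_lt(abs(lhs - rhs) / rhs, 1e-9)
})

test_that("stagger values are restricted to the protocol set", {
  expect_error(dual_protocol("A", "B", stagger = 10), "stagger")
  expect_error(dual_protocol("A", "A", stagger = 45), "distinct")
})

test_that("early window equals the first tracer's truncated measurement", {
  dual <- fixture_noiseless_dual(c("HAR", "DASB"), stagger = 45)
  ew <- early_window(dual)
  first <- dual$provenance$first
  expect_identical(ew$aif$values,
                   first$aif$values[first$aif$times < 45 - 1e-9])
  for (r in ROI_NAMES) {
    expect_identical(ew$tacs[[r]]$values,
                     first$tacs[[r]]$values[first$tacs[[r]]$times < 45 - 1e-9])
  }

  d15 <- fixture_noiseless_dual(c("HAR", "DASB"), stagger = 15)
  expect_length(early_window(d15)$aif$times, 180)

  d0 <- fixture_noiseless_dual(c("HAR", "DASB"), stagger = 0)
  expect_error(early_window(d0), "stagger 0")
})

test_that("dual minus shifted second recovers the first curve exactly", {
  dual <- fixture_noiseless_dual(c("DASB", "HAR"), stagger = 30)
  k <- round(30 * 12)
  for (r in c("THA", "OCC", "CRB")) {
    v <- dual$tacs[[r]]$values
    sec <- dual$provenance$second$tacs[[r]]$values
    v[(k + 1):length(v)] <- v[(k + 1):length(v)] - sec[1:(length(v) - k)]
    expect_lt(max(abs(v - dual$provenance$first$tacs[[r]]$values)), 1e-10)
  }
})
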