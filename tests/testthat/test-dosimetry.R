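test_that("decay arithmetic reproduces the planning numbers", {
  expect_equal(half_lives_elapsed(45, 20), 2.25)
  expect_equal(half_lives_elapsed(20, 20), 1.0)
  expect_equal(half_lives_elapsed(0, 20), 0)

  expect_equal(round(decayed_quantity(100, 45, 20), 1), 21.0)
  expect_equal(decayed_quantity(100, 45, 20), 100 / 2^2.25)
  expect_equal(decayed_quantity(7.3, 0, 20), 7.3)
  expect_equal(decayed_quantity(2.0, 45, 20), 2.0 / 2^2.25)
  expect_equal(round(decayed_quantity(2.0, 45, 20), 4), 0.4204)

  expect_equal(dose_for_weight(4.51, 75), 338.25)
  expect_equal(dose_for_weight(1, 1), 1)
  expect_equal(dose_for_weight(4.66, 75), 349.5)
  expect_error(dose_for_weight(0, 75), "> 0")
})

test_that("decay is multiplicative over consecutive delays and halves exactly", {
  d <- function(t) decayed_quantity(1, t, 20)
  for (ab in list(c(5, 7), c(12, 33), c(0, 45))) {
    expect_equal(d(ab[1] + ab[2]), d(ab[1]) * d(ab[2]), tolerance = 1e-12)
  }
  expect_equal(d(20), 0.5)
  tt <- seq(0, 90, by = 5)
  expect_true(all(diff(decayed_quantity(10, tt, 20)) < 0))
})

test_that("feasibility of the delayed injection is judged against the limits", {
  ok <- feasibility_check(decay_plan(delay = 45), min_molar_activity = 20)
  expect_true(ok$pass)
  expect_equal(round(ok$margin_molar, 0), 1)
  expect_equal(ok$half_lives, 2.25)

  late <- feasibility_check(decay_plan(delay = 60), min_molar_activity = 20)
  expect_false(late$pass)
  expect_equal(late$molar_activity, 12.5)

  # a vacuous molar-activity limit never blocks a sufficiently active batch
  vac <- feasibility_check(decay_plan(delay = 60, activity = 10),
                           min_molar_activity = 0)
  expect_true(vac$pass)
  expect_gte(vac$margin_molar, 0)
})

test_that("physical-decay conversion halves activity after one half-life", {
  cv <- pet_curve(c(0, 20.38, 40.76), c(10, 10, 10))
  out <- apply_physical_decay(cv)
  expect_equal(out$values, c(10, 5, 2.5))
})
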