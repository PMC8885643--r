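test_that("plasma model is zero before appearance and continuous at t0", {
  m <- fixture_input_model()
  cv <- eval_input_function(m, c(0, m$t0 / 2, m$t0, m$t0 + 1e-9, 1, 5, 90))
  expect_identical(cv$kind, "plasma")
  expect_equal(cv$values[1:3], c(0, 0, 0))
  expect_lt(cv$values[4], 1e-5)          # continuity at t0
  expect_true(all(is.finite(cv$values)))
  expect_true(all(cv$values >= 0))

  zero <- input_function_model(A1 = 0, A2 = 0, A3 = 0)
  expect_equal(eval_input_function(zero, seq(0, 90, by = 1))$values,
               rep(0, 91))
})

test_that("plasma model rejects invalid parameters and times", {
  expect_error(input_function_model(A1 = NaN), "finite")
  expect_error(input_function_model(l1 = -0.1, l2 = -4), "l1 < l2")
  expect_error(input_function_model(l3 = 0.1), "l3 <= 0")
  expect_error(eval_input_function(fixture_input_model(), c(-1, 5)), "120")
})

test_that("coarse-grid peak location matches a dense-grid argmax scan", {
  m <- fixture_input_model()
  dense_t <- seq(0, 5, by = 0.001)
  dense <- eval_input_function(m, dense_t)
  t_peak_dense <- dense_t[which.max(dense$values)]
  gen_t <- (0:5400) / 60
  gen <- eval_input_function(m, gen_t)
  t_peak_gen <- gen_t[which.max(gen$values)]
  expect_lt(abs(t_peak_gen - t_peak_dense), 1 / 60 + 1e-9)
  # defaults place the peak about a minute after injection
  expect_gt(t_peak_dense, 0.5)
  expect_lt(t_peak_dense, 1.5)
})

test_that("parent fraction declines from 1 to p_inf with exact midpoint", {
  m <- fixture_pf_model()
  tt <- seq(0, 90, by = 0.25)
  f <- eval_parent_fraction(m, tt)
  expect_equal(f[1], 1)
  expect_true(all(diff(f) <= 1e-12))
  expect_true(all(f >= m$p_inf - 1e-12 & f <= 1 + 1e-12))
  # closed-form Hill midpoint
  expect_equal(eval_parent_fraction(m, m$t50), (1 + m$p_inf) / 2)
  # steep Hill slope approaches a step at t50
  steep <- parent_fraction_model(p_inf = 0.3, t50 = 20, h = 200)
  expect_equal(eval_parent_fraction(steep, 10), 1, tolerance = 1e-6)
  expect_equal(eval_parent_fraction(steep, 40), 0.3, tolerance = 1e-6)
})

test_that("metabolite correction multiplies pointwise and respects grids", {
  tt <- seq(0, 90, by = 1 / 12)
  plasma <- eval_input_function(fixture_input_model(), tt)

  ident <- apply_parent_fraction(plasma, parent_fraction_model(p_inf = 1))
  expect_equal(ident$values, plasma$values)
  expect_identical(ident$kind, "input")

  m <- fixture_pf_model()
  out <- apply_parent_fraction(plasma, m)
  expect_true(all(out$values <= plasma$values + 1e-12))
  expect_equal(out$values[tt == m$t50],
               plasma$values[tt == m$t50] * (1 + m$p_inf) / 2)

  frac_off_grid <- pet_curve(tt[-1], eval_parent_fraction(m, tt[-1]),
                             kind = "parent_fraction")
  expect_error(apply_parent_fraction(plasma, frac_off_grid), "grid")
})
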