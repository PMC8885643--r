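test_that("analytic V_T follows the compartmental identity", {
  expect_equal(analytic_vt(tissue_model("1TCM", K1 = 0.5, k2 = 0.25)), 2.0)
  expect_equal(analytic_vt(tissue_model("2TCM", K1 = 0.5, k2 = 0.25,
                                        k3 = 0.07, k4 = 0.07)), 4.0)
  expect_error(tissue_model("2TCM", K1 = 0.5, k2 = 0), "k2")
  expect_error(tissue_model("2TCM", K1 = 0.5, k2 = 0.2, k3 = 0.1, k4 = 0),
               "k4")
  expect_error(tissue_model("1TCM", K1 = 0.5, k2 = 0.2, k3 = 0.1, k4 = 0.1),
               "1TCM")
})

test_that("no uptake and model nesting limits hold on the simulation grid", {
  inp <- fixture_input_curve(duration = 60)
  zero <- tissue_tac(tissue_model("1TCM", K1 = 0, k2 = 0.1), inp)
  expect_equal(zero$values, rep(0, length(inp$times)))

  one <- tissue_tac(tissue_model("1TCM", K1 = 0.3, k2 = 0.12), inp)
  nested <- tissue_tac(tissue_model("2TCM", K1 = 0.3, k2 = 0.12,
                                    k3 = 0, k4 = 0), inp)
  expect_lt(max(abs(one$values - nested$values)), 1e-9)
})

test_that("property: 2TCM with k3 = 0 reproduces 1TCM across random draws", {
  set.seed(101)
  inp <- fixture_input_curve(duration = 45)
  for (i in 1:10) {
    K1 <- runif(1, 0.1, 0.6)
    k2 <- runif(1, 0.05, 0.4)
    a <- tissue_tac(tissue_model("1TCM", K1 = K1, k2 = k2), inp)
    b <- tissue_tac(tissue_model("2TCM", K1 = K1, k2 = k2, k3 = 0, k4 = 0), inp)
    expect_lt(max(abs(a$values - b$values)), 1e-9)
  }
})

test_that("convolution TAC matches an independent stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  inp <- fixture_input_curve(duration = 90)
  u <- approxfun(inp$times, inp$values, rule = 2)
  for (m in list(fixture_fast_model(), fixture_slow_model())) {
    tac <- tissue_tac(m, inp)
    deriv <- function(t, y, p) {
      list(c(m$K1 * u(t) - (m$k2 + m$k3) * y[1] + m$k4 * y[2],
             m$k3 * y[1] - m$k4 * y[2]))
    }
    out <- deSolve::lsoda(c(0, 0), inp$times, deriv, NULL,
                          rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(tac$values - (out[, 2] + out[, 3]))), 1e-5)
  }
})

test_that("blood volume mixes whole-blood signal into the measured TAC", {
  inp <- fixture_input_curve(duration = 30)
  wb <- pet_curve(inp$times, inp$values * 1.3, kind = "whole_blood")
  m <- tissue_model("2TCM", K1 = 0.4, k2 = 0.25, k3 = 0.15, k4 = 0.08,
                    vB = 0.05)
  with_vb <- tissue_tac(m, inp, whole_blood = wb)
  no_vb <- tissue_tac(fixture_fast_model(), inp)
  expect_equal(with_vb$values, 0.95 * no_vb$values + 0.05 * wb$values,
               tolerance = 1e-12)
  expect_error(tissue_tac(m, inp), "whole_blood")
})
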