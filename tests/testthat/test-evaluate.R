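test_that("APD follows its defining formula and scale invariance", {
  expect_equal(apd(1, 1), 0)
  expect_equal(apd(1.1, 1.0), 10.0)
  expect_equal(apd(0.5, 2.0), 75.0)
  expect_error(apd(1, 0), "positive")
  expect_error(apd(1, -2), "positive")
  set.seed(9)
  a <- runif(20, 0.5, 5); b <- runif(20, 0.5, 5); cc <- runif(20, 0.1, 10)
  expect_equal(apd(cc * a, cc * b), apd(a, b))
})

test_that("APD summaries use type-7 quantiles per region", {
  df <- data.frame(roi = rep("THA", 3), apd = c(10, 10, 10))
  s <- summarize_apd(df)
  expect_equal(s$median, 10)
  expect_equal(s$iqr, 0)

  df2 <- data.frame(roi = rep("FRO", 4), apd = c(1, 2, 3, 4))
  s2 <- summarize_apd(df2)
  expect_equal(s2$median, 2.5)
  expect_equal(s2$iqr, 1.5)

  expect_error(summarize_apd(data.frame(roi = character(), apd = numeric())),
               "empty")
})

test_that("Pearson r matches closed forms and affine invariance", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(x, -2 * x + 7), -1.0)

  y <- c(2.3, 1.9, 4.1, 3.3, 5.0)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), hand, tolerance = 1e-12)
  expect_equal(pearson_r(3 * x + 1, y), pearson_r(x, y), tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), "variance")
  expect_error(pearson_r(x, y[1:4]), "equal length")
})

test_that("order evaluation reports 13-region APD tables and pooled r", {
  coh <- fixture_cohort(2)
  run <- run_order(coh, "HAR", "DASB", seed = 3, use_true_tacs = TRUE,
                   sep_config = separation_config(extrapolation = "oracle"))
  rep <- run$report
  expect_equal(nrow(rep$apd_est), 13)
  expect_equal(nrow(rep$apd_45$HAR), 13)
  expect_equal(nrow(rep$apd_45$DASB), 13)
  expect_equal(rep$r_est, 1.0, tolerance = 1e-9)      # oracle separation
  expect_true(all(rep$apd_est$median < 1e-6))
  expect_true(all(rep$r_90_45 > 0.9 & rep$r_90_45 <= 1))
  expect_equal(rep$n_subjects, 2)
})
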