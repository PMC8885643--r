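test_that("cohort generation is deterministic under a fixed seed", {
  expect_identical(make_cohort(n_pairs = 3, seed = 11),
                   make_cohort(n_pairs = 3, seed = 11))
  a <- make_cohort(n_pairs = 3, seed = 11)
  b <- make_cohort(n_pairs = 3, seed = 12)
  expect_false(identical(a, b))
})

test_that("subjects carry the 13 regions, valid kinetics and weight-based doses", {
  coh <- fixture_cohort(4)
  for (s in coh) {
    for (tr in c("HAR", "DASB")) {
      expect_identical(names(s$tracers[[tr]]$tissue), ROI_NAMES)
      expect_equal(s$tracers[[tr]]$dose_mbq,
                   cohort_config()$dose_per_kg[[tr]] * s$weight)
      expect_gt(s$tracers[[tr]]$dose_mbq, 0)
    }
    # the harmine-like tracer has the faster washout
    expect_gt(s$tracers$HAR$tissue$THA$k2, s$tracers$DASB$tissue$THA$k2)
  }
})

test_that("all generated analytic V_T are positive and finite at scale", {
  coh <- make_cohort(n_pairs = 39, seed = 5)   # 39 x 13 x 2 > 1000 models
  vts <- unlist(lapply(coh, function(s) {
    c(s$tracers$HAR$vt_true, s$tracers$DASB$vt_true)
  }))
  expect_gte(length(vts), 1000)
  expect_true(all(is.finite(vts)))
  expect_true(all(vts > 0))
})

test_that("generated scans combine framing, noise and ground truth coherently", {
  coh <- fixture_cohort(1)
  cfg <- cohort_config()
  scan <- generate_single_scan(coh[[1]], "HAR", cfg, seed = 3)
  expect_identical(names(scan$tacs), ROI_NAMES)
  expect_identical(scan$tracer, "HAR")
  # noiseless fine TACs are non-negative; framed ones sit near them
  for (r in c("THA", "CRB")) {
    expect_true(all(scan$tacs_true[[r]]$values >= 0))
    mid_true <- approx(scan$tacs_true[[r]]$times, scan$tacs_true[[r]]$values,
                       xout = scan$tacs[[r]]$times)$y
    expect_lt(mean(abs(scan$tacs[[r]]$values - mid_true)) /
                mean(mid_true), 0.25)
  }
  expect_identical(generate_single_scan(coh[[1]], "HAR", cfg, seed = 3)$tacs,
                   scan$tacs)
})
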