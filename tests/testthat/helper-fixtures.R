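# Shared fixtures: small deterministic models and scans built in code.

fixture_input_model <- function() {
  input_function_model(t0 = 0.5, A1 = 600, A2 = 12, A3 = 10,
                       l1 = -4, l2 = -0.25, l3 = -0.012)
}

fixture_pf_model <- function() parent_fraction_model(p_inf = 0.2, t50 = 15, h = 1.8)

fixture_fast_model <- function(vB = 0) {
  tissue_model("2TCM", K1 = 0.40, k2 = 0.25, k3 = 0.15, k4 = 0.08, vB = vB)
}

fixture_slow_model <- function(vB = 0) {
  tissue_model("2TCM", K1 = 0.35, k2 = 0.10, k3 = 0.09, k4 = 0.06, vB = vB)
}

# metabolite-corrected input on the 1-s generation grid
fixture_input_curve <- function(duration = 90, step = 1 / 60) {
  tt <- (0:round(duration / step)) * step
  plasma <- eval_input_function(fixture_input_model(), tt)
  apply_parent_fraction(plasma, fixture_pf_model())
}

# a deterministic two-subject cohort shared across tests
fixture_cohort <- function(n_pairs = 2) make_cohort(n_pairs = n_pairs, seed = 42)

# noiseless dual measurement of one subject for a given order/stagger
fixture_noiseless_dual <- function(order = c("HAR", "DASB"), stagger = 45,
                                   subject = fixture_cohort(1)[[1]]) {
  cfg <- cohort_config()
  s1 <- generate_single_scan(subject, order[1], cfg)
  s2 <- generate_single_scan(subject, order[2], cfg)
  rs1 <- resample_scan(s1, use_true_tacs = TRUE)
  rs2 <- resample_scan(s2, use_true_tacs = TRUE)
  build_dual_measurement(rs1, rs2, dual_protocol(order[1], order[2], stagger))
}
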