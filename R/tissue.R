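#' Compartmental tissue model
#'
#' Rate constants of a one- or two-tissue compartment model with fractional
#' blood volume. The analytic total volume of distribution is
#' \eqn{V_T = (K_1/k_2)(1 + k_3/k_4)} (reducing to \eqn{K_1/k_2} for 1TCM).
#'
#' @param family `"1TCM"` or `"2TCM"`.
#' @param K1 Plasma-to-tissue transfer (mL/cm^3/min), >= 0.
#' @param k2 Tissue-to-plasma rate (1/min), > 0 (V_T undefined otherwise).
#' @param k3,k4 Exchange rates with the second (bound) compartment (1/min);
#'   must be 0 for 1TCM, and `k4 > 0` whenever `k3 > 0` (reversible binding).
#' @param vB Fractional blood volume, in \[0, 0.1\].
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(family = c("2TCM", "1TCM"), K1, k2, k3 = 0, k4 = 0,
                         vB = 0) {
  family <- match.arg(family)
  p <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB)
  if (any(!is.finite(p))) stop("tissue-model rates must be finite", call. = FALSE)
  if (any(p < 0)) stop("tissue-model rates must be >= 0", call. = FALSE)
  if (k2 <= 0) stop("k2 must be > 0 (V_T undefined for k2 = 0)", call. = FALSE)
  if (vB > 0.1) stop("vB must lie in [0, 0.1]", call. = FALSE)
  if (family == "1TCM" && (k3 != 0 || k4 != 0)) {
    stop("1TCM requires k3 = k4 = 0", call. = FALSE)
  }
  if (family == "2TCM" && k3 > 0 && k4 <= 0) {
    stop("k4 must be > 0 when k3 > 0 (irreversible binding has no finite V_T)",
         call. = FALSE)
  }
  structure(list(family = family, K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "tissue_model")
}

#' Analytic total volume of distribution
#'
#' @param model A [tissue_model()].
#' @return \eqn{V_T = (K_1/k_2)(1 + k_3/k_4)} in mL/cm^3 (for 1TCM,
#'   \eqn{K_1/k_2}).
#' @export
analytic_vt <- function(model) {
  if (!inherits(model, "tissue_model")) {
    stop("`model` must be a tissue_model", call. = FALSE)
  }
  if (model$k3 > 0) {
    model$K1 / model$k2 * (1 + model$k3 / model$k4)
  } else {
    model$K1 / model$k2
  }
}

# Impulse-response terms of the compartment model: C_T(t) = sum A_i e^{-a_i t}.
# For 2TCM the macro rates are a_{1,2} = (s -/+ sqrt(s^2 - 4 k2 k4))/2 with
# s = k2 + k3 + k4. A vanishing discriminant (repeated eigenvalue) is lifted
# by a relative 1e-9 nudge of k4; the parameter set is measure-zero.
irf_terms <- function(K1, k2, k3 = 0, k4 = 0) {
  if (k3 == 0) return(list(A = K1, a = k2))
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  if (disc < 1e-12 * s^2) {
    k4 <- k4 * (1 + 1e-9)
    s <- k2 + k3 + k4
    disc <- s^2 - 4 * k2 * k4
  }
  d <- sqrt(disc)
  a1 <- (s - d) / 2
  a2 <- (s + d) / 2
  list(A = c(K1 * (k3 + k4 - a1), K1 * (a2 - k3 - k4)) / (a2 - a1),
       a = c(a1, a2))
}

# Exact convolution of A*exp(-a t) with the piecewise-linear interpolant of u
# on a uniform grid of step dt. Runs as a first-order recursion evaluated by
# stats::filter, so the result is exact (to rounding) for the interpolant.
conv_exp_lin <- function(A, a, u, dt) {
  n <- length(u)
  if (n < 2) stop("need at least 2 input samples", call. = FALSE)
  E <- exp(-a * dt)
  if (a * dt > 1e-6) {
    c_right <- (1 - E) / a                       # weight of u at interval end
    c_tri <- (1 - E * (1 + a * dt)) / (a^2 * dt) # weight of (u_start - u_end)
  } else {
    # series limits for a -> 0 (trapezoid weights)
    c_right <- dt * (1 - a * dt / 2 + (a * dt)^2 / 6)
    c_tri <- dt * (0.5 - a * dt / 3 + (a * dt)^2 / 8)
  }
  inc <- A * (u[-1] * c_right + (u[-n] - u[-1]) * c_tri)
  c(0, as.numeric(stats::filter(inc, E, method = "recursive")))
}

#' Simulate a noiseless tissue time-activity curve
#'
#' \deqn{C_{meas}(t) = (1 - v_B)\,[h \otimes C_p](t) + v_B\, C_{wb}(t)}
#' with \eqn{h} the compartmental impulse response (1TCM: \eqn{K_1 e^{-k_2 t}};
#' 2TCM: the standard two-exponential response) and \eqn{C_p} the
#' metabolite-corrected input. The convolution is exact for the
#' piecewise-linear interpolant of the input, so the input grid must be
#' uniform and at least as fine as 5 s.
#'
#' @param model A [tissue_model()].
#' @param input `pet_curve` of kind `"input"` (or `"plasma"`) on a uniform
#'   fine grid starting at the injection time.
#' @param whole_blood Whole-blood `pet_curve` on the same grid; required when
#'   `vB > 0`.
#' @param times Optional output times (min); defaults to the input grid.
#'   Values off the grid are linearly interpolated.
#' @return A `pet_curve` of kind `"TAC"` (non-negative).
#' @export
tissue_tac <- function(model, input, whole_blood = NULL, times = NULL) {
  if (!inherits(model, "tissue_model")) {
    stop("`model` must be a tissue_model", call. = FALSE)
  }
  stopifnot_curve(input, kind = c("input", "plasma"))
  dt <- grid_step(input)
  if (is.na(dt)) stop("input must be on a uniform grid", call. = FALSE)
  if (dt > DUAL_GRID_STEP + 1e-9) {
    stop("input grid must be at least as fine as 5 s (got ",
         round(dt * 60, 3), " s)", call. = FALSE)
  }
  terms <- irf_terms(model$K1, model$k2, model$k3, model$k4)
  ct <- 0
  for (i in seq_along(terms$A)) {
    ct <- ct + conv_exp_lin(terms$A[i], terms$a[i], input$values, dt)
  }
  if (model$vB > 0) {
    if (is.null(whole_blood)) {
      stop("whole_blood curve required when vB > 0", call. = FALSE)
    }
    stopifnot_curve(whole_blood, kind = "whole_blood")
    if (!same_grid(input, whole_blood)) {
      stop("whole_blood must be on the input grid", call. = FALSE)
    }
    ct <- (1 - model$vB) * ct + model$vB * whole_blood$values
  }
  ct <- pmax(ct, 0)
  if (!is.null(times)) {
    ct <- stats::approx(input$times, ct, xout = times, rule = 2)$y
    out_t <- times
  } else {
    out_t <- input$times
  }
  pet_curve(out_t, ct, kind = "TAC", tracer_label = input$tracer_label,
            injection_time = input$injection_time)
}
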