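#' Feng-type arterial plasma model
#'
#' Parametric plasma concentration model used to generate synthetic arterial
#' data: a delayed linear ramp damped by a fast exponential plus two slower
#' washout exponentials,
#' \deqn{C_p(t) = (A_1 (t - t_0) - A_2 - A_3) e^{l_1 (t-t_0)} +
#'       A_2 e^{l_2 (t-t_0)} + A_3 e^{l_3 (t-t_0)}, \quad t \ge t_0,}
#' and 0 before the appearance delay \eqn{t_0}. The value is continuous (0) at
#' \eqn{t_0}. Chosen for realism of bolus plasma curves and closed-form
#' integrability; the defaults place the peak about one minute after injection.
#'
#' @param t0 Appearance delay (min).
#' @param A1 Ramp amplitude (kBq/mL/min).
#' @param A2,A3 Exponential amplitudes (kBq/mL).
#' @param l1,l2,l3 Decay rates (1/min), `l1 < l2 < l3 <= 0`.
#' @return An object of class `input_function_model`.
#' @export
input_function_model <- function(t0 = 0.5, A1 = 600, A2 = 12, A3 = 10,
                                 l1 = -4, l2 = -0.25, l3 = -0.012) {
  p <- c(t0 = t0, A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3)
  if (any(!is.finite(p))) stop("input-function parameters must be finite",
                               call. = FALSE)
  if (!(l1 < l2 && l2 < l3 && l3 <= 0)) {
    stop("decay rates must satisfy l1 < l2 < l3 <= 0", call. = FALSE)
  }
  if (t0 < 0) stop("appearance delay t0 must be >= 0", call. = FALSE)
  structure(as.list(p), class = "input_function_model")
}

#' Evaluate a plasma model on a time grid
#'
#' @param model An [input_function_model()].
#' @param times Sample times (min), within \[0, 120\].
#' @param tracer_label Optional tracer identifier attached to the curve.
#' @return A `pet_curve` of kind `"plasma"`.
#' @export
eval_input_function <- function(model, times, tracer_label = NA_character_) {
  if (!inherits(model, "input_function_model")) {
    stop("`model` must be an input_function_model", call. = FALSE)
  }
  if (any(times < 0 | times > 120)) {
    stop("times must lie within [0, 120] min", call. = FALSE)
  }
  tau <- times - model$t0
  v <- (model$A1 * tau - model$A2 - model$A3) * exp(model$l1 * tau) +
    model$A2 * exp(model$l2 * tau) + model$A3 * exp(model$l3 * tau)
  v[tau < 0] <- 0
  pet_curve(times, v, kind = "plasma", tracer_label = tracer_label)
}

#' Hill-type parent-fraction model
#'
#' Fraction of plasma activity attributable to the unmetabolized parent
#' compound, declining from 1 at injection to an asymptote `p_inf`:
#' \deqn{f(t) = p_\infty + (1 - p_\infty) / (1 + (t/t_{50})^h).}
#' At `t = t50` the fraction is exactly `(1 + p_inf)/2`.
#'
#' @param p_inf Asymptotic parent fraction in \[0, 1\].
#' @param t50 Half-decline time (min), > 0.
#' @param h Hill slope, > 0.
#' @return An object of class `parent_fraction_model`.
#' @export
parent_fraction_model <- function(p_inf = 0.2, t50 = 15, h = 1.8) {
  if (any(!is.finite(c(p_inf, t50, h)))) {
    stop("parent-fraction parameters must be finite", call. = FALSE)
  }
  if (p_inf < 0 || p_inf > 1) stop("p_inf must lie in [0, 1]", call. = FALSE)
  if (t50 <= 0) stop("t50 must be > 0", call. = FALSE)
  if (h <= 0) stop("Hill slope h must be > 0", call. = FALSE)
  structure(list(p_inf = p_inf, t50 = t50, h = h),
            class = "parent_fraction_model")
}

#' Evaluate the parent fraction at given times
#' @param model A [parent_fraction_model()].
#' @param times Times (min), >= 0.
#' @return Numeric vector of fractions in \[p_inf, 1\].
#' @export
eval_parent_fraction <- function(model, times) {
  if (!inherits(model, "parent_fraction_model")) {
    stop("`model` must be a parent_fraction_model", call. = FALSE)
  }
  model$p_inf + (1 - model$p_inf) / (1 + (times / model$t50)^model$h)
}

#' Metabolite-correct a plasma curve
#'
#' Pointwise product of plasma activity and the parent fraction, giving the
#' metabolite-corrected input function. `fraction` is either a
#' [parent_fraction_model()] (evaluated on the plasma grid) or a
#' `pet_curve` of kind `"parent_fraction"`, which must sit on exactly the same
#' grid as the plasma curve; there is no silent interpolation.
#'
#' @param plasma A `pet_curve` of kind `"plasma"`.
#' @param fraction Parent-fraction model or curve.
#' @return A `pet_curve` of kind `"input"`, pointwise <= the plasma curve.
#' @export
apply_parent_fraction <- function(plasma, fraction) {
  stopifnot_curve(plasma, kind = "plasma")
  if (inherits(fraction, "parent_fraction_model")) {
    f <- eval_parent_fraction(fraction, plasma$times)
  } else if (is_pet_curve(fraction)) {
    stopifnot_curve(fraction, kind = "parent_fraction")
    if (!same_grid(plasma, fraction)) {
      stop("parent-fraction curve is not on the plasma grid; ",
           "resample explicitly before correcting", call. = FALSE)
    }
    f <- fraction$values
  } else {
    stop("`fraction` must be a parent_fraction_model or a pet_curve",
         call. = FALSE)
  }
  pet_curve(plasma$times, plasma$values * f, kind = "input",
            tracer_label = plasma$tracer_label,
            injection_time = plasma$injection_time)
}
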