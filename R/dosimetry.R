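#' Carbon-11 decay plan for a delayed second injection
#'
#' Decay arithmetic for protocol planning: how much molar activity and
#' activity remain when the second tracer is injected `delay` minutes after
#' synthesis-calibrated values. The default half-life is 20.0 min, the
#' rounded carbon-11 value commonly used in planning arithmetic; the physical
#' value 20.38 min can be selected.
#'
#' @param delay Delay of the second injection (min), >= 0.
#' @param half_life Half-life (min), > 0; default 20.0 (physical: 20.38).
#' @param molar_activity Initial molar activity (GBq/umol).
#' @param activity Initial activity (GBq).
#' @param dose_per_kg Planned dose (MBq/kg).
#' @param weight Body weight (kg).
#' @return An object of class `decay_plan`.
#' @export
decay_plan <- function(delay, half_life = 20.0, molar_activity = 100,
                       activity = 2.0, dose_per_kg = 4.51, weight = 75) {
  if (half_life <= 0) stop("half_life must be > 0", call. = FALSE)
  if (delay < 0) stop("delay must be >= 0", call. = FALSE)
  structure(list(delay = delay, half_life = half_life,
                 molar_activity = molar_activity, activity = activity,
                 dose_per_kg = dose_per_kg, weight = weight),
            class = "decay_plan")
}

#' Half-lives elapsed over a delay
#' @param delay Delay (min).
#' @param half_life Half-life (min), > 0.
#' @return `delay / half_life` (dimensionless; 45 min at a 20-min half-life
#'   is 2.25 half-lives).
#' @export
half_lives_elapsed <- function(delay, half_life = 20.0) {
  if (any(half_life <= 0)) stop("half_life must be > 0", call. = FALSE)
  delay / half_life
}

#' Radioactive decay of a quantity
#' @param initial Initial value (any activity-proportional unit), >= 0.
#' @param delay Elapsed time (min).
#' @param half_life Half-life (min), > 0.
#' @return `initial * 2^(-delay/half_life)`; 100 GBq/umol decays to
#'   21.02 GBq/umol over 45 min at a 20-min half-life.
#' @export
decayed_quantity <- function(initial, delay, half_life = 20.0) {
  if (any(initial < 0)) stop("initial must be >= 0", call. = FALSE)
  initial * 2^(-half_lives_elapsed(delay, half_life))
}

#' Weight-based application dose
#' @param dose_per_kg Dose per kg (MBq/kg), > 0.
#' @param weight Body weight (kg), > 0.
#' @return Dose in MBq (4.51 MBq/kg for 75 kg gives 338.25 MBq).
#' @export
dose_for_weight <- function(dose_per_kg, weight) {
  if (any(dose_per_kg <= 0) || any(weight <= 0)) {
    stop("dose_per_kg and weight must be > 0", call. = FALSE)
  }
  dose_per_kg * weight
}

#' Feasibility of the delayed second injection
#'
#' Compares the decayed molar activity against the lower application limit
#' and the decayed activity against the required weight-based dose.
#'
#' @param plan A [decay_plan()].
#' @param min_molar_activity Lower molar-activity limit (GBq/umol),
#'   default 20.
#' @return List: `pass`, decayed values, and margins (`margin_molar` in
#'   GBq/umol, `margin_activity` in MBq).
#' @export
feasibility_check <- function(plan, min_molar_activity = 20) {
  if (!inherits(plan, "decay_plan")) {
    stop("`plan` must be a decay_plan", call. = FALSE)
  }
  ma <- decayed_quantity(plan$molar_activity, plan$delay, plan$half_life)
  act_mbq <- decayed_quantity(plan$activity, plan$delay, plan$half_life) * 1000
  dose <- dose_for_weight(plan$dose_per_kg, plan$weight)
  list(pass = ma >= min_molar_activity && act_mbq >= dose,
       molar_activity = ma,
       margin_molar = ma - min_molar_activity,
       remaining_activity_mbq = act_mbq,
       required_dose_mbq = dose,
       margin_activity = act_mbq - dose,
       half_lives = half_lives_elapsed(plan$delay, plan$half_life))
}

#' Convert a decay-corrected curve to physical (uncorrected) activity
#'
#' Generated curves are stored decay-corrected to their own tracer's
#' injection time, the convention of reconstructed clinical TACs. For
#' sensitivity analyses in physical-activity space this multiplies by
#' \eqn{2^{-(t - t_{inj})/T_{1/2}}}.
#'
#' @param curve A `pet_curve`.
#' @param half_life Half-life (min); default the physical carbon-11 value
#'   20.38.
#' @return The decay-uncorrected `pet_curve`.
#' @export
apply_physical_decay <- function(curve, half_life = 20.38) {
  stopifnot_curve(curve)
  f <- 2^(-(curve$times - curve$injection_time) / half_life)
  f[curve$times < curve$injection_time] <- 1
  pet_curve(curve$times, curve$values * f, kind = curve$kind,
            tracer_label = curve$tracer_label,
            injection_time = curve$injection_time)
}
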