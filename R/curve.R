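#' Sampled activity curve
#'
#' The basic container of the package: a sampled time-series of activity
#' concentration (kBq/mL) against time (minutes on the scan clock). Used for
#' tissue time-activity curves (TACs), whole-blood and plasma activity, and
#' metabolite-corrected input functions.
#'
#' @param times Sample times in minutes, strictly increasing.
#' @param values Activity concentration in kBq/mL (dimensionless for
#'   parent-fraction curves); must be finite and the same length as `times`.
#' @param kind One of `"TAC"`, `"whole_blood"`, `"plasma"`, `"input"`,
#'   `"parent_fraction"`.
#' @param tracer_label Identifier of the tracer the curve belongs to
#'   (e.g. `"HAR"`, `"DASB"`), or `NA` for tracer-agnostic curves.
#' @param injection_time Injection time of the curve's tracer, minutes on the
#'   scan clock (0 for a tracer given at scan start).
#'
#' @return An object of class `pet_curve`: a list with the fields above.
#' @export
pet_curve <- function(times, values, kind = "TAC", tracer_label = NA_character_,
                      injection_time = 0) {
  kind <- match.arg(kind, c("TAC", "whole_blood", "plasma", "input",
                            "parent_fraction"))
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length (", length(times),
         " vs ", length(values), ")", call. = FALSE)
  }
  if (length(times) == 0) stop("empty curve", call. = FALSE)
  if (any(!is.finite(times))) stop("non-finite sample times", call. = FALSE)
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1]
    stop("sample times must be strictly increasing (violated between rows ",
         bad, " and ", bad + 1, ")", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite curve values", call. = FALSE)
  structure(
    list(times = times, values = values, kind = kind,
         tracer_label = tracer_label, injection_time = injection_time),
    class = "pet_curve"
  )
}

#' @export
print.pet_curve <- function(x, ...) {
  cat(sprintf("<pet_curve> %s%s: %d samples, t = [%.3g, %.3g] min, injected at %.3g min\n",
              x$kind,
              if (is.na(x$tracer_label)) "" else paste0(" [", x$tracer_label, "]"),
              length(x$times), min(x$times), max(x$times), x$injection_time))
  invisible(x)
}

#' @export
length.pet_curve <- function(x) length(x$times)

is_pet_curve <- function(x) inherits(x, "pet_curve")

stopifnot_curve <- function(x, kind = NULL, arg = deparse(substitute(x))) {
  if (!is_pet_curve(x)) stop("`", arg, "` must be a pet_curve", call. = FALSE)
  if (!is.null(kind) && !(x$kind %in% kind)) {
    stop("`", arg, "` must have kind ", paste(kind, collapse = "/"),
         ", got ", x$kind, call. = FALSE)
  }
  invisible(x)
}

#' Default dual-tracer sampling step (5 seconds, in minutes)
#' @export
DUAL_GRID_STEP <- 1 / 12

# Canonical uniform grid 0, step, ..., duration. Always built the same way so
# that independently constructed grids compare bit-identically.
uniform_grid <- function(duration, step = DUAL_GRID_STEP) {
  n <- round(duration / step)
  if (abs(n * step - duration) > 1e-9) {
    stop("duration ", duration, " min is not a multiple of the step (",
         step * 60, " s)", call. = FALSE)
  }
  (0:n) * step
}

grid_step <- function(curve) {
  d <- diff(curve$times)
  if (diff(range(d)) > 1e-9) return(NA_real_)
  mean(d)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$times) == length(b$times) && all(abs(a$times - b$times) <= tol)
}

#' Resample a curve onto a uniform grid
#'
#' Linear interpolation onto the grid `0, step, ..., duration` (minutes).
#' Beyond the last sample the last value is held; before the first sample the
#' first value is held. This is the resampling applied to framed TACs and
#' blood data before dual-tracer summation.
#'
#' @param curve A [pet_curve()].
#' @param step Grid step in minutes; default 5 s.
#' @param duration Grid end in minutes; defaults to the last sample time
#'   rounded down to the grid.
#' @return A `pet_curve` on the uniform grid, retaining kind and tracer.
#' @export
resample_uniform <- function(curve, step = DUAL_GRID_STEP, duration = NULL) {
  stopifnot_curve(curve)
  if (length(curve$times) < 2) stop("cannot resample a curve with fewer than 2 samples",
                                    call. = FALSE)
  if (is.null(duration)) duration <- floor(max(curve$times) / step) * step
  grid <- uniform_grid(duration, step)
  vals <- stats::approx(curve$times, curve$values, xout = grid,
                        method = "linear", rule = 2)$y
  pet_curve(grid, vals, kind = curve$kind, tracer_label = curve$tracer_label,
            injection_time = curve$injection_time)
}

#' Running trapezoidal integral of a curve
#'
#' Cumulative trapezoidal integral from the first sample; the first value is 0.
#' This is the integral transform used on both axes of the Logan plot, so the
#' curve is expected to start at its tracer's injection time.
#'
#' @param curve A [pet_curve()].
#' @return A `pet_curve` on the same grid whose values are the running
#'   integrals (kBq/mL x min).
#' @export
cumulative_integral <- function(curve) {
  stopifnot_curve(curve)
  if (length(curve$times) < 2) {
    stop("cumulative integral needs at least 2 samples", call. = FALSE)
  }
  cum <- cumtrapz(curve$times, curve$values)
  pet_curve(curve$times, cum, kind = curve$kind,
            tracer_label = curve$tracer_label,
            injection_time = curve$injection_time)
}

cumtrapz <- function(t, v) {
  c(0, cumsum(diff(t) * (v[-1] + v[-length(v)]) / 2))
}

trapz <- function(t, v) {
  sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
}

# Crop a curve to times <= t_max (inclusive, with tolerance).
crop_curve <- function(curve, t_max) {
  keep <- curve$times <= t_max + 1e-9
  pet_curve(curve$times[keep], curve$values[keep], kind = curve$kind,
            tracer_label = curve$tracer_label,
            injection_time = curve$injection_time)
}

# Shift a curve onto its own injection clock, dropping pre-injection samples.
rezero_curve <- function(curve) {
  keep <- curve$times >= curve$injection_time - 1e-9
  pet_curve(curve$times[keep] - curve$injection_time, curve$values[keep],
            kind = curve$kind, tracer_label = curve$tracer_label,
            injection_time = 0)
}
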