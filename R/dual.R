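#' Staggered dual-injection protocol
#'
#' @param first_tracer,second_tracer Distinct tracer labels.
#' @param stagger Delay of the second injection (min), one of 0, 15, 30, 45.
#' @param total_duration Scan length (min), default 90.
#' @return An object of class `dual_protocol`.
#' @export
dual_protocol <- function(first_tracer, second_tracer, stagger = 45,
                          total_duration = 90) {
  if (identical(first_tracer, second_tracer)) {
    stop("the two tracers must be distinct", call. = FALSE)
  }
  if (!stagger %in% c(0, 15, 30, 45)) {
    stop("stagger must be one of 0, 15, 30, 45 min", call. = FALSE)
  }
  if (stagger >= total_duration) {
    stop("stagger must be smaller than the total duration", call. = FALSE)
  }
  structure(list(first_tracer = first_tracer, second_tracer = second_tracer,
                 stagger = stagger, total_duration = total_duration),
            class = "dual_protocol")
}

# number of grid nodes the second tracer is shifted by; stagger must sit on
# the grid exactly (it always does for 5-s grids and whole-minute staggers)
shift_nodes <- function(stagger, step) {
  k <- round(stagger / step)
  if (abs(k * step - stagger) > 1e-9) {
    stop("stagger is not a multiple of the grid step", call. = FALSE)
  }
  k
}

#' Sum two single-tracer curves into a staggered dual curve
#'
#' \eqn{S(t) = C_1(t) + C_2(t - \Delta)} for \eqn{t \ge \Delta} and
#' \eqn{S(t) = C_1(t)} before the second injection. The shift is an integer
#' number of grid nodes, so no interpolation occurs at the injection boundary.
#' Both curves must already sit on the protocol's uniform 5-s grid
#' (second curve on its own injection clock).
#'
#' @param first,second `pet_curve`s on the same uniform grid.
#' @param protocol A [dual_protocol()].
#' @return The summed `pet_curve` on the scan clock.
#' @export
simulate_dual <- function(first, second, protocol) {
  stopifnot_curve(first); stopifnot_curve(second)
  if (!inherits(protocol, "dual_protocol")) {
    stop("`protocol` must be a dual_protocol", call. = FALSE)
  }
  if (!same_grid(first, second)) {
    stop("first and second curves must be on the same grid", call. = FALSE)
  }
  step <- grid_step(first)
  if (is.na(step)) stop("curves must be on a uniform grid", call. = FALSE)
  k <- shift_nodes(protocol$stagger, step)
  n <- length(first$times)
  v <- first$values
  if (k < n) {
    idx <- (k + 1):n
    v[idx] <- v[idx] + second$values[idx - k]
  }
  pet_curve(first$times, v, kind = first$kind,
            tracer_label = paste(protocol$first_tracer, protocol$second_tracer,
                                 sep = "_"),
            injection_time = first$injection_time)
}

#' Build a full dual-tracer measurement from two resampled single scans
#'
#' Applies [simulate_dual()] identically to every regional TAC and to the AIF,
#' and keeps the source single-tracer curves as provenance (they play the role
#' of the retrospective single-tracer measurements the dual session is summed
#' from, and provide the ground truth for oracle separation).
#'
#' @param first,second `scan_curves` (see [resample_scan()]) of the two
#'   tracers, on the same grid.
#' @param protocol A [dual_protocol()]; its tracer labels must match the scans.
#' @return An object of class `dual_measurement` with fields `protocol`,
#'   `aif`, `tacs`, `provenance`.
#' @export
build_dual_measurement <- function(first, second, protocol) {
  if (!inherits(first, "scan_curves") || !inherits(second, "scan_curves")) {
    stop("`first` and `second` must be scan_curves", call. = FALSE)
  }
  if (first$tracer != protocol$first_tracer ||
      second$tracer != protocol$second_tracer) {
    stop("scan tracer labels do not match the protocol order", call. = FALSE)
  }
  if (!setequal(names(first$tacs), names(second$tacs))) {
    stop("the two scans cover different region sets", call. = FALSE)
  }
  tacs <- stats::setNames(lapply(names(first$tacs), function(r) {
    simulate_dual(first$tacs[[r]], second$tacs[[r]], protocol)
  }), names(first$tacs))
  wb <- if (!is.null(first$whole_blood) && !is.null(second$whole_blood)) {
    simulate_dual(first$whole_blood, second$whole_blood, protocol)
  }
  structure(list(protocol = protocol,
                 aif = simulate_dual(first$aif, second$aif, protocol),
                 whole_blood = wb,
                 tacs = tacs,
                 provenance = list(first = first, second = second)),
            class = "dual_measurement")
}

#' Early clean window of a dual measurement
#'
#' The samples strictly before the second injection, which by construction
#' equal the first tracer's single-tracer curves there.
#'
#' @param dual A `dual_measurement` with stagger > 0.
#' @return List with `aif` and `tacs` restricted to `[0, stagger)`.
#' @export
early_window <- function(dual) {
  if (!inherits(dual, "dual_measurement")) {
    stop("`dual` must be a dual_measurement", call. = FALSE)
  }
  delta <- dual$protocol$stagger
  if (delta <= 0) {
    stop("no clean window exists for a simultaneous (stagger 0) protocol",
         call. = FALSE)
  }
  cut <- function(cv) {
    keep <- cv$times < delta - 1e-9
    pet_curve(cv$times[keep], cv$values[keep], kind = cv$kind,
              tracer_label = cv$tracer_label,
              injection_time = cv$injection_time)
  }
  list(aif = cut(dual$aif), tacs = lapply(dual$tacs, cut))
}
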