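#' Scanner frame schedule
#'
#' Non-overlapping, strictly increasing acquisition frames covering the scan.
#'
#' @param start,end Frame start/end times (min), equal length.
#' @return An object of class `frame_schedule` (data.frame with `start`,
#'   `end`, `mid`, `duration`).
#' @export
frame_schedule <- function(start, end) {
  if (length(start) != length(end) || length(start) == 0) {
    stop("start and end must be non-empty and of equal length", call. = FALSE)
  }
  if (any(end <= start)) stop("every frame must have end > start", call. = FALSE)
  if (any(diff(start) <= 0) || any(start[-1] < end[-length(end)] - 1e-9)) {
    stop("frames must be strictly increasing and non-overlapping", call. = FALSE)
  }
  structure(data.frame(start = start, end = end, mid = (start + end) / 2,
                       duration = end - start),
            class = c("frame_schedule", "data.frame"))
}

#' Frame schedule from a vector of frame durations
#' @param durations Frame durations (min), contiguous from t = 0.
#' @return A [frame_schedule()].
#' @export
frame_schedule_from_durations <- function(durations) {
  end <- cumsum(durations)
  frame_schedule(c(0, end[-length(end)]), end)
}

#' Default 90-min dynamic framing
#'
#' 6 x 30 s, 7 x 1 min, 4 x 5 min, 6 x 10 min (23 frames, 90 min total) --
#' a typical clinical dynamic brain protocol shape.
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  frame_schedule_from_durations(c(rep(0.5, 6), rep(1, 7), rep(5, 4), rep(10, 6)))
}

#' Frame-average a fine curve and add count-like noise
#'
#' Each frame value is the mean of the fine curve within the frame. Optional
#' additive zero-mean Gaussian noise has standard deviation
#' `noise_scale * sqrt(max(value, 0) / duration)` -- the variance falls with
#' frame duration and grows with activity, emulating count statistics of
#' framed ROI means. Frame values are stamped at frame midpoints.
#'
#' @param fine A `pet_curve` on a grid covering all frames.
#' @param schedule A [frame_schedule()].
#' @param noise_scale Noise magnitude (kBq/mL per sqrt(min^-1)); 0 = noiseless.
#' @param seed Optional integer seed for reproducible noise.
#' @return A `pet_curve` at frame midpoints; the frame schedule and the
#'   per-frame noise standard deviations are attached as attributes
#'   `"schedule"` and `"noise_sd"`.
#' @export
frame_and_noise <- function(fine, schedule, noise_scale = 0, seed = NULL) {
  stopifnot_curve(fine)
  if (!inherits(schedule, "frame_schedule")) {
    stop("`schedule` must be a frame_schedule", call. = FALSE)
  }
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  if (min(fine$times) > min(schedule$start) + 1e-9 ||
      max(fine$times) < max(schedule$end) - 1e-9) {
    stop("fine grid does not cover the frame schedule", call. = FALSE)
  }
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    sel <- fine$times >= schedule$start[i] - 1e-9 &
      fine$times < schedule$end[i] - 1e-9
    mean(fine$values[sel])
  }, numeric(1))
  sd <- noise_scale * sqrt(pmax(vals, 0) / schedule$duration)
  if (noise_scale > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + stats::rnorm(length(vals), 0, sd)
  }
  out <- pet_curve(schedule$mid, vals, kind = fine$kind,
                   tracer_label = fine$tracer_label,
                   injection_time = fine$injection_time)
  attr(out, "schedule") <- schedule
  attr(out, "noise_sd") <- sd
  out
}
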