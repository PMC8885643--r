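#' Logan graphical analysis of total volume of distribution
#'
#' Ordinary least squares of the Logan-transformed coordinates
#' \deqn{y(t) = \frac{\int_0^t C_T\,ds}{C_T(t)}, \qquad
#'       x(t) = \frac{\int_0^t C_p\,ds}{C_T(t)}}
#' restricted to \eqn{t \ge t^*}, with the metabolite-corrected plasma input
#' \eqn{C_p}. For a reversible tracer the plot becomes linear beyond
#' \eqn{t^*} and the slope is \eqn{V_T} (the intercept, in minutes, is
#' negative). Times are measured from the tracer's own injection: curves whose
#' `injection_time` is not 0 are re-zeroed (pre-injection samples dropped)
#' before the transform, and both curves must sit on the same grid.
#'
#' @param tac Tissue `pet_curve`; must be strictly positive beyond `t_star`.
#' @param input Metabolite-corrected input `pet_curve` on the same grid.
#' @param t_star Start of the linear segment (min, on the tracer's own clock).
#' @return An object of class `logan_fit`: `vt` (slope), `intercept`,
#'   `r2_linear`, `n_points`, `t_star`.
#' @export
logan_vt <- function(tac, input, t_star) {
  stopifnot_curve(tac)
  stopifnot_curve(input, kind = c("input", "plasma"))
  if (abs(tac$injection_time - input$injection_time) > 1e-9) {
    stop("tac and input have different injection times", call. = FALSE)
  }
  tac <- rezero_curve(tac)
  input <- rezero_curve(input)
  if (!same_grid(tac, input)) {
    stop("tac and input must be sampled on the same grid", call. = FALSE)
  }
  t <- tac$times
  if (max(t) < t_star + 15 - 1e-9) {
    stop("curves must extend at least 15 min beyond t_star (have ",
         round(max(t) - t_star, 2), " min)", call. = FALSE)
  }
  int_tac <- cumtrapz(t, tac$values)
  int_inp <- cumtrapz(t, input$values)
  seg <- t >= t_star - 1e-9
  if (any(tac$values[seg] <= 0)) {
    stop("TAC has non-positive values beyond t_star; Logan transform undefined",
         call. = FALSE)
  }
  y <- int_tac[seg] / tac$values[seg]
  x <- int_inp[seg] / tac$values[seg]
  if (length(x) < 5) {
    stop("fewer than 5 usable points beyond t_star", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(vt = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2_linear = r2,
                 n_points = length(x),
                 t_star = t_star),
            class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf("<logan_fit> V_T = %.3f mL/cm^3 (intercept %.2f min, R^2 %.4f, %d points, t* = %g min)\n",
              x$vt, x$intercept, x$r2_linear, x$n_points, x$t_star))
  invisible(x)
}

#' Logan t* defaults per tracer speed
#'
#' 20 min for the fast (harmine-like) tracer, 30 min for the slow (DASB-like)
#' tracer; used for 90-min and 45-min segments alike (45-min data then retain
#' at least 15 min, i.e. 180 five-second points, past t*).
#' @param tracer `"HAR"` or `"DASB"`.
#' @return t* in minutes.
#' @export
default_t_star <- function(tracer) {
  switch(tracer, HAR = 20, DASB = 30,
         stop("no default t* for tracer ", tracer, call. = FALSE))
}

# Logan V_T for a named list of regional TACs against one input curve.
quantify_curve_set <- function(tacs, aif, t_star, duration = NULL) {
  if (!is.null(duration)) {
    tacs <- lapply(tacs, crop_curve, t_max = duration + unique(vapply(
      tacs, function(x) x$injection_time, numeric(1)))[1])
    aif <- crop_curve(aif, duration + aif$injection_time)
  }
  rows <- lapply(names(tacs), function(r) {
    lf <- tryCatch(logan_vt(tacs[[r]], aif, t_star), error = function(e) e)
    if (inherits(lf, "error")) {
      # a quantification failure of one curve (e.g. a clipped-to-zero
      # estimated TAC) is recorded, not fatal to the cohort run
      return(data.frame(roi = r, vt = NA_real_, intercept = NA_real_,
                        r2 = NA_real_, n_points = NA_integer_,
                        t_star = t_star))
    }
    data.frame(roi = r, vt = lf$vt, intercept = lf$intercept,
               r2 = lf$r2_linear, n_points = lf$n_points, t_star = t_star)
  })
  do.call(rbind, rows)
}

#' Quantify V_T under the three study conditions
#'
#' Builds the tidy V_T table of one injection order for one subject:
#' \describe{
#'   \item{`single90`}{full 90-min single-tracer data, both tracers;}
#'   \item{`single45`}{the first 45 min of the single-tracer data, both
#'     tracers (for the first tracer this equals the dual measurement's clean
#'     early window);}
#'   \item{`est`}{the separated second-tracer curves, on the second tracer's
#'     own injection clock, quantified with the separated AIF.}
#' }
#'
#' @param single_first,single_second `scan_curves` of the first and second
#'   tracer (full duration, 5-s grid).
#' @param sep A `separation_result` for the corresponding dual measurement.
#' @param t_star Named vector of t* per tracer label; defaults via
#'   [default_t_star()].
#' @param short_duration Length of the truncated condition (min), default 45.
#' @return data.frame with columns `subject`, `roi`, `tracer`, `condition`,
#'   `vt`, `intercept`, `r2`, `n_points`, `t_star`.
#' @export
quantify_conditions <- function(single_first, single_second, sep,
                                t_star = NULL, short_duration = 45) {
  labs <- c(single_first$tracer, single_second$tracer)
  if (is.null(t_star)) {
    t_star <- stats::setNames(vapply(labs, default_t_star, numeric(1)), labs)
  }
  missing_roi <- setdiff(ROI_NAMES, names(single_first$tacs))
  if (length(missing_roi) > 0) {
    stop("missing regions: ", paste(missing_roi, collapse = ", "),
         call. = FALSE)
  }
  one <- function(scan, cond, dur) {
    df <- quantify_curve_set(scan$tacs, scan$aif, t_star[[scan$tracer]],
                             duration = dur)
    df$tracer <- scan$tracer
    df$condition <- cond
    df$subject <- scan$subject_id
    df
  }
  out <- rbind(
    one(single_first, "single90", NULL),
    one(single_second, "single90", NULL),
    one(single_first, "single45", short_duration),
    one(single_second, "single45", short_duration)
  )
  est <- quantify_curve_set(sep$est_second$tacs, sep$est_second$aif,
                            t_star[[single_second$tracer]])
  est$tracer <- single_second$tracer
  est$condition <- "est"
  est$subject <- single_second$subject_id
  out <- rbind(out, est)
  rownames(out) <- NULL
  out[, c("subject", "roi", "tracer", "condition", "vt", "intercept", "r2",
          "n_points", "t_star")]
}
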