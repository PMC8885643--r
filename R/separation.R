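#' Separation settings
#'
#' @param tac_family Extrapolation family for regional TACs: `"2tcm"` (refit of
#'   the generating kinetic family, driven by the extrapolated AIF -- the
#'   default) or `"exp1"`/`"exp2"`/`"exp3"` (model-agnostic sum of
#'   exponentials fitted to the post-peak tail).
#' @param aif_family Extrapolation family for the AIF tail (sum of
#'   exponentials; default tri-exponential).
#' @param t_fit_start_offset Start of the tail-fit window, minutes after the
#'   curve's peak (default 3 min) -- excludes the delivery phase that
#'   exponential tails cannot represent.
#' @param max_rel_unc Failure threshold: relative 1-sigma uncertainty of the
#'   extrapolated value at scan end above which a curve's separation is
#'   flagged (default 0.20).
#' @param extrapolation `"fit"` (normal operation) or `"oracle"` (replace the
#'   extrapolated first-tracer curves by their ground-truth continuation from
#'   the measurement's provenance; for validation).
#' @return A list of class `separation_config`.
#' @export
separation_config <- function(tac_family = c("2tcm", "exp3", "exp2", "exp1"),
                              aif_family = c("exp3", "exp2", "exp1"),
                              t_fit_start_offset = 3,
                              max_rel_unc = 0.20,
                              extrapolation = c("fit", "oracle")) {
  structure(list(tac_family = match.arg(tac_family),
                 aif_family = match.arg(aif_family),
                 t_fit_start_offset = t_fit_start_offset,
                 max_rel_unc = max_rel_unc,
                 extrapolation = match.arg(extrapolation)),
            class = "separation_config")
}

exp_sum_eval <- function(coef, t) {
  k <- length(coef) / 2
  a <- coef[seq_len(k)]
  b <- coef[k + seq_len(k)]
  v <- 0
  for (i in seq_len(k)) v <- v + a[i] * exp(b[i] * t)
  v
}

# log-linear single-exponential fit; always computable, used as init and as
# a last-resort fallback
exp1_loglin <- function(t, v) {
  eps <- max(v, 0) * 1e-6 + 1e-9
  fit <- stats::lm(log(pmax(v, eps)) ~ t)
  b <- min(unname(stats::coef(fit)[2]), 0)
  a <- exp(unname(stats::coef(fit)[1]))
  c(a1 = a, b1 = b)
}

exp_inits <- function(t, v, order) {
  base <- exp1_loglin(t, v)
  if (order == 1) return(list(base))
  # cascade: slow component from the late half, fast from the early residual
  half <- t >= stats::median(t)
  slow <- exp1_loglin(t[half], v[half])
  resid <- pmax(v - exp_sum_eval(c(slow[1], slow[2]), t), 0)
  fast <- if (any(resid[!half] > 0)) exp1_loglin(t[!half], resid[!half]) else
    c(a1 = max(resid, 1e-6), b1 = -1)
  if (order == 2) {
    return(list(c(a1 = unname(fast[1]), a2 = unname(slow[1]),
                  b1 = unname(min(fast[2], slow[2] - 0.05)),
                  b2 = unname(slow[2])),
                c(a1 = unname(base[1]) / 2, a2 = unname(base[1]) / 2,
                  b1 = unname(base[2]) * 3 - 0.1, b2 = unname(base[2]) / 2)))
  }
  list(c(a1 = unname(fast[1]), a2 = unname(slow[1]) / 2, a3 = unname(slow[1]) / 2,
         b1 = unname(min(fast[2], slow[2] - 0.1)), b2 = unname(slow[2]) * 2 - 0.05,
         b3 = unname(slow[2]) / 2),
       c(a1 = unname(base[1]) / 3, a2 = unname(base[1]) / 3,
         a3 = unname(base[1]) / 3,
         b1 = unname(base[2]) * 5 - 0.5, b2 = unname(base[2]) * 2 - 0.05,
         b3 = unname(base[2]) / 3))
}

# prediction of a 2TCM refit on the stored input grid
tcm_predict_grid <- function(coef, input, dt = grid_step(input)) {
  terms <- irf_terms(coef[["K1"]], coef[["k2"]], coef[["k3"]], coef[["k4"]])
  v <- 0
  for (i in seq_along(terms$A)) {
    v <- v + conv_exp_lin(terms$A[i], terms$a[i], input$values, dt)
  }
  v
}

# full refit prediction on the input grid, incl. the blood-signal term
tcm_full_pred <- function(coef, input, blood = NULL) {
  v <- tcm_predict_grid(coef[c("K1", "k2", "k3", "k4")], input)
  if ("vb" %in% names(coef)) {
    bv <- if (is.null(blood)) input$values else blood$values
    v <- v + coef[["vb"]] * bv
  }
  v
}

predict_tail <- function(fit, times) {
  if (startsWith(fit$family, "exp")) {
    exp_sum_eval(fit$coef, times)
  } else {
    stats::approx(fit$input$times, fit$grid_pred, xout = times, rule = 2)$y
  }
}

tail_rel_unc <- function(fit, t_eval) {
  if (is.null(fit$vcov) || any(!is.finite(fit$vcov))) return(Inf)
  pred0 <- predict_tail(fit, t_eval)
  g <- vapply(seq_along(fit$coef), function(i) {
    h <- 1e-5 * max(abs(fit$coef[i]), 1e-5)
    cf <- fit$coef; cf[i] <- cf[i] + h
    f2 <- fit; f2$coef <- cf
    if (!startsWith(fit$family, "exp")) {
      f2$grid_pred <- tcm_full_pred(cf, fit$input, fit$blood)
    }
    (predict_tail(f2, t_eval) - pred0) / h
  }, numeric(1))
  se <- sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
  if (pred0 <= 0) return(Inf)
  se / pred0
}

#' Fit an extrapolation model to the pre-second-injection window
#'
#' Weighted least-squares fit of either a sum of 1-3 decaying exponentials to
#' the post-peak tail, or a full 2TCM refit (requires the first tracer's input
#' curve over the whole scan). Non-convergence, an unfinished peak, or an
#' ill-conditioned Jacobian set `converged = FALSE` rather than raising.
#'
#' @param curve The dual-measurement curve (equal to the first tracer's data
#'   before the second injection).
#' @param window Fit window `c(start, end)` in minutes; `end` is the stagger.
#' @param family `"exp1"`, `"exp2"`, `"exp3"` or `"2tcm"`.
#' @param input For `family = "2tcm"`: the first tracer's (extrapolated)
#'   input `pet_curve` covering the full scan on a uniform grid.
#' @param blood For `family = "2tcm"`: blood-signal regressor `pet_curve`
#'   (extrapolated whole blood) on the input grid; the refit's `vb`
#'   coefficient scales it. Falls back to the input curve when absent.
#' @param weights Optional per-sample weights on the window (default uniform;
#'   supply inverse variances when the noise model is known).
#' @return An object of class `tail_fit`: family, coefficients, covariance,
#'   fit window, weighted residual norm, `converged` flag and reason.
#' @export
fit_tail <- function(curve, window, family = c("exp2", "exp1", "exp3", "2tcm"),
                     input = NULL, blood = NULL, weights = NULL) {
  family <- match.arg(family)
  stopifnot_curve(curve)
  sel <- curve$times >= window[1] - 1e-9 & curve$times <= window[2] + 1e-9
  t <- curve$times[sel]
  v <- curve$values[sel]
  if (length(t) < 4) {
    stop("fit window contains fewer than 4 samples", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(t))
  peak_t <- t[which.max(v)]
  n_past_peak <- sum(t > peak_t)
  converged <- TRUE
  reason <- "ok"
  if (n_past_peak < 20) {
    converged <- FALSE
    reason <- "peak_not_passed"
  }

  if (family != "2tcm" && stats::sd(v) <= 1e-12 * max(abs(v), 1)) {
    # degenerate constant curve: exact order-1 fit with rate 0
    fit <- structure(list(family = "exp1", coef = c(a1 = mean(v), b1 = 0),
                          vcov = matrix(0, 2, 2), window = window,
                          resid_norm = 0, n = length(t),
                          converged = TRUE, reason = "constant"),
                     class = "tail_fit")
    return(fit)
  }

  if (family == "2tcm") {
    if (is.null(input)) stop("2tcm refit requires `input`", call. = FALSE)
    stopifnot_curve(input, kind = c("input", "plasma"))
    # vb scales the blood-borne signal; the regressor is the extrapolated
    # whole-blood curve when available, else the input curve itself
    bcv <- if (is.null(blood)) input else blood
    step_in <- grid_step(input)
    # the refit convolves on a ~15-s thinned copy of the input grid (the
    # input is smooth; the full 5-s grid triples cost for no visible gain)
    thin <- if (!is.na(step_in)) max(1L, round((15 / 60) / step_in)) else 1L
    keep <- seq(1, length(input$times), by = thin)
    input_f <- pet_curve(input$times[keep], input$values[keep],
                         kind = input$kind)
    dt_f <- grid_step(input_f)
    # fit residuals on window samples that sit on the thinned grid
    idx_f <- round((t - input_f$times[1]) / dt_f) + 1
    on_grid <- !is.na(dt_f) & idx_f >= 1 & idx_f <= length(input_f$times)
    on_grid <- on_grid & abs(input_f$times[pmin(pmax(idx_f, 1),
                             length(input_f$times))] - t) < 1e-9
    if (sum(on_grid) >= 20) {
      t <- t[on_grid]; v <- v[on_grid]; weights <- weights[on_grid]
      idx_f <- idx_f[on_grid]
      lookup <- function(pg) pg[idx_f]
    } else {
      lookup <- function(pg) stats::approx(input_f$times, pg, xout = t,
                                           rule = 2)$y
    }
    b_at_t <- stats::approx(bcv$times, bcv$values, xout = t, rule = 2)$y
    obj <- function(K1, k2, k3, k4, vb) {
      pg <- tcm_predict_grid(c(K1 = K1, k2 = k2, k3 = k3, k4 = k4),
                             input_f, dt = dt_f)
      lookup(pg) + vb * b_at_t
    }
    starts <- list(c(K1 = 0.3, k2 = 0.15, k3 = 0.05, k4 = 0.05, vb = 0.05),
                   c(K1 = 0.4, k2 = 0.30, k3 = 0.12, k4 = 0.08, vb = 0.02),
                   c(K1 = 0.3, k2 = 0.08, k3 = 0.04, k4 = 0.04, vb = 0.1))
    lower <- c(1e-4, 1e-3, 0, 1e-3, 0)
    upper <- c(3, 3, 1.5, 1, 1)
    form <- v ~ obj(K1, k2, k3, k4, vb)
  } else {
    order <- as.integer(substring(family, 4))
    starts <- exp_inits(t, v, order)
    lower <- c(rep(0, order), rep(-10, order))
    upper <- c(rep(Inf, order), rep(0, order))
    form <- switch(order,
      v ~ a1 * exp(b1 * tt),
      v ~ a1 * exp(b1 * tt) + a2 * exp(b2 * tt),
      v ~ a1 * exp(b1 * tt) + a2 * exp(b2 * tt) + a3 * exp(b3 * tt))
    tt <- t
  }

  best <- NULL
  tss <- sum(weights * (v - stats::weighted.mean(v, weights))^2)
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nlsLM(form, start = as.list(st), weights = weights,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (!is.null(res)) {
      rss <- sum(weights * stats::residuals(res)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = res, rss = rss)
      if (rss < 1e-8 * tss) break   # near-perfect fit; later starts are moot
    }
  }

  if (is.null(best)) {
    cf <- exp1_loglin(t, v)
    return(structure(list(family = "exp1", coef = cf, vcov = NULL,
                          window = window,
                          resid_norm = sqrt(sum(weights *
                            (v - exp_sum_eval(cf, t))^2)),
                          n = length(t), converged = FALSE,
                          reason = "no_fit"),
                     class = "tail_fit"))
  }

  nf <- best$fit
  cf <- stats::coef(nf)
  if (!isTRUE(nf$convInfo$isConv)) {
    converged <- FALSE
    if (reason == "ok") reason <- "not_converged"
  }
  J <- nf$m$gradient()
  if (any(!is.finite(J)) || kappa(crossprod(J)) > 1e12) {
    converged <- FALSE
    if (reason == "ok") reason <- "ill_conditioned"
  }
  V <- tryCatch(stats::vcov(nf), error = function(e) NULL)
  if (is.null(V) && converged) {
    converged <- FALSE
    reason <- "singular_covariance"
  }
  out <- structure(list(family = family, coef = cf, vcov = V, window = window,
                        resid_norm = sqrt(best$rss), n = length(t),
                        converged = converged, reason = reason),
                   class = "tail_fit")
  if (family == "2tcm") {
    out$input <- input
    out$blood <- blood
    out$grid_pred <- tcm_full_pred(cf, input, blood)
  }
  out
}

#' Evaluate a converged tail fit at new times
#'
#' Substituting window-interior times returns the fitted values; later times
#' give the extrapolation. Raises for a non-converged fit (use the
#' diagnostics in the fit object to decide how to proceed).
#'
#' @param fit A [fit_tail()] result with `converged = TRUE`.
#' @param times Evaluation times (min).
#' @param kind,tracer_label,injection_time Metadata of the returned curve.
#' @return A `pet_curve`.
#' @export
extrapolate <- function(fit, times, kind = "TAC",
                        tracer_label = NA_character_, injection_time = 0) {
  if (!inherits(fit, "tail_fit")) stop("`fit` must be a tail_fit", call. = FALSE)
  if (!isTRUE(fit$converged)) {
    stop("refusing to extrapolate a non-converged tail fit (reason: ",
         fit$reason, ")", call. = FALSE)
  }
  pet_curve(times, predict_tail(fit, times), kind = kind,
            tracer_label = tracer_label, injection_time = injection_time)
}

#' Subtract extrapolated first-tracer curves from a dual measurement
#'
#' Implements the estimation step: the second tracer's curve is the dual
#' measurement minus the extrapolated continuation of the first tracer,
#' pointwise, for every region and the AIF. Values before the second
#' injection are forced to 0 and negative values are floored at 0; the
#' per-sample adjustment is kept (`clip`), so that
#' `dual = ext_first + est_second + clip` holds exactly.
#'
#' @param dual A `dual_measurement`.
#' @param ext_first List with `aif` and `tacs`: first-tracer curves
#'   extrapolated to the full duration, on the dual grid.
#' @param diagnostics Optional per-curve `tail_fit` diagnostics to attach.
#' @param status Separation status to attach (`"ok"` or
#'   `"failed_separation"`).
#' @return An object of class `separation_result`.
#' @export
estimate_second <- function(dual, ext_first, diagnostics = NULL,
                            status = "ok") {
  if (!inherits(dual, "dual_measurement")) {
    stop("`dual` must be a dual_measurement", call. = FALSE)
  }
  delta <- dual$protocol$stagger
  second_label <- dual$protocol$second_tracer
  sub1 <- function(obs, ext) {
    if (!same_grid(obs, ext)) {
      stop("extrapolated curve is not on the dual measurement grid",
           call. = FALSE)
    }
    raw <- obs$values - ext$values
    est <- raw
    est[obs$times < delta - 1e-9] <- 0
    est <- pmax(est, 0)
    list(est = pet_curve(obs$times, est, kind = obs$kind,
                         tracer_label = second_label,
                         injection_time = delta),
         clip = raw - est)
  }
  aif_s <- sub1(dual$aif, ext_first$aif)
  tac_s <- lapply(names(dual$tacs), function(r) {
    sub1(dual$tacs[[r]], ext_first$tacs[[r]])
  })
  names(tac_s) <- names(dual$tacs)
  clip <- c(list(aif = aif_s$clip), lapply(tac_s, `[[`, "clip"))
  step <- grid_step(dual$aif)
  structure(list(
    status = status,
    ext_first = ext_first,
    est_second = list(aif = aif_s$est, tacs = lapply(tac_s, `[[`, "est")),
    clip = clip,
    clipped_integral = vapply(clip, function(cv) -sum(cv[cv < 0]) * step,
                              numeric(1)),
    diagnostics = diagnostics,
    protocol = dual$protocol
  ), class = "separation_result")
}

#' Separate a dual-tracer measurement into its two tracers
#'
#' Fits and extrapolates the first tracer from the clean window before the
#' second injection (AIF first, then every regional TAC), subtracts the
#' extrapolation from the dual measurement, and reports diagnostics. Inside
#' the clean window the first tracer's "extrapolation" is the observed data
#' itself (the dual measurement equals the first tracer there); the fitted
#' model takes over at the second injection.
#'
#' The separation is flagged `failed_separation` when any required fit does
#' not converge or its extrapolated value at scan end carries more than
#' `max_rel_unc` relative uncertainty; estimated curves are still returned
#' for inspection whenever they are computable.
#'
#' @param dual A `dual_measurement` with stagger in 15/30/45 min.
#' @param config A [separation_config()].
#' @return A `separation_result` (see [estimate_second()]).
#' @export
separate <- function(dual, config = separation_config()) {
  if (!inherits(dual, "dual_measurement")) {
    stop("`dual` must be a dual_measurement", call. = FALSE)
  }
  delta <- dual$protocol$stagger
  if (delta <= 0) {
    stop("a simultaneous (stagger 0) protocol cannot be separated by ",
         "extrapolation", call. = FALSE)
  }
  tt <- dual$aif$times
  dur <- max(tt)

  if (config$extrapolation == "oracle") {
    prov <- dual$provenance$first
    ext <- list(aif = prov$aif, tacs = prov$tacs)
    return(estimate_second(dual, ext, diagnostics = list(mode = "oracle"),
                           status = "ok"))
  }

  splice <- function(obs, fit) {
    v <- obs$values
    late <- obs$times >= delta - 1e-9
    if (!startsWith(fit$family, "exp") && same_grid(obs, fit$input)) {
      v[late] <- fit$grid_pred[late]
    } else {
      v[late] <- predict_tail(fit, obs$times[late])
    }
    pet_curve(obs$times, pmax(v, 0), kind = obs$kind,
              tracer_label = dual$protocol$first_tracer,
              injection_time = 0)
  }

  fit_one <- function(curve, family, input = NULL, blood = NULL) {
    pre <- curve$times < delta - 1e-9   # only the clean window informs the fit
    peak_t <- curve$times[pre][which.max(curve$values[pre])]
    win <- if (family == "2tcm") c(0, delta) else
      c(min(peak_t + config$t_fit_start_offset, delta - 2), delta)
    fit_tail(curve, win, family = family, input = input, blood = blood)
  }

  aif_fit <- fit_one(dual$aif, config$aif_family)
  aif_ext <- splice(dual$aif, aif_fit)
  aif_ext$kind <- "input"

  wb_ext <- NULL
  if (!is.null(dual$whole_blood)) {
    wb_fit <- fit_one(dual$whole_blood, config$aif_family)
    wb_ext <- splice(dual$whole_blood, wb_fit)
    wb_ext$kind <- "whole_blood"
  }

  tac_fits <- lapply(dual$tacs, function(tc) {
    fit_one(tc, config$tac_family,
            input = if (config$tac_family == "2tcm") aif_ext else NULL,
            blood = if (config$tac_family == "2tcm") wb_ext else NULL)
  })
  ext <- list(aif = aif_ext,
              tacs = stats::setNames(lapply(names(dual$tacs), function(r) {
                splice(dual$tacs[[r]], tac_fits[[r]])
              }), names(dual$tacs)))

  diags <- c(list(aif = aif_fit), tac_fits)
  rel_unc <- vapply(diags, tail_rel_unc, numeric(1), t_eval = dur)
  conv <- vapply(diags, function(f) isTRUE(f$converged), logical(1))
  ok <- all(conv) && all(rel_unc <= config$max_rel_unc)
  diag_tbl <- data.frame(curve = names(diags),
                         family = vapply(diags, `[[`, "", "family"),
                         converged = conv,
                         reason = vapply(diags, `[[`, "", "reason"),
                         rel_unc_end = rel_unc,
                         resid_norm = vapply(diags, `[[`, 0, "resid_norm"),
                         row.names = NULL)
  estimate_second(dual, ext,
                  diagnostics = list(fits = diags, table = diag_tbl),
                  status = if (ok) "ok" else "failed_separation")
}
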