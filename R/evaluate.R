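#' Absolute percentage difference
#'
#' \eqn{APD = |v_{test} - v_{ref}| / v_{ref} \times 100}. Vectorized;
#' scale-invariant in the sense `apd(c*a, c*b) == apd(a, b)` for `c > 0`.
#'
#' @param v_test,v_ref Test and reference values; `v_ref` must be > 0.
#' @return APD in percent (>= 0).
#' @export
apd <- function(v_test, v_ref) {
  if (any(!is.finite(v_ref)) || any(v_ref <= 0)) {
    stop("reference values must be positive and finite", call. = FALSE)
  }
  abs(v_test - v_ref) / v_ref * 100
}

#' Median/IQR summary of APD per region
#'
#' Aggregates per-subject APD values across subjects within each region,
#' reporting the median, the interquartile range (Q3 - Q1) and, since
#' aggregation conventions differ, also the mean. Quantiles use linear
#' interpolation (R type 7). Regions reduced to a single subject (after
#' failed-fit dropout) degenerate to median = value, IQR = 0.
#'
#' @param df data.frame with columns `roi` and `apd` (one row per subject and
#'   region).
#' @return data.frame with one row per region: `roi`, `median`, `iqr`,
#'   `mean`, `n`.
#' @export
summarize_apd <- function(df) {
  if (!all(c("roi", "apd") %in% names(df))) {
    stop("`df` needs columns roi and apd", call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty APD table", call. = FALSE)
  rois <- unique(df$roi)
  out <- do.call(rbind, lapply(rois, function(r) {
    v <- df$apd[df$roi == r]
    if (length(v) == 0) stop("empty APD group for region ", r, call. = FALSE)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(roi = r, median = q[2], iqr = q[3] - q[1], mean = mean(v),
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Pooled Pearson correlation between two V_T sets
#'
#' @param x,y Equal-length numeric vectors (>= 3 values, nonzero variance),
#'   typically V_T pooled over regions and subjects.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in correlation input", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in correlation input", call. = FALSE)
  }
  stats::cor(x, y)
}

# join two conditions of a V_T table into paired columns
pair_conditions <- function(vt, tracer, cond_test, cond_ref) {
  a <- vt[vt$tracer == tracer & vt$condition == cond_test,
          c("subject", "roi", "vt")]
  b <- vt[vt$tracer == tracer & vt$condition == cond_ref,
          c("subject", "roi", "vt")]
  m <- merge(a, b, by = c("subject", "roi"), suffixes = c("_test", "_ref"))
  m <- m[is.finite(m$vt_test) & is.finite(m$vt_ref), ]  # drop failed fits
  if (nrow(m) == 0) stop("no paired V_T values for tracer ", tracer,
                         " (", cond_test, " vs ", cond_ref, ")", call. = FALSE)
  m
}

#' Evaluation report for one injection order
#'
#' From a tidy V_T table (one injection order), computes the study's metrics:
#' per-region median/IQR APD of the estimated second tracer against its
#' 45-min single-tracer reference, per-region APD of each tracer's 45-min
#' against 90-min single data, pooled Pearson correlations (est vs 45; 90 vs
#' 45 per tracer), and per-region correlations as diagnostics.
#'
#' @param vt V_T table from [quantify_conditions()] (stacked over subjects).
#' @param first,second Tracer labels of the injection order.
#' @return An object of class `eval_report`.
#' @export
evaluate_order <- function(vt, first, second) {
  est <- pair_conditions(vt, second, "est", "single45")
  est$apd <- apd(est$vt_test, est$vt_ref)
  apd45 <- lapply(stats::setNames(c(first, second), c(first, second)),
                  function(tr) {
    p <- pair_conditions(vt, tr, "single45", "single90")
    p$apd <- apd(p$vt_test, p$vt_ref)
    p
  })
  per_roi_r <- do.call(rbind, lapply(unique(est$roi), function(r) {
    s <- est[est$roi == r, ]
    data.frame(roi = r,
               r = if (nrow(s) >= 3 && stats::sd(s$vt_test) > 0 &&
                       stats::sd(s$vt_ref) > 0)
                 pearson_r(s$vt_test, s$vt_ref) else NA_real_)
  }))
  structure(list(
    first = first, second = second,
    n_subjects = length(unique(vt$subject)),
    apd_est = summarize_apd(est[, c("roi", "apd")]),
    apd_45 = lapply(apd45, function(p) summarize_apd(p[, c("roi", "apd")])),
    r_est = pearson_r(est$vt_test, est$vt_ref),
    r_90_45 = vapply(apd45, function(p) pearson_r(p$vt_test, p$vt_ref),
                     numeric(1)),
    per_roi_r = per_roi_r,
    pairs_est = est
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s first, %s second (n = %d)\n", x$first,
              x$second, x$n_subjects))
  cat(sprintf("  pooled r(V_T %s est vs 45 min single): %.3f\n", x$second,
              x$r_est))
  for (tr in names(x$r_90_45)) {
    cat(sprintf("  pooled r(V_T %s 90 vs 45 min): %.3f\n", tr, x$r_90_45[[tr]]))
  }
  cat(sprintf("  median APD (%s est vs 45): %.1f%% across %d regions\n",
              x$second, stats::median(x$apd_est$median), nrow(x$apd_est)))
  invisible(x)
}
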