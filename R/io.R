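#' Write regional TACs to a tab-separated file
#'
#' Schema: `time_start_min  time_end_min  <ROI...>`, activities in kBq/mL,
#' times with 6 decimals. Point-sampled curves (e.g. the 5-s resampled grid)
#' are written with `time_start_min == time_end_min`; framed curves carry the
#' frame boundaries when a schedule is attached.
#'
#' @param tacs Named list of `pet_curve`s on a common grid.
#' @param path Output path.
#' @export
write_tac_file <- function(tacs, path) {
  if (length(tacs) == 0) stop("no curves to write", call. = FALSE)
  ref <- tacs[[1]]
  for (tc in tacs) {
    stopifnot_curve(tc)
    if (!same_grid(tc, ref)) stop("curves are not on a common grid", call. = FALSE)
  }
  sched <- attr(ref, "schedule")
  if (!is.null(sched)) {
    start <- sched$start; end <- sched$end
  } else {
    start <- end <- ref$times
  }
  df <- data.frame(time_start_min = sprintf("%.6f", start),
                   time_end_min = sprintf("%.6f", end))
  for (r in names(tacs)) df[[r]] <- sprintf("%.15g", tacs[[r]]$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regional TAC file
#'
#' Validates the schema of [write_tac_file()]; schema violations are reported
#' with the offending row.
#'
#' @param path File path.
#' @param tracer_label,injection_time Metadata attached to the curves.
#' @return Named list of `pet_curve`s (kind `"TAC"`), sampled at frame
#'   midpoints, column order preserved.
#' @export
read_tac_file <- function(path, tracer_label = NA_character_,
                          injection_time = 0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("time_start_min", "time_end_min")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  rois <- setdiff(names(df), need)
  if (length(rois) == 0) stop("no region columns found", call. = FALSE)
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  for (cn in names(num)) {
    bad <- which(!is.finite(num[[cn]]))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", cn, "', data row ", bad[1],
           call. = FALSE)
    }
  }
  mid <- (num$time_start_min + num$time_end_min) / 2
  if (any(diff(mid) <= 0)) {
    bad <- which(diff(mid) <= 0)[1]
    stop("times must be strictly increasing; violated at data row ", bad + 1,
         call. = FALSE)
  }
  stats::setNames(lapply(rois, function(r) {
    pet_curve(mid, num[[r]], kind = "TAC", tracer_label = tracer_label,
              injection_time = injection_time)
  }), rois)
}

#' Write arterial data to a tab-separated file
#'
#' Schema: `time_min  whole_blood  plasma  parent_fraction  input`
#' (kBq/mL except the dimensionless parent fraction).
#'
#' @param times Sample times (min).
#' @param whole_blood,plasma,input Activity vectors (kBq/mL).
#' @param parent_fraction Fraction vector in \[0, 1\].
#' @param path Output path.
#' @export
write_aif_file <- function(times, whole_blood, plasma, parent_fraction,
                           input, path) {
  n <- length(times)
  if (!all(lengths(list(whole_blood, plasma, parent_fraction, input)) == n)) {
    stop("all columns must have the length of `times`", call. = FALSE)
  }
  df <- data.frame(time_min = sprintf("%.6f", times),
                   whole_blood = sprintf("%.15g", whole_blood),
                   plasma = sprintf("%.15g", plasma),
                   parent_fraction = sprintf("%.15g", parent_fraction),
                   input = sprintf("%.15g", input))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an arterial data file
#'
#' @param path File path.
#' @param tracer_label,injection_time Metadata attached to the curves.
#' @return List of `pet_curve`s: `whole_blood`, `plasma`, `parent_fraction`,
#'   `input`.
#' @export
read_aif_file <- function(path, tracer_label = NA_character_,
                          injection_time = 0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("time_min", "whole_blood", "plasma", "parent_fraction", "input")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  num <- lapply(df[need], function(col) suppressWarnings(as.numeric(col)))
  for (cn in names(num)) {
    bad <- which(!is.finite(num[[cn]]))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", cn, "', data row ", bad[1],
           call. = FALSE)
    }
  }
  if (any(num$parent_fraction < 0 | num$parent_fraction > 1)) {
    stop("parent_fraction outside [0, 1]", call. = FALSE)
  }
  kinds <- c(whole_blood = "whole_blood", plasma = "plasma",
             parent_fraction = "parent_fraction", input = "input")
  stats::setNames(lapply(names(kinds), function(cn) {
    pet_curve(num$time_min, num[[cn]], kind = kinds[[cn]],
              tracer_label = tracer_label, injection_time = injection_time)
  }), names(kinds))
}

#' Default run configuration
#'
#' Every tunable of the pipeline in one serializable structure: cohort
#' parameters, protocol, separation, quantification and evaluation settings,
#' and the seed. Round-trips losslessly through YAML.
#'
#' @param seed Base seed.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    report_version = 1L,
    seed = as.integer(seed),
    cohort = list(n_pairs = 8L, dose_per_kg = list(HAR = 4.66, DASB = 4.51),
                  weight_mean = 75, weight_sd = 8, noise_scale = 0.3,
                  vB_range = c(0.02, 0.04)),
    protocol = list(stagger = 45, total_duration = 90,
                    orders = list(c("HAR", "DASB"), c("DASB", "HAR"))),
    separation = list(tac_family = "2tcm", aif_family = "exp3",
                      t_fit_start_offset = 3, max_rel_unc = 0.2),
    quantify = list(t_star = list(HAR = 20, DASB = 30)),
    evaluate = list(quantile_type = 7L)
  ), class = "run_config")
}

#' Write / read a run configuration (YAML)
#' @param config A `run_config` list.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Write a protocol-comparison report as versioned JSON
#'
#' Serializes both injection orders' pooled correlations and per-region APD
#' tables (Median/IQR layout) with a `report_version` field.
#'
#' @param comparison A `protocol_comparison` from
#'   [run_protocol_comparison()].
#' @param path Output path.
#' @export
write_eval_report <- function(comparison, path) {
  if (!inherits(comparison, "protocol_comparison")) {
    stop("`comparison` must be a protocol_comparison", call. = FALSE)
  }
  one <- function(run) {
    rep <- run$report
    list(first = rep$first, second = rep$second,
         n_subjects = rep$n_subjects,
         r_est_vs_45 = rep$r_est,
         r_90_vs_45 = as.list(rep$r_90_45),
         apd_est = rep$apd_est,
         apd_45 = rep$apd_45,
         failed_fraction = run$failed_fraction)
  }
  jsonlite::write_json(
    list(report_version = 1L, stagger = comparison$stagger,
         seed = comparison$seed, flagged = comparison$flagged,
         quantile_type = 7L,
         har_first = one(comparison$har_first),
         dasb_first = one(comparison$dasb_first)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
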