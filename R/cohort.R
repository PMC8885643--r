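#' The 13 analysis regions
#'
#' Thalamus, frontal/occipital/parietal/temporal cortex, anterior cingulate,
#' insula, hippocampus, olfactory cortex, caudate, putamen, striatum,
#' cerebellar grey matter.
#' @export
ROI_NAMES <- c("THA", "FRO", "OCC", "PAR", "TMP", "ACC", "INS", "HIP",
               "OLF", "CAU", "PUT", "STR", "CRB")

#' Region-level kinetic means of the two synthetic tracers
#'
#' Mean 2TCM rate constants per region for the fast, harmine-like tracer
#' (`HAR`) and the slow, DASB-like tracer (`DASB`). The fast tracer's k2 is
#' 2.5x the slow tracer's, encoding the faster washout that motivates giving
#' it first in a staggered protocol. Binding (k3/k4) is comparatively uniform
#' across cortex for the MAO-A-like target and strongly enriched in thalamus
#' and striatum for the SERT-like target, with near-reference cerebellum.
#'
#' @return data.frame with columns `tracer`, `roi`, `K1`, `k2`, `k3`, `k4`.
#' @export
kinetic_prior_table <- function() {
  bp_har <- c(THA = 2.2, FRO = 1.8, OCC = 1.6, PAR = 1.7, TMP = 1.8,
              ACC = 1.9, INS = 2.0, HIP = 1.9, OLF = 1.8, CAU = 1.7,
              PUT = 1.8, STR = 1.8, CRB = 1.0)
  bp_dasb <- c(THA = 1.8, FRO = 0.5, OCC = 0.5, PAR = 0.5, TMP = 0.6,
               ACC = 0.8, INS = 1.0, HIP = 0.9, OLF = 0.9, CAU = 1.3,
               PUT = 1.5, STR = 1.4, CRB = 0.2)
  rbind(
    data.frame(tracer = "HAR", roi = ROI_NAMES, K1 = 0.40, k2 = 0.25,
               k3 = bp_har[ROI_NAMES] * 0.08, k4 = 0.08, row.names = NULL),
    data.frame(tracer = "DASB", roi = ROI_NAMES, K1 = 0.35, k2 = 0.10,
               k3 = bp_dasb[ROI_NAMES] * 0.06, k4 = 0.06, row.names = NULL)
  )
}

#' Cohort generation settings
#'
#' Study conditions of the synthetic cohort: per-kg doses of the two tracers,
#' body-weight distribution, between-subject log-normal spread of the kinetic
#' rates and blood parameters, blood-volume range, frame schedule, and the
#' TAC noise magnitude.
#'
#' @param dose_per_kg Named per-kg doses (MBq/kg): 4.66 for the fast tracer,
#'   4.51 for the slow one.
#' @param weight_mean,weight_sd Body weight distribution (kg).
#' @param sdlog Named log-normal sd of subject-level multipliers on `K1`,
#'   `k2`, `k4`, the binding ratio `bp = k3/k4`, the input-curve amplitude
#'   (`amp`), and the parent-fraction half-time (`t50`).
#' @param vB_range Uniform range of fractional blood volume.
#' @param noise_scale TAC frame-noise magnitude (see [frame_and_noise()]).
#' @param fine_step Generation grid step (min); default 1 s.
#' @param duration Scan length (min).
#' @param schedule Frame schedule.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(dose_per_kg = c(HAR = 4.66, DASB = 4.51),
                          weight_mean = 75, weight_sd = 8,
                          sdlog = c(K1 = 0.12, k2 = 0.10, k4 = 0.08,
                                    bp = 0.15, amp = 0.10, t50 = 0.10),
                          vB_range = c(0.02, 0.04),
                          noise_scale = 0.3,
                          fine_step = 1 / 60,
                          duration = 90,
                          schedule = default_frame_schedule()) {
  structure(list(dose_per_kg = dose_per_kg, weight_mean = weight_mean,
                 weight_sd = weight_sd, sdlog = sdlog, vB_range = vB_range,
                 noise_scale = noise_scale, fine_step = fine_step,
                 duration = duration, schedule = schedule),
            class = "cohort_config")
}

# tracer-level blood/metabolism defaults
tracer_blood_defaults <- function(label) {
  switch(label,
    HAR = list(input = input_function_model(t0 = 0.5, A1 = 600, A2 = 12,
                                            A3 = 10, l1 = -4, l2 = -0.25,
                                            l3 = -0.012),
               pf = parent_fraction_model(p_inf = 0.15, t50 = 12, h = 1.6),
               pwb_ratio = 1.1),
    DASB = list(input = input_function_model(t0 = 0.5, A1 = 650, A2 = 14,
                                             A3 = 9, l1 = -4, l2 = -0.30,
                                             l3 = -0.015),
                pf = parent_fraction_model(p_inf = 0.30, t50 = 25, h = 1.8),
                pwb_ratio = 0.9),
    stop("unknown tracer label: ", label, call. = FALSE)
  )
}

scale_input_model <- function(model, factor) {
  input_function_model(t0 = model$t0, A1 = model$A1 * factor,
                       A2 = model$A2 * factor, A3 = model$A3 * factor,
                       l1 = model$l1, l2 = model$l2, l3 = model$l3)
}

#' Generate a matched synthetic cohort
#'
#' Draws `n_pairs` subjects, each carrying both tracers' per-region tissue
#' models, input-function and parent-fraction models, body weight and injected
#' doses (`dose_per_kg x weight`, deterministic given weight). Subject-level
#' variation is multiplicative log-normal on the kinetic rates and on the
#' input-curve amplitude; blood volume is uniform within `vB_range`.
#' Deterministic under `seed`.
#'
#' @param n_pairs Number of matched subjects (a subject stands for one matched
#'   pair of single-tracer scans); default 8.
#' @param seed Integer seed.
#' @param config A [cohort_config()].
#' @return List of `dual_subject` objects (class `dual_cohort`).
#' @export
make_cohort <- function(n_pairs = 8, seed = 1, config = cohort_config()) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config", call. = FALSE)
  }
  set.seed(seed)
  priors <- kinetic_prior_table()
  sdl <- config$sdlog
  subjects <- lapply(seq_len(n_pairs), function(i) {
    weight <- min(max(stats::rnorm(1, config$weight_mean, config$weight_sd), 50), 110)
    vB <- stats::runif(1, config$vB_range[1], config$vB_range[2])
    tracers <- lapply(c("HAR", "DASB"), function(label) {
      base <- tracer_blood_defaults(label)
      pr <- priors[priors$tracer == label, ]
      mK1 <- stats::rlnorm(1, 0, sdl["K1"])
      mk2 <- stats::rlnorm(1, 0, sdl["k2"])
      mk4 <- stats::rlnorm(1, 0, sdl["k4"])
      tissue <- stats::setNames(lapply(seq_len(nrow(pr)), function(j) {
        bp <- pr$k3[j] / pr$k4[j] * stats::rlnorm(1, 0, sdl["bp"])
        k4 <- pr$k4[j] * mk4
        tissue_model("2TCM", K1 = pr$K1[j] * mK1, k2 = pr$k2[j] * mk2,
                     k3 = bp * k4, k4 = k4, vB = vB)
      }), pr$roi)
      amp <- stats::rlnorm(1, 0, sdl["amp"])
      pf <- base$pf
      pf$t50 <- pf$t50 * stats::rlnorm(1, 0, sdl["t50"])
      list(label = label,
           dose_mbq = unname(config$dose_per_kg[label]) * weight,
           input_model = scale_input_model(base$input, amp),
           pf_model = pf,
           pwb_ratio = base$pwb_ratio,
           tissue = tissue,
           vt_true = vapply(tissue, analytic_vt, numeric(1)))
    })
    names(tracers) <- c("HAR", "DASB")
    structure(list(subject_id = sprintf("S%02d", i), weight = weight,
                   vB = vB, tracers = tracers),
              class = "dual_subject")
  })
  structure(subjects, class = "dual_cohort", seed = seed, config = config)
}

#' Simulate one single-tracer dynamic scan of a cohort subject
#'
#' Evaluates the subject's plasma model on the fine grid, derives whole blood
#' (plasma / plasma-to-whole-blood ratio) and the metabolite-corrected input,
#' convolves each region's tissue model into a noiseless TAC, and frames the
#' TACs with count-like noise. Blood curves are kept noiseless: arterial data
#' are far less noisy than framed ROI means and the study's separation step is
#' stressed through the TACs.
#'
#' @param subject A `dual_subject` from [make_cohort()].
#' @param tracer `"HAR"` or `"DASB"`.
#' @param config A [cohort_config()] (noise scale, framing, grids).
#' @param seed Optional integer seed for the frame noise.
#' @return A `single_scan`: fine-grid blood curves and noiseless TACs, framed
#'   noisy TACs, and the generating truth (models, analytic V_T).
#' @export
generate_single_scan <- function(subject, tracer, config = cohort_config(),
                                 seed = NULL) {
  if (!inherits(subject, "dual_subject")) {
    stop("`subject` must be a dual_subject", call. = FALSE)
  }
  tr <- subject$tracers[[tracer]]
  if (is.null(tr)) stop("subject carries no tracer ", tracer, call. = FALSE)
  times <- uniform_grid(config$duration, config$fine_step)
  plasma <- eval_input_function(tr$input_model, times, tracer_label = tracer)
  wb <- pet_curve(times, plasma$values / tr$pwb_ratio, kind = "whole_blood",
                  tracer_label = tracer)
  pf <- eval_parent_fraction(tr$pf_model, times)
  input <- apply_parent_fraction(plasma, parent_fraction_model(
    p_inf = tr$pf_model$p_inf, t50 = tr$pf_model$t50, h = tr$pf_model$h))
  tacs_true <- lapply(tr$tissue, function(m) tissue_tac(m, input, wb))
  if (!is.null(seed)) set.seed(seed)
  tacs <- lapply(tacs_true, function(tc) {
    frame_and_noise(tc, config$schedule, noise_scale = config$noise_scale)
  })
  structure(list(subject_id = subject$subject_id, tracer = tracer,
                 dose_mbq = tr$dose_mbq,
                 fine = list(times = times, plasma = plasma, whole_blood = wb,
                             parent_fraction = pf, input = input),
                 tacs_true = tacs_true, tacs = tacs,
                 truth = list(models = tr$tissue, vt = tr$vt_true)),
            class = "single_scan")
}

#' Resample a single scan onto the 5-s dual-tracer grid
#'
#' @param scan A `single_scan`.
#' @param step Grid step (min); default 5 s.
#' @param duration Grid end (min); default the scan duration.
#' @param use_true_tacs Resample the noiseless fine TACs instead of the framed
#'   noisy ones (ground-truth mode).
#' @return A `scan_curves` list: `aif` (metabolite-corrected input) and `tacs`
#'   (named list over regions), all on the common uniform grid.
#' @export
resample_scan <- function(scan, step = DUAL_GRID_STEP, duration = NULL,
                          use_true_tacs = FALSE) {
  if (!inherits(scan, "single_scan")) {
    stop("`scan` must be a single_scan", call. = FALSE)
  }
  if (is.null(duration)) duration <- max(scan$fine$times)
  src <- if (use_true_tacs) scan$tacs_true else scan$tacs
  structure(list(
    subject_id = scan$subject_id, tracer = scan$tracer,
    aif = resample_uniform(scan$fine$input, step, duration),
    whole_blood = resample_uniform(scan$fine$whole_blood, step, duration),
    tacs = lapply(src, resample_uniform, step = step, duration = duration)
  ), class = "scan_curves")
}
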