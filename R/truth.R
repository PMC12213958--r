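#' Study design parameters
#'
#' Defaults follow the recording protocol the pipeline targets: 512 Hz
#' sampling, epochs from -100 to 1500 ms around stimulus onset, and two
#' encoding-trial conditions (subsequent source memory correct/incorrect)
#' with 40 trials each.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_condition Trials per condition per subject.
#' @param fs_hz Sampling rate (Hz).
#' @param epoch_ms Epoch window `c(start, end)` in ms relative to onset.
#' @param master_seed Master seed; per-subject seeds are derived from it.
#' @return `smeloc_design` list.
#' @export
study_design <- function(n_subjects = 20L, n_trials_per_condition = 40L,
                         fs_hz = 512, epoch_ms = c(-100, 1500),
                         master_seed = 1L) {
  if (n_subjects < 1L) stopf("empty study: n_subjects must be >= 1")
  if (n_trials_per_condition < 1L) stopf("n_trials_per_condition must be >= 1")
  if (fs_hz <= 0) stopf("sampling rate must be positive")
  if (epoch_ms[2] <= epoch_ms[1]) stopf("epoch window must be increasing")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 fs_hz = fs_hz, epoch_ms = as.numeric(epoch_ms),
                 master_seed = as.integer(master_seed),
                 conditions = c("source_correct", "source_incorrect")),
            class = "smeloc_design")
}

#' Ground-truth record for the synthetic study
#'
#' Defines where and how condition effects are planted. Each effect ROI
#' contributes `sources_per_roi` active grid points whose dipole moments
#' follow the component time course (Gaussian P2 bump with a preceding
#' N1-like trough, logistic-onset LSW plateau). Per subject, the condition
#' amplitude difference in a given (component, ROI) is `diff + delta` with
#' `delta ~ N(0, effect_sd)` drawn independently per ROI, so the planted
#' standardized effect size is `d = (amp[1] - amp[2]) / effect_sd` per ROI
#' (0.8 under the defaults), and subjects vary region by region in how
#' strongly they express the effect.
#'
#' @param masks A [make_roi_masks()] mask set; effect ROIs must be mask keys.
#' @param p2_rois,lsw_rois Mask keys carrying the condition effect for each
#'   component. Defaults: P2 in all six left medial-temporal masks plus
#'   "OFG"; LSW in left EC, left rostral/caudal PhG and left medial PPHC.
#' @param p2_amp,lsw_amp Length-2 `c(correct, incorrect)` population mean
#'   moment amplitudes in nA·m.
#' @param effect_sd Between-subject SD of the condition difference (nA·m).
#' @param sources_per_roi Active grid points per effect ROI.
#' @param p2_latency_ms,p2_fwhm_ms P2 bump center (population) and width.
#' @param latency_jitter_sd_ms Between-subject SD of the P2 peak latency.
#' @param lsw_onset_ms,lsw_rise_ms Logistic onset center and rise constant.
#' @param noise_white_uv,noise_pink_uv,pink_exponent Sensor-noise mix: white
#'   SD, 1/f SD and spectral exponent.
#' @param artifact_fraction Fraction of trials receiving a high-amplitude
#'   low-frequency artifact; @param artifact_amp_uv its amplitude.
#' @param subject_amp_cv Between-subject CV of overall source amplitude.
#' @param trial_amp_cv Within-subject trial-to-trial amplitude CV.
#' @return `smeloc_truth` list; `active_sources` is a data.frame with one
#'   row per (grid index, component).
#' @export
make_ground_truth <- function(masks,
                              p2_rois = c(paste("left", mtl_roi_names()), "OFG"),
                              lsw_rois = c("left EC", "left rostral PhG",
                                           "left caudal PhG", "left medial PPHC"),
                              p2_amp = c(45, 33), lsw_amp = c(42, 30),
                              effect_sd = 15, sources_per_roi = 3L,
                              p2_latency_ms = 190, p2_fwhm_ms = 50,
                              latency_jitter_sd_ms = 15,
                              lsw_onset_ms = 1050, lsw_rise_ms = 40,
                              noise_white_uv = 6, noise_pink_uv = 6,
                              pink_exponent = 1,
                              artifact_fraction = 0.05,
                              artifact_amp_uv = 350,
                              subject_amp_cv = 0.15, trial_amp_cv = 0.2) {
  stopifnot(inherits(masks, "smeloc_roi_masks"))
  all_keys <- names(masks$masks)
  missing <- setdiff(c(p2_rois, lsw_rois), all_keys)
  if (length(missing))
    stopf("effect ROIs not in the mask set: %s", paste(missing, collapse = ", "))
  if (any(c(p2_amp, lsw_amp) < 0)) stopf("amplitudes must be >= 0")
  if (artifact_fraction < 0 || artifact_fraction >= 1)
    stopf("artifact fraction must be in [0, 1)")
  pick <- function(key) {
    idx <- masks$masks[[key]]$indices
    idx[seq_len(min(sources_per_roi, length(idx)))]
  }
  rows <- list()
  for (key in p2_rois)
    rows[[length(rows) + 1L]] <- data.frame(
      grid_index = pick(key), component = "P2", roi = key,
      amp_correct = p2_amp[1], amp_incorrect = p2_amp[2])
  for (key in lsw_rois)
    rows[[length(rows) + 1L]] <- data.frame(
      grid_index = pick(key), component = "LSW", roi = key,
      amp_correct = lsw_amp[1], amp_incorrect = lsw_amp[2])
  structure(list(
    active_sources = do.call(rbind, rows),
    effect_rois = list(P2 = p2_rois, LSW = lsw_rois),
    effect_sd = effect_sd,
    planted_d = c(P2 = unname(p2_amp[1] - p2_amp[2]) / effect_sd,
                  LSW = unname(lsw_amp[1] - lsw_amp[2]) / effect_sd),
    p2_latency_ms = p2_latency_ms, p2_fwhm_ms = p2_fwhm_ms,
    latency_jitter_sd_ms = latency_jitter_sd_ms,
    lsw_onset_ms = lsw_onset_ms, lsw_rise_ms = lsw_rise_ms,
    noise_white_uv = noise_white_uv, noise_pink_uv = noise_pink_uv,
    pink_exponent = pink_exponent,
    artifact_fraction = artifact_fraction, artifact_amp_uv = artifact_amp_uv,
    subject_amp_cv = subject_amp_cv, trial_amp_cv = trial_amp_cv,
    orientation_rule = "radial, sign set for frontal positivity"
  ), class = "smeloc_truth")
}

#' A null-effect copy of a ground truth
#'
#' Sets the condition amplitudes of every active source equal (at the mean
#' of the pair) and the between-subject effect SD unchanged, so no ROI has
#' a planted condition difference.
#' @param truth A [make_ground_truth()] object.
#' @return A `smeloc_truth` with zero condition effects.
#' @export
null_truth <- function(truth) {
  a <- (truth$active_sources$amp_correct + truth$active_sources$amp_incorrect) / 2
  truth$active_sources$amp_correct <- a
  truth$active_sources$amp_incorrect <- a
  truth$planted_d <- c(P2 = 0, LSW = 0)
  truth
}

#' Write / read a ground-truth record as JSON
#' @param truth Truth record; @param path JSON path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the record.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$active_sources <- as.data.frame(x$active_sources)
  x$planted_d <- unlist(x$planted_d)
  structure(x, class = "smeloc_truth")
}
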