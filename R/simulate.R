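# Synthetic multi-subject study engine: planted P2/LSW dipole sources with
# condition-dependent amplitudes, projected through the lead field, plus
# 1/f + white sensor noise and occasional high-amplitude artifact trials.

# Component source time courses on a millisecond grid, unit peak amplitude.
# The P2 course carries a preceding N1-like negativity so that the fixed
# 130-140 ms re-baseline interval falls in the trough between components,
# as it does in real ERPs.
p2_timecourse <- function(times_ms, latency_ms, fwhm_ms,
                          n1_latency_ms = 115, n1_fwhm_ms = 35,
                          n1_rel_amp = 0.5) {
  s <- fwhm_ms / (2 * sqrt(2 * log(2)))
  sn <- n1_fwhm_ms / (2 * sqrt(2 * log(2)))
  exp(-(times_ms - latency_ms)^2 / (2 * s^2)) -
    n1_rel_amp * exp(-(times_ms - n1_latency_ms)^2 / (2 * sn^2))
}

lsw_timecourse <- function(times_ms, onset_ms, rise_ms) {
  stats::plogis((times_ms - onset_ms) / rise_ms)
}

# Unit-variance 1/f^beta noise, one column per channel/trial, via spectral
# shaping of white noise. Theoretical (Parseval) normalisation keeps the
# scale independent of the number of columns.
pink_noise <- function(n, m, fs_hz, beta = 1) {
  nf <- stats::nextn(n, 2)               # power-of-two synthesis length
  w <- matrix(stats::rnorm(nf * m), nf, m)
  W <- stats::mvfft(w)
  k <- seq_len(nf) - 1
  f <- pmin(k, nf - k) * fs_hz / nf
  g <- c(0, f[-1]^(-beta / 2))
  g <- g / sqrt(mean(g^2))
  out <- Re(stats::mvfft(W * g, inverse = TRUE)) / nf
  out[seq_len(n), , drop = FALSE]
}

#' Simulate one subject's epoched EEG
#'
#' Realizes the ground truth for a single subject: draws the subject's P2
#' peak latency, overall amplitude scale and component-wise condition-effect
#' deviation; builds per-condition clean scalp signals by projecting the
#' active sources (radial orientation, sign fixed for frontal positivity)
#' through the lead field; then adds trial amplitude jitter, sensor noise
#' and planted artifact trials. All randomness derives from `subject_seed`.
#'
#' @param design A [study_design()].
#' @param montage,source_space,masks,truth,leadfield Study-level objects;
#'   the lead field must match the montage channel count.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier stored in the epochs.
#' @return An [epochs_set()] with an extra `subject_truth` element recording
#'   the realized latency, amplitude scale, per-component condition
#'   difference, and planted artifact trial indices.
#' @export
simulate_subject <- function(design, montage, source_space, masks, truth,
                             leadfield, subject_seed, subject_id = "sub-01") {
  stopifnot(inherits(design, "smeloc_design"), inherits(truth, "smeloc_truth"),
            inherits(leadfield, "smeloc_leadfield"))
  ne <- length(montage$labels)
  if (nrow(leadfield$gain) != ne)
    stopf("lead field has %d channels but montage has %d",
          nrow(leadfield$gain), ne)
  set.seed(subject_seed)
  fs <- design$fs_hz
  t0 <- design$epoch_ms[1]
  nsamp <- as.integer(round(diff(design$epoch_ms) * fs / 1000)) + 1L
  times <- epoch_times_ms(fs, t0, nsamp)
  npc <- design$n_trials_per_condition
  ntot <- 2L * npc

  lat <- min(240, max(130, truth$p2_latency_ms +
                        stats::rnorm(1) * truth$latency_jitter_sd_ms))
  s_i <- max(0.2, 1 + stats::rnorm(1) * truth$subject_amp_cv)

  src <- truth$active_sources
  # one effect deviation per (component, ROI): subjects vary independently
  # in how strongly each region expresses the condition effect
  eff_key <- paste(src$component, src$roi)
  delta_roi <- stats::setNames(stats::rnorm(length(unique(eff_key)), 0,
                                            truth$effect_sd),
                               unique(eff_key))
  tc <- rbind(P2 = p2_timecourse(times, lat, truth$p2_fwhm_ms),
              LSW = lsw_timecourse(times, truth$lsw_onset_ms,
                                   truth$lsw_rise_ms))
  # scalp pattern per active source (radial orientation, frontal-positive)
  frontal <- which(montage$coronal == "frontal")
  pat <- matrix(0, ne, nrow(src))
  g <- source_space$grid_positions
  for (r in seq_len(nrow(src))) {
    j <- src$grid_index[r]
    p <- g[j, ]
    o <- if (vec_norm(p) == 0) c(0, 0, 1) else p / vec_norm(p)
    v <- leadfield$gain[, (3L * j - 2L):(3L * j)] %*% o
    if (mean(v[frontal]) < 0) v <- -v
    pat[, r] <- v
  }
  amp_inc <- src$amp_incorrect * s_i
  amp_cor <- pmax(0, amp_inc + (src$amp_correct - src$amp_incorrect) +
                    delta_roi[eff_key])
  clean <- list(
    source_correct = pat %*% (amp_cor * tc[src$component, , drop = FALSE]),
    source_incorrect = pat %*% (amp_inc * tc[src$component, , drop = FALSE]))
  realized_diff <- c(
    P2 = if (any(src$component == "P2"))
      mean((amp_cor - amp_inc)[src$component == "P2"]) else 0,
    LSW = if (any(src$component == "LSW"))
      mean((amp_cor - amp_inc)[src$component == "LSW"]) else 0)

  condition <- sample(rep(design$conditions, each = npc))
  u <- pmax(0, 1 + stats::rnorm(ntot) * truth$trial_amp_cv)
  data <- array(0, c(ntot, ne, nsamp))
  for (tr in seq_len(ntot))
    data[tr, , ] <- u[tr] * clean[[condition[tr]]]

  if (truth$noise_white_uv > 0)
    data <- data + array(stats::rnorm(length(data), 0, truth$noise_white_uv),
                         dim(data))
  if (truth$noise_pink_uv > 0) {
    pn <- pink_noise(nsamp, ntot * ne, fs, truth$pink_exponent)
    data <- data + truth$noise_pink_uv *
      aperm(array(pn, c(nsamp, ne, ntot)), c(3, 2, 1))
  }

  k_art <- as.integer(round(truth$artifact_fraction * ntot))
  art_trials <- if (k_art > 0) sort(sample(ntot, k_art)) else integer(0)
  if (k_art > 0) {
    topo <- montage$positions[, 2] / montage$r_shell
    wave <- truth$artifact_amp_uv * sin(2 * pi * 1.25 * (times - t0) / 1000)
    art <- outer(topo, wave)
    for (tr in art_trials) data[tr, , ] <- data[tr, , ] + art
  }

  ep <- epochs_set(data, condition, fs, t0, montage$labels, subject_id,
                   subject_seed)
  ep$subject_truth <- list(p2_latency_ms = lat, amp_scale = s_i,
                           condition_diff_nam = realized_diff,
                           artifact_trials = art_trials)
  ep
}

#' Simulate and write a full study to disk
#'
#' Writes one directory per subject (float32 epochs + JSON sidecar), the
#' montage (.sfp), masks and truth (JSON), and a manifest recording the
#' design, per-subject seeds and file hashes. Rerunning with the same
#' master seed reproduces byte-identical arrays.
#'
#' @param design A [study_design()].
#' @param out_dir Output directory; must not already contain a study unless
#'   `overwrite = TRUE`.
#' @param head,montage,source_space,masks,truth Study-level objects;
#'   defaults are built when omitted.
#' @param leadfield Optional precomputed lead field.
#' @param overwrite Allow writing over an existing study directory.
#' @return Invisibly, the manifest list.
#' @export
simulate_study <- function(design, out_dir, head = make_head(),
                           montage = make_montage(head),
                           source_space = make_source_space(head, spacing = 0.012),
                           masks = make_roi_masks(source_space),
                           truth = make_ground_truth(masks),
                           leadfield = NULL, overwrite = FALSE) {
  stopifnot(inherits(design, "smeloc_design"))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stopf("output directory already holds a study; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(leadfield)) leadfield <- compute_leadfield(head, source_space, montage)

  write_sfp(montage, file.path(out_dir, "montage.sfp"))
  write_roi_masks(masks, file.path(out_dir, "masks.json"))
  write_truth(truth, file.path(out_dir, "truth.json"))

  seeds <- vapply(seq_len(design$n_subjects), function(i)
    derive_seed(design$master_seed, i), integer(1))
  subjects <- sprintf("sub-%02d", seq_len(design$n_subjects))
  for (i in seq_len(design$n_subjects)) {
    sd <- file.path(out_dir, subjects[i])
    dir.create(sd, showWarnings = FALSE)
    ep <- simulate_subject(design, montage, source_space, masks, truth,
                           leadfield, seeds[i], subjects[i])
    write_epochs(ep, file.path(sd, "epochs"))
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", out_dir, "/?"), "", names(hashes))
  manifest <- list(design = unclass(design), subjects = subjects,
                   subject_seeds = seeds, hash_algo = "md5",
                   hashes = as.list(hashes))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
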