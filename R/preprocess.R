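# Scalp preprocessing: bad-channel detection, Perrin-style spherical-spline
# interpolation, zero-phase band-pass filtering, amplitude-based trial
# rejection, average re-referencing, and subject inclusion rules.

#' Preprocessing configuration
#'
#' Defaults mirror the target recording pipeline: 0.1-30 Hz band-pass,
#' -100..1500 ms epochs, +/-200 μV rejection, at most 8 interpolated
#' channels, at least 10 trials per condition for inclusion, average
#' reference.
#'
#' @param highpass_hz,lowpass_hz Band edges in Hz.
#' @param reject_uv Absolute rejection threshold in μV.
#' @param max_bad_channels Maximum interpolated channels before exclusion.
#' @param min_trials_per_condition Inclusion threshold after rejection.
#' @param reference Only "average" is supported.
#' @return `smeloc_preproc_config` list.
#' @export
preproc_config <- function(highpass_hz = 0.1, lowpass_hz = 30,
                           reject_uv = 200, max_bad_channels = 8L,
                           min_trials_per_condition = 10L,
                           reference = "average") {
  if (highpass_hz <= 0 || lowpass_hz <= highpass_hz)
    stopf("need 0 < highpass < lowpass")
  if (reject_uv <= 0) stopf("rejection threshold must be positive")
  if (reference != "average") stopf("only the average reference is supported")
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 reject_uv = reject_uv,
                 max_bad_channels = as.integer(max_bad_channels),
                 min_trials_per_condition = as.integer(min_trials_per_condition),
                 reference = reference),
            class = "smeloc_preproc_config")
}

#' Detect bad channels
#'
#' Channel health is judged on the noise a channel carries, not on the
#' evoked signal: per channel, the across-trial mean waveform is removed
#' (when more than one trial is available) and the variance of the residual
#' is summarized. Flatline channels (raw variance below `flat_floor`) are
#' flagged directly; otherwise a channel is flagged when its log residual
#' variance has a robust z score (median/MAD across channels) above
#' `z_limit` *and* the residual variance deviates from the channel median
#' by more than `ratio_limit`-fold (gain faults are order-of-magnitude
#' outliers; the guard keeps the z score from firing on the small spread of
#' clean data). Deterministic.
#'
#' @param epochs An [epochs_set()].
#' @param flat_floor Variance floor in μV² (default 1e-12).
#' @param z_limit Robust z threshold on log residual variance (default 5).
#' @param ratio_limit Minimum fold-change of residual variance against the
#'   channel median (default 4).
#' @return Integer vector of bad channel indices (possibly empty).
#' @export
detect_bad_channels <- function(epochs, flat_floor = 1e-12, z_limit = 5,
                                ratio_limit = 4) {
  d <- dim(epochs$data)
  if (d[2] < 8L) stopf("bad-channel detection expects at least 8 channels")
  chan_var <- function(ch, residual) {
    x <- epochs$data[, ch, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = d[1])
    if (residual && d[1] > 1L) x <- sweep(x, 2, colMeans(x))
    stats::var(as.vector(x))
  }
  v_raw <- vapply(seq_len(d[2]), chan_var, numeric(1), residual = FALSE)
  flat <- v_raw < flat_floor
  if (all(flat)) return(integer(0))   # no reference distribution to flag against
  v <- vapply(seq_len(d[2]), chan_var, numeric(1), residual = TRUE)
  lv <- log(pmax(v, flat_floor))
  med <- stats::median(lv[!flat])
  madv <- stats::mad(lv[!flat])
  z <- if (is.finite(madv) && madv > 0) abs(lv - med) / madv else rep(0, d[2])
  medv <- stats::median(v[!flat])
  extreme <- v > ratio_limit * medv | v < medv / ratio_limit
  sort(which(flat | (!flat & z > z_limit & extreme)))
}

# Perrin (1989)-style spherical spline basis: g(x) with order m and L terms.
spline_g <- function(x, m = 4, L = 50L) {
  n <- seq_len(L)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  P <- legendre_table(L, pmin(1, pmax(-1, x)))$P
  drop(crossprod(P, coef)) / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Fits a spherical spline (order m = 4, 50 Legendre terms, ridge
#' regularization 1e-5) to the good channels at every sample and replaces
#' the bad channels with the spline prediction. Good channels are returned
#' untouched.
#'
#' @param epochs An [epochs_set()].
#' @param montage The matching [make_montage()].
#' @param bad_channels Integer indices to rebuild; at least 4 good channels
#'   must remain.
#' @param lambda Ridge regularization (default 1e-5).
#' @return The epochs with interpolated channels.
#' @export
interpolate_channels <- function(epochs, montage, bad_channels,
                                 lambda = 1e-5) {
  if (!length(bad_channels)) return(epochs)
  d <- dim(epochs$data)
  bad <- sort(unique(as.integer(bad_channels)))
  if (any(bad < 1 | bad > d[2])) stopf("bad channel index out of range")
  good <- setdiff(seq_len(d[2]), bad)
  if (length(good) < 4L) stopf("fewer than 4 good channels remain")
  U <- unit_rows(montage$positions)
  Ggg <- matrix(spline_g(tcrossprod(U[good, , drop = FALSE])),
                length(good), length(good))
  Gbg <- matrix(spline_g(U[bad, , drop = FALSE] %*% t(U[good, , drop = FALSE])),
                length(bad), length(good))
  A <- rbind(cbind(Ggg + lambda * diag(length(good)), 1),
             c(rep(1, length(good)), 0))
  # data at good channels: (good x (trials*samples))
  X <- matrix(aperm(epochs$data[, good, , drop = FALSE], c(2, 1, 3)),
              nrow = length(good))
  sol <- solve(A, rbind(X, 0))
  pred <- Gbg %*% sol[seq_along(good), , drop = FALSE] +
    rep(1, length(bad)) %o% sol[length(good) + 1L, ]
  for (i in seq_along(bad))
    epochs$data[, bad[i], ] <- matrix(pred[i, ], d[1], d[3])
  epochs
}

# Zero-phase band-pass: linear-phase FIR (signal::fir1, Hamming window)
# applied by FFT convolution with reflection padding; the group delay of
# (ntaps-1)/2 samples is removed exactly, so a symmetric input stays
# symmetric. Tap count adapts to the epoch length.
bandpass_filter <- function(x, fs_hz, lo, hi) {
  n <- length(x)
  ntaps <- min(2L * floor((n - 1) / 2) + 1L, 2L * floor(1.5 * fs_hz) + 1L)
  h <- signal::fir1(ntaps - 1L, c(lo, hi) / (fs_hz / 2), type = "pass")
  filter_zero_phase(x, h)
}

filter_zero_phase <- function(x, h) {
  n <- length(x)
  ntaps <- length(h)
  half <- (ntaps - 1L) %/% 2L
  pad <- c(2 * x[1] - rev(x[seq_len(min(half, n - 1)) + 1L]), x,
           2 * x[n] - x[n - seq_len(min(half, n - 1))])
  y <- stats::filter(pad, h, sides = 1)
  npad <- min(half, n - 1)
  as.numeric(y[(npad + ntaps - half):(npad + ntaps - half + n - 1)])
}

# Band-pass every trial x channel of an epochs array (matrix form, one FFT
# design shared across columns for speed).
bandpass_epochs <- function(epochs, lo, hi) {
  d <- dim(epochs$data)
  n <- d[3]
  fs <- epochs$fs_hz
  ntaps <- min(2L * floor((n - 1) / 2) + 1L, 2L * floor(1.5 * fs) + 1L)
  h <- signal::fir1(ntaps - 1L, c(lo, hi) / (fs / 2), type = "pass")
  half <- (ntaps - 1L) %/% 2L
  npad <- min(half, n - 1L, as.integer(fs %/% 4))   # 250 ms edge context
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)    # samples x (tr*ch)
  nf <- stats::nextn(n + 2L * npad + ntaps, 2)
  H <- stats::fft(c(h, numeric(nf - ntaps)))
  out <- matrix(0, n, ncol(X))
  for (block in split(seq_len(ncol(X)),
                      ceiling(seq_len(ncol(X)) / 1024))) {
    Xb <- X[, block, drop = FALSE]
    top <- 2 * rep(Xb[1, ], each = npad) - Xb[npad:1 + 1L, , drop = FALSE]
    bot <- 2 * rep(Xb[n, ], each = npad) - Xb[n - seq_len(npad), , drop = FALSE]
    P <- rbind(matrix(top, npad), Xb, matrix(bot, npad),
               matrix(0, nf - n - 2L * npad, length(block)))
    Y <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / nf
    out[, block] <- Y[(npad + half + 1):(npad + half + n), , drop = FALSE]
  }
  epochs$data <- aperm(array(out, c(n, d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Preprocess an epochs set
#'
#' Runs the full scalp pipeline: bad-channel detection (excluding the
#' subject when more than `max_bad_channels` are found), spherical-spline
#' interpolation, zero-phase 0.1-30 Hz band-pass, rejection of trials with
#' any |sample| above the threshold, average re-referencing, and the
#' minimum-trials-per-condition inclusion rule.
#'
#' @param epochs An [epochs_set()].
#' @param config A [preproc_config()].
#' @param montage The matching montage (needed for interpolation).
#' @return List with `epochs` (cleaned; NULL when excluded) and `report`
#'   (bad channels, rejected trial indices, per-condition counts,
#'   `excluded` flag and `reason`).
#' @export
preprocess <- function(epochs, config = preproc_config(), montage) {
  stopifnot(inherits(epochs, "smeloc_epochs"),
            inherits(config, "smeloc_preproc_config"))
  report <- list(subject_id = epochs$subject_id, bad_channels = integer(0),
                 n_rejected = 0L, rejected_trials = integer(0),
                 trials_per_condition = table(epochs$condition),
                 excluded = FALSE, reason = NA_character_)
  bad <- detect_bad_channels(epochs)
  report$bad_channels <- bad
  if (length(bad) > config$max_bad_channels) {
    report$excluded <- TRUE
    report$reason <- sprintf("%d bad channels exceed the maximum of %d",
                             length(bad), config$max_bad_channels)
    return(list(epochs = NULL, report = report))
  }
  if (length(bad)) epochs <- interpolate_channels(epochs, montage, bad)
  epochs <- bandpass_epochs(epochs, config$highpass_hz, config$lowpass_hz)
  peak <- apply(abs(epochs$data), 1, max)
  drop_tr <- which(peak > config$reject_uv)
  report$n_rejected <- length(drop_tr)
  report$rejected_trials <- drop_tr
  if (length(drop_tr)) {
    epochs$data <- epochs$data[-drop_tr, , , drop = FALSE]
    epochs$condition <- epochs$condition[-drop_tr]
  }
  # average reference: subtract the channel mean at every trial x sample
  d2 <- dim(epochs$data)
  chm <- colMeans(aperm(epochs$data, c(2, 1, 3)))          # trials x samples
  epochs$data <- epochs$data - aperm(array(chm, c(d2[1], d2[3], d2[2])),
                                     c(1, 3, 2))
  counts <- table(factor(epochs$condition,
                         levels = names(report$trials_per_condition)))
  report$trials_per_condition <- counts
  if (any(counts < config$min_trials_per_condition)) {
    report$excluded <- TRUE
    report$reason <- sprintf("fewer than %d trials in a condition after rejection",
                             config$min_trials_per_condition)
    return(list(epochs = NULL, report = report))
  }
  list(epochs = epochs, report = report)
}
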