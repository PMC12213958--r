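# Scalp ERP component quantification: collapsed-localizer window
# suggestion, per-subject P2 window extraction, fixed LSW window,
# re-baselining to the preceding negative trough, and 3 x 3 channel-cluster
# mean amplitudes per condition.

#' Component analysis window
#'
#' @param component "P2" or "LSW".
#' @param center_ms Window center latency (ms).
#' @param window_ms Window length (ms), default 50.
#' @param search_range_ms Range the center was searched in.
#' @param baseline_ms Re-baseline interval: P2 defaults to 130-140 ms,
#'   LSW to 610-620 ms (the last negative-going stretch ahead of each).
#' @param epoch_ms Epoch limits used for clipping.
#' @return `smeloc_window` with `win_ms = c(start, end)` (clipped to the
#'   epoch and flagged `clipped` when that truncates it), `center_ms`,
#'   `baseline_ms`, `low_confidence` flag.
#' @export
component_window <- function(component, center_ms, window_ms = 50,
                             search_range_ms = NULL,
                             baseline_ms = if (component == "P2")
                               c(130, 140) else c(610, 620),
                             epoch_ms = c(-100, 1500)) {
  win <- center_ms + c(-1, 1) * window_ms / 2
  clipped <- win[1] < epoch_ms[1] || win[2] > epoch_ms[2]
  win <- pmin(pmax(win, epoch_ms[1]), epoch_ms[2])
  structure(list(component = component, center_ms = center_ms,
                 window_ms = window_ms, win_ms = win,
                 search_range_ms = search_range_ms,
                 baseline_ms = baseline_ms, epoch_ms = epoch_ms,
                 clipped = clipped, low_confidence = FALSE),
            class = "smeloc_window")
}

# Sample indices of a window within an epoch.
window_samples <- function(window, fs_hz, t0_ms, n_samples) {
  i <- ms_to_sample(window$win_ms, fs_hz, t0_ms)
  i <- pmin(pmax(i, 1L), n_samples)
  seq.int(i[1], i[2])
}

baseline_samples <- function(window, fs_hz, t0_ms, n_samples) {
  i <- ms_to_sample(window$baseline_ms, fs_hz, t0_ms)
  if (any(i < 1L | i > n_samples))
    stopf("baseline window [%g, %g] ms lies outside the epoch",
          window$baseline_ms[1], window$baseline_ms[2])
  seq.int(i[1], i[2])
}

#' Grand-average ERP collapsed over subjects, trials and conditions
#'
#' Pools every trial of every included subject (so subjects with more
#' surviving trials weigh proportionally) and suggests component search
#' ranges: the P2 range is the contiguous positive deflection of the
#' frontal-cluster mean overlapping 120-250 ms; the LSW range defaults to
#' 1100-1500 ms. Both are advisory and config-overridable.
#'
#' @param epochs_list List of preprocessed [epochs_set()] objects.
#' @param montage The montage (for the frontal cluster).
#' @return List with `grand_average` (channels x samples), `n_trials`,
#'   `p2_range_ms`, `lsw_range_ms`, `times_ms`.
#' @export
collapsed_localizer <- function(epochs_list, montage) {
  epochs_list <- Filter(Negate(is.null), epochs_list)
  if (!length(epochs_list)) stopf("no included subjects")
  ref <- epochs_list[[1]]
  nsamp <- dim(ref$data)[3]
  acc <- matrix(0, dim(ref$data)[2], nsamp)
  ntr <- 0L
  for (ep in epochs_list) {
    acc <- acc + apply(ep$data, c(2, 3), sum)
    ntr <- ntr + dim(ep$data)[1]
  }
  ga <- acc / ntr
  times <- epoch_times_ms(ref$fs_hz, ref$t0_ms, nsamp)
  frontal <- cluster_channels(montage, coronal = "frontal")
  fm <- colMeans(ga[frontal, , drop = FALSE])
  # contiguous positive run of the frontal mean overlapping 120-250 ms
  idx <- which(times >= 120 & times <= 250)
  peak <- idx[which.max(fm[idx])]
  if (fm[peak] > 0) {
    lo <- peak; while (lo > 1 && fm[lo - 1] > 0) lo <- lo - 1
    hi <- peak; while (hi < nsamp && fm[hi + 1] > 0) hi <- hi + 1
    p2_range <- c(max(times[lo], 120), min(times[hi], 250))
  } else {
    p2_range <- c(120, 250)
  }
  list(grand_average = ga, n_trials = ntr, times_ms = times,
       p2_range_ms = p2_range, lsw_range_ms = c(1100, 1500))
}

#' Locate the subject-specific P2 window
#'
#' For every trial, finds the latency of the maximum of the frontal-cluster
#' mean within the search range (ties resolved to the earliest sample);
#' the window is centered on the median of those per-trial peak latencies
#' (lower median for even trial counts).
#'
#' @param epochs A preprocessed [epochs_set()].
#' @param montage The montage.
#' @param search_range_ms Search interval, default `c(120, 250)`.
#' @param window_ms Window length (default 50 ms).
#' @return A [component_window()] for "P2"; `low_confidence` is set when
#'   the frontal mean was non-positive at the chosen peak in most trials.
#' @export
locate_p2_window <- function(epochs, montage, search_range_ms = c(120, 250),
                             window_ms = 50) {
  d <- dim(epochs$data)
  times <- epoch_times_ms(epochs$fs_hz, epochs$t0_ms, d[3])
  idx <- which(times >= search_range_ms[1] & times <= search_range_ms[2])
  if (!length(idx)) stopf("empty P2 search range")
  frontal <- cluster_channels(montage, coronal = "frontal")
  fm <- apply(epochs$data[, frontal, idx, drop = FALSE], c(1, 3), mean)
  peak_i <- apply(fm, 1, which.max)           # earliest max by convention
  peak_ms <- times[idx[peak_i]]
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  center <- lower_median(peak_ms)
  w <- component_window("P2", center, window_ms,
                        search_range_ms = search_range_ms,
                        epoch_ms = range(times))
  peak_vals <- fm[cbind(seq_len(d[1]), peak_i)]
  w$low_confidence <- mean(peak_vals > 0) < 0.5
  w
}

#' The fixed LSW window
#'
#' The late slow wave is quantified in a fixed window for all subjects,
#' centered at 1200 ms inside the 1100-1500 ms range (default 50 ms long,
#' giving 1175-1225 ms).
#'
#' @param window_ms Window length (default 50 ms).
#' @param center_ms Center latency (default 1200 ms).
#' @param epoch_ms Epoch limits for clipping.
#' @return A [component_window()] for "LSW".
#' @export
locate_lsw_window <- function(window_ms = 50, center_ms = 1200,
                              epoch_ms = c(-100, 1500)) {
  component_window("LSW", center_ms, window_ms,
                   search_range_ms = c(1100, 1500), epoch_ms = epoch_ms)
}

#' Re-baseline epochs to a component's pre-window trough
#'
#' Subtracts, per channel and trial, the mean over the component's baseline
#' interval (P2: 130-140 ms; LSW: 610-620 ms). Idempotent.
#'
#' @param epochs An [epochs_set()].
#' @param window A [component_window()].
#' @return The re-baselined epochs.
#' @export
rebaseline <- function(epochs, window) {
  d <- dim(epochs$data)
  bi <- baseline_samples(window, epochs$fs_hz, epochs$t0_ms, d[3])
  bl <- apply(epochs$data[, , bi, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)   # recycles over samples
  epochs
}

#' Cluster mean amplitudes for the 2 x 3 x 3 design
#'
#' Mean amplitude per condition over (trials, in-window samples, cluster
#' channels) for each coronal x sagittal cell.
#'
#' @param epochs A preprocessed, re-baselined [epochs_set()].
#' @param window The [component_window()].
#' @param montage The montage carrying the cluster assignment.
#' @return data.frame with `condition`, `coronal`, `sagittal`, `amplitude`
#'   (18 rows).
#' @export
cluster_means <- function(epochs, window, montage) {
  d <- dim(epochs$data)
  wi <- window_samples(window, epochs$fs_hz, epochs$t0_ms, d[3])
  out <- expand.grid(condition = unique(epochs$condition),
                     coronal = levels(montage$coronal),
                     sagittal = levels(montage$sagittal),
                     stringsAsFactors = FALSE)
  out$amplitude <- NA_real_
  for (r in seq_len(nrow(out))) {
    ch <- cluster_channels(montage, out$coronal[r], out$sagittal[r])
    tr <- which(epochs$condition == out$condition[r])
    out$amplitude[r] <- mean(epochs$data[tr, ch, wi])
  }
  out
}
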