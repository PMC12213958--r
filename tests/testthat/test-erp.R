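make_pulse_epochs <- function(peaks_ms, n_ch = 64, fs = 512, t0 = -100,
                              n_samp = 820, width_ms = 40) {
  times <- t0 + (seq_len(n_samp) - 1) * 1000 / fs
  data <- array(0, c(length(peaks_ms), n_ch, n_samp))
  for (i in seq_along(peaks_ms))
    data[i, , ] <- rep(exp(-(times - peaks_ms[i])^2 / (2 * (width_ms / 2.355)^2)),
                       each = n_ch)
  epochs_set(data, rep(c("source_correct", "source_incorrect"),
                       length.out = length(peaks_ms)), fs, t0,
             fix_montage()$labels)
}

test_that("the collapsed localizer pools all trials and brackets the true peak", {
  ep1 <- make_pulse_epochs(c(180, 180, 180, 180))
  ep2 <- make_pulse_epochs(c(180, 180))
  loc <- collapsed_localizer(list(ep1, ep2), fix_montage())
  expect_true(loc$p2_range_ms[1] <= 180 && 180 <= loc$p2_range_ms[2])
  expect_equal(loc$lsw_range_ms, c(1100, 1500))

  # permuting condition labels changes nothing (collapsing ignores them)
  ep1b <- ep1; ep1b$condition <- rev(ep1$condition)
  loc2 <- collapsed_localizer(list(ep1b, ep2), fix_montage())
  expect_identical(loc$grand_average, loc2$grand_average)

  # oracle: trial-count-weighted pooled mean computed by brute force
  pooled <- (4 * apply(ep1$data, c(2, 3), mean) +
               2 * apply(ep2$data, c(2, 3), mean)) / 6
  expect_equal(loc$grand_average, pooled, tolerance = 1e-12)
  expect_error(collapsed_localizer(list(), fix_montage()), "no included")
})

test_that("the P2 window centers on the median per-trial frontal peak", {
  ep <- make_pulse_epochs(c(180, 180, 180))
  w <- locate_p2_window(ep, fix_montage())
  # 180 ms is not exactly on the 512 Hz grid; allow one sample
  expect_lt(abs(w$center_ms - 180), 1000 / 512)
  expect_equal(w$win_ms, w$center_ms + c(-25, 25))

  ep3 <- make_pulse_epochs(c(160, 180, 200))
  w3 <- locate_p2_window(ep3, fix_montage())
  expect_lt(abs(w3$center_ms - 180), 1000 / 512)

  # even trial count: lower median by convention
  ep4 <- make_pulse_epochs(c(160, 180, 200, 220))
  w4 <- locate_p2_window(ep4, fix_montage())
  expect_lt(abs(w4$center_ms - 180), 1000 / 512)
})

test_that("a flat signal yields the range start and a low-confidence flag", {
  ep <- constant_epochs(0, n_trials = 3)
  w <- locate_p2_window(ep, fix_montage())
  expect_lt(abs(w$center_ms - 120), 1000 / 512)
  expect_true(w$low_confidence)
  expect_error(locate_p2_window(ep, fix_montage(),
                                search_range_ms = c(2000, 2100)),
               "empty")
})

test_that("the LSW window is fixed at 1200 ms and clips at the epoch edge", {
  w <- locate_lsw_window()
  expect_equal(w$win_ms, c(1175, 1225))
  w150 <- locate_lsw_window(window_ms = 150)
  expect_equal(w150$win_ms, c(1125, 1275))
  wbig <- locate_lsw_window(window_ms = 700)
  expect_true(wbig$clipped)
  expect_equal(wbig$win_ms[2], 1500)
})

test_that("re-baselining removes the baseline-window mean exactly and is idempotent", {
  ep <- constant_epochs(3, n_trials = 2)
  w <- locate_lsw_window()
  out <- rebaseline(ep, w)
  expect_identical(max(abs(out$data)), 0)

  # planted ramp: hand-computed baseline mean must be subtracted exactly
  n_samp <- 820
  times <- -100 + (seq_len(n_samp) - 1) * 1000 / 512
  ramp <- 0.01 * times
  ep2 <- constant_epochs(0, n_trials = 2)
  ep2$data <- ep2$data + rep(ramp, each = 2 * 64)
  out2 <- rebaseline(ep2, w)
  i0 <- as.integer(round((w$baseline_ms - (-100)) * 512 / 1000)) + 1L
  hand <- mean(ramp[i0[1]:i0[2]])
  expect_equal(out2$data[1, 1, ], ramp - hand, tolerance = 1e-12)
  out3 <- rebaseline(out2, w)
  expect_equal(out3$data, out2$data, tolerance = 1e-12)

  wbad <- component_window("P2", 200, baseline_ms = c(-500, -400))
  expect_error(rebaseline(ep, wbad), "outside the epoch")
})

test_that("cluster means reduce to the expected arithmetic", {
  mon <- fix_montage()
  w <- locate_lsw_window()
  ep <- constant_epochs(2, n_trials = 4)
  cm <- cluster_means(ep, w, mon)
  expect_equal(cm$amplitude, rep(2, 18))

  # one frontal-left channel carries a boxcar: its cell averages it down
  ep2 <- constant_epochs(0, n_trials = 4)
  fl <- cluster_channels(mon, "frontal", "left")
  wi <- smeloc:::window_samples(w, 512, -100, 820)
  ep2$data[, fl[1], wi] <- 9
  cm2 <- cluster_means(ep2, w, mon)
  cell <- cm2$coronal == "frontal" & cm2$sagittal == "left"
  expect_equal(unique(cm2$amplitude[cell]), 9 / length(fl))
  expect_equal(unique(cm2$amplitude[!cell]), 0)

  # swapping trials within a condition changes nothing
  ep3 <- fix_subject()
  i <- which(ep3$condition == "source_correct")[1:2]
  ep4 <- ep3
  ep4$data[i, , ] <- ep3$data[rev(i), , ]
  expect_equal(cluster_means(ep3, w, mon), cluster_means(ep4, w, mon),
               tolerance = 1e-12)
})
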