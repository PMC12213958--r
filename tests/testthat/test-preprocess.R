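test_that("flat and high-variance channels are detected, with a hand-computed z oracle", {
  ep <- fix_subject()
  ep$data[, 5, ] <- 0                     # flatline
  ep$data[, 12, ] <- ep$data[, 12, ] * 50 # gain fault
  bad <- detect_bad_channels(ep)
  expect_true(5L %in% bad)
  expect_true(12L %in% bad)

  # oracle: robust z of log residual (trial-mean-removed) variances plus
  # the fold-change guard, computed independently
  v_raw <- sapply(seq_len(64), function(ch) var(as.vector(ep$data[, ch, ])))
  v <- sapply(seq_len(64), function(ch) {
    x <- ep$data[, ch, ]
    var(as.vector(sweep(x, 2, colMeans(x))))
  })
  ok <- v_raw >= 1e-12
  lv <- log(pmax(v, 1e-12))
  z <- abs(lv - median(lv[ok])) / mad(lv[ok])
  extreme <- v > 4 * median(v[ok]) | v < median(v[ok]) / 4
  expect_setequal(bad, sort(unique(c(which(!ok),
                                     which(ok & z > 5 & extreme)))))
})

test_that("more than 8 bad channels excludes the subject", {
  ep <- fix_subject()
  for (ch in 1:9) ep$data[, ch, ] <- 0
  res <- preprocess(ep, preproc_config(), fix_montage())
  expect_true(res$report$excluded)
  expect_match(res$report$reason, "bad channels")
  expect_null(res$epochs)
})

test_that("spherical splines reproduce a constant field and are idempotent", {
  ep <- constant_epochs(5, n_trials = 2)
  mon <- fix_montage()
  out <- interpolate_channels(ep, mon, bad_channels = 10L)
  expect_equal(max(abs(out$data[, 10, ] - 5)), 0, tolerance = 1e-6)
  again <- interpolate_channels(out, mon, bad_channels = 10L)
  expect_equal(again$data[, 10, ], out$data[, 10, ], tolerance = 1e-9)
  # untouched good channels
  expect_identical(out$data[, -10, ], ep$data[, -10, ])
  expect_error(interpolate_channels(ep, mon, bad_channels = 1:61),
               "4 good channels")
})

test_that("a smooth dipolar field is reconstructed at a held-out channel", {
  mon <- fix_montage()
  h <- fix_head()
  field <- dipole_potential(h, c(0.015, 0.02, 0.03), c(10, 5, 20),
                            mon$positions)
  field <- field - mean(field)
  ep <- epochs_set(array(rep(field, each = 2), c(2, 64, 1)),
                   c("source_correct", "source_incorrect"), 512, 0,
                   mon$labels)
  drop_ch <- which.max(abs(field))        # hardest case: the extremum
  out <- interpolate_channels(ep, mon, drop_ch)
  rel_err <- abs(out$data[1, drop_ch, 1] - field[drop_ch]) /
    max(abs(field))
  expect_lt(rel_err, 0.05)
})

test_that("the band-pass filter is zero-phase", {
  fs <- 512
  n <- 821L
  x <- exp(-((seq_len(n) - 411) / 30)^2)   # symmetric pulse, center 411
  y <- smeloc:::bandpass_filter(x, fs, 0.1, 30)
  expect_lt(max(abs(y - rev(y))), 1e-9)
  expect_equal(which.max(y), 411L)
})

test_that("preprocessing rejects exactly the planted artifact trials and re-references", {
  masks <- fix_masks_coarse()
  tr <- make_ground_truth(masks)
  tr$artifact_fraction <- 0.1
  tr$noise_white_uv <- 4
  tr$noise_pink_uv <- 2
  design <- study_design(1, 40, master_seed = 8)
  ep <- simulate_subject(design, fix_montage(), fix_source_coarse(), masks,
                         tr, fix_leadfield_coarse(), 31L)
  k <- length(ep$subject_truth$artifact_trials)
  expect_identical(k, 8L)
  res <- preprocess(ep, preproc_config(), fix_montage())
  expect_identical(res$report$n_rejected, k)
  expect_identical(res$report$rejected_trials, ep$subject_truth$artifact_trials)
  chan_means <- apply(res$epochs$data, c(1, 3), mean)
  expect_lt(max(abs(chan_means)), 1e-9)
})

test_that("all-zero data pass through preprocessing unchanged", {
  ep <- constant_epochs(0, n_trials = 22)
  res <- preprocess(ep, preproc_config(min_trials_per_condition = 5),
                    fix_montage())
  expect_identical(res$report$n_rejected, 0L)
  expect_false(res$report$excluded)
  expect_identical(max(abs(res$epochs$data)), 0)
})

test_that("too few surviving trials in a condition excludes the subject", {
  ep <- fix_subject()                     # 20 per condition
  res <- preprocess(ep, preproc_config(min_trials_per_condition = 21),
                    fix_montage())
  expect_true(res$report$excluded)
  expect_match(res$report$reason, "fewer than 21 trials")
})

test_that("scaling the data scales cluster means and leaves ANOVA F unchanged", {
  set.seed(12)
  n_sub <- 5
  tabs <- lapply(seq_len(n_sub), function(i) {
    ep <- constant_epochs(0, n_trials = 8)
    ep$data <- array(rnorm(length(ep$data)), dim(ep$data))
    ep
  })
  mon <- fix_montage()
  w <- locate_lsw_window()
  cm1 <- lapply(tabs, function(ep) cluster_means(ep, w, mon))
  cm2 <- lapply(tabs, function(ep) {
    ep$data <- 3 * ep$data
    cluster_means(ep, w, mon)
  })
  a1 <- rm_anova_2x3x3(amplitude_table(cm1))
  a2 <- rm_anova_2x3x3(amplitude_table(cm2))
  expect_equal(sapply(cm2, `[[`, "amplitude"),
               3 * sapply(cm1, `[[`, "amplitude"), tolerance = 1e-12)
  expect_equal(a1$effects$F, a2$effects$F, tolerance = 1e-9)
})
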