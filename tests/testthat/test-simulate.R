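silent_truth <- function(masks) {
  tr <- make_ground_truth(masks)
  tr$noise_white_uv <- 0
  tr$noise_pink_uv <- 0
  tr$artifact_fraction <- 0
  tr$subject_amp_cv <- 0
  tr$trial_amp_cv <- 0
  tr$latency_jitter_sd_ms <- 0
  tr$effect_sd <- 0
  tr
}

test_that("zero source amplitudes and zero noise give an exactly silent recording", {
  masks <- fix_masks_coarse()
  tr <- silent_truth(masks)
  tr$active_sources$amp_correct <- 0
  tr$active_sources$amp_incorrect <- 0
  design <- study_design(1, 5, master_seed = 1)
  ep <- simulate_subject(design, fix_montage(), fix_source_coarse(), masks,
                         tr, fix_leadfield_coarse(), 7L)
  expect_identical(max(abs(ep$data)), 0)
})

test_that("a single noiseless P2 source projects the lead-field pattern at its peak", {
  masks <- fix_masks_coarse()
  ss <- fix_source_coarse()
  lf <- fix_leadfield_coarse()
  tr <- silent_truth(masks)
  j <- masks$masks[["left EC"]]$indices[1]
  tr$active_sources <- data.frame(grid_index = j, component = "P2",
                                  roi = "left EC", amp_correct = 30,
                                  amp_incorrect = 30)
  design <- study_design(1, 4, master_seed = 2)
  ep <- simulate_subject(design, fix_montage(), ss, masks, tr, lf, 11L)
  # oracle: direct projection of a radial unit moment at j
  pos <- ss$grid_positions[j, ]
  o <- pos / sqrt(sum(pos^2))
  pattern <- drop(lf$gain[, (3 * j - 2):(3 * j)] %*% o)
  frontal <- which(fix_montage()$coronal == "frontal")
  if (mean(pattern[frontal]) < 0) pattern <- -pattern
  peak_sample <- which.max(abs(ep$data[1, which.max(abs(pattern)), ]))
  map <- ep$data[1, , peak_sample]
  scale <- sum(map * pattern) / sum(pattern^2)
  expect_gt(scale, 0)
  expect_lt(max(abs(map - scale * pattern)), 1e-8 * max(abs(map)))
})

test_that("exactly the planted fraction of trials exceeds the artifact floor", {
  masks <- fix_masks_coarse()
  tr <- make_ground_truth(masks)
  tr$artifact_fraction <- 0.1
  tr$noise_white_uv <- 3
  tr$noise_pink_uv <- 2
  design <- study_design(1, 40, master_seed = 3)
  ep <- simulate_subject(design, fix_montage(), fix_source_coarse(), masks,
                         tr, fix_leadfield_coarse(), 23L)
  peak <- apply(abs(ep$data), 1, max)
  over <- which(peak > 200)
  expect_identical(length(over), as.integer(round(0.1 * 80)))
  expect_identical(over, ep$subject_truth$artifact_trials)
})

test_that("the simulation is a pure function of the subject seed", {
  masks <- fix_masks_coarse()
  tr <- make_ground_truth(masks)
  design <- study_design(1, 6, master_seed = 4)
  args <- list(design, fix_montage(), fix_source_coarse(), masks, tr,
               fix_leadfield_coarse(), 99L)
  e1 <- do.call(simulate_subject, args)
  e2 <- do.call(simulate_subject, args)
  expect_identical(e1$data, e2$data)
  expect_identical(e1$condition, e2$condition)
  e3 <- do.call(simulate_subject, c(args[1:6], 100L))
  expect_false(identical(e1$data, e3$data))
})

test_that("null truth removes every planted condition difference", {
  masks <- fix_masks_coarse()
  tr0 <- null_truth(make_ground_truth(masks))
  expect_identical(tr0$active_sources$amp_correct,
                   tr0$active_sources$amp_incorrect)
  tr0$effect_sd <- 0
  design <- study_design(1, 5, master_seed = 6)
  ep <- simulate_subject(design, fix_montage(), fix_source_coarse(), masks,
                         tr0, fix_leadfield_coarse(), 55L)
  expect_equal(unname(ep$subject_truth$condition_diff_nam), c(0, 0))
})

test_that("the planted condition effect is recoverable from the truth record", {
  tr <- make_ground_truth(fix_masks_coarse())
  p2 <- tr$active_sources[tr$active_sources$component == "P2", ]
  expect_equal(p2$amp_correct - p2$amp_incorrect,
               rep(tr$effect_sd * tr$planted_d[["P2"]], nrow(p2)))
  expect_equal(tr$planted_d[["LSW"]],
               (tr$active_sources$amp_correct[nrow(tr$active_sources)] -
                  tr$active_sources$amp_incorrect[nrow(tr$active_sources)]) /
                 tr$effect_sd)
})

test_that("epochs round-trip bit-exactly through the binary container", {
  ep <- fix_subject()
  stem <- file.path(withr::local_tempdir(), "epochs")
  write_epochs(ep, stem)
  back <- read_epochs(stem)
  # float32 storage: values agree at single precision, and a second write
  # is byte-identical
  expect_equal(back$data, ep$data, tolerance = 1e-6)
  expect_identical(back$condition, ep$condition)
  expect_identical(back$channel, ep$channel)
  stem2 <- file.path(withr::local_tempdir(), "epochs2")
  write_epochs(back, stem2)
  expect_identical(unname(tools::md5sum(paste0(stem, ".bin"))),
                   unname(tools::md5sum(paste0(stem2, ".bin"))))
  back2 <- read_epochs(stem2)
  expect_identical(back2$data, back$data)
})

test_that("simulate_study writes a reproducible on-disk dataset", {
  design <- study_design(n_subjects = 2, n_trials_per_condition = 4,
                         fs_hz = 128, master_seed = 7)
  masks <- fix_masks_coarse()
  tr <- make_ground_truth(masks)
  d1 <- file.path(withr::local_tempdir(), "study1")
  d2 <- file.path(withr::local_tempdir(), "study2")
  m1 <- simulate_study(design, d1, fix_head(), fix_montage(),
                       fix_source_coarse(), masks, tr,
                       leadfield = fix_leadfield_coarse())
  m2 <- simulate_study(design, d2, fix_head(), fix_montage(),
                       fix_source_coarse(), masks, tr,
                       leadfield = fix_leadfield_coarse())
  expect_identical(m1$hashes, m2$hashes)
  expect_identical(m1$subject_seeds, m2$subject_seeds)
  subs <- list.dirs(d1, recursive = FALSE)
  expect_length(subs[grepl("sub-", basename(subs))], length(m1$subjects))
  expect_error(simulate_study(design, d1, fix_head(), fix_montage(),
                              fix_source_coarse(), masks, tr,
                              leadfield = fix_leadfield_coarse()),
               "overwrite")
  expect_error(study_design(n_subjects = 0), "empty study")
})
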