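# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

fix_head <- function() fixture("head", function() make_head())

fix_montage <- function() fixture("montage", function() make_montage(fix_head()))

fix_source_coarse <- function() fixture("ss_coarse", function()
  make_source_space(fix_head(), spacing = 0.016))

fix_masks_coarse <- function() fixture("masks_coarse", function()
  make_roi_masks(fix_source_coarse()))

fix_leadfield_coarse <- function() fixture("lf_coarse", function()
  compute_leadfield(fix_head(), fix_source_coarse(), fix_montage()))

# Tiny deterministic epochs with a known constant value.
constant_epochs <- function(value = 0, n_trials = 4, n_ch = 64, fs = 512,
                            t0 = -100, n_samp = 820,
                            conditions = rep(c("source_correct",
                                               "source_incorrect"),
                                             length.out = n_trials)) {
  epochs_set(array(value, c(n_trials, n_ch, n_samp)), conditions, fs, t0,
             if (n_ch == 64) make_montage(fix_head())$labels
             else sprintf("E%02d", seq_len(n_ch)))
}

# A small simulated subject reused by several test files (default truth,
# coarse grid, low artifact count).
fix_subject <- function() fixture("subject", function() {
  design <- study_design(n_subjects = 1, n_trials_per_condition = 20,
                         master_seed = 5)
  truth <- make_ground_truth(fix_masks_coarse())
  simulate_subject(design, fix_montage(), fix_source_coarse(),
                   fix_masks_coarse(), truth, fix_leadfield_coarse(),
                   subject_seed = 101L, subject_id = "sub-01")
})

random_sphere_points <- function(n, radius) {
  m <- matrix(stats::rnorm(3 * n), n)
  radius * m / sqrt(rowSums(m^2))
}
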