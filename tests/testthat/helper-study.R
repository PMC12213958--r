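# Fast in-memory replicate studies for the calibration and recovery
# properties: a reduced montage/grid/sampling-rate configuration whose
# geometry, lead field and inverse operator are computed once and shared
# across replicates.

fast_setup <- function(n_electrodes = 32L, spacing = 0.016, alpha = 0.05) {
  key <- sprintf("fast_%d_%g_%g", n_electrodes, spacing, alpha)
  fixture(key, function() {
    head <- make_head()
    montage <- make_montage(head, n_electrodes)
    ss <- make_source_space(head, spacing = spacing)
    masks <- make_roi_masks(ss)
    lf <- compute_leadfield(head, ss, montage)
    w <- eloreta_weights(lf, alpha = alpha)
    inv <- make_inverse_operator(lf, w)
    list(head = head, montage = montage, ss = ss, masks = masks, lf = lf,
         inv = inv)
  })
}

# One complete study at reduced scale: simulate every subject, preprocess,
# locate windows, and return the P2 scalp ANOVA plus the ROI stat table.
run_fast_study <- function(setup, truth, n_subjects, trials_per_cond,
                           master_seed, fs_hz = 256) {
  design <- study_design(n_subjects, trials_per_cond, fs_hz = fs_hz,
                         master_seed = master_seed)
  cfg <- preproc_config()
  cms <- list()
  cdr_rows <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("sub-%02d", i)
    ep <- simulate_subject(design, setup$montage, setup$ss, setup$masks,
                           truth, setup$lf, smeloc:::derive_seed(master_seed, i),
                           sid)
    res <- preprocess(ep, cfg, setup$montage)
    if (res$report$excluded) next
    epc <- res$epochs
    w_p2 <- locate_p2_window(epc, setup$montage)
    w_lsw <- locate_lsw_window()
    cms[[sid]] <- cluster_means(rebaseline(epc, w_p2), w_p2, setup$montage)
    for (comp in c("P2", "LSW")) {
      cw <- if (comp == "P2") w_p2 else w_lsw
      epb <- rebaseline(epc, cw)
      for (cond in design$conditions) {
        agg <- roi_aggregate(cdr_scores(
          apply_inverse_window(setup$inv, epb, cw, cond)), setup$masks)
        agg$subject <- sid; agg$component <- comp; agg$condition <- cond
        cdr_rows[[length(cdr_rows) + 1L]] <- agg
      }
    }
  }
  an <- rm_anova_2x3x3(amplitude_table(cms))
  stat <- build_stat_report(do.call(rbind, cdr_rows))
  list(anova = an, stat = stat$table, n_included = length(cms))
}

planted_pairs <- function(truth) {
  do.call(rbind, lapply(names(truth$effect_rois), function(comp)
    data.frame(component = comp, mask = truth$effect_rois[[comp]])))
}
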