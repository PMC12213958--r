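# Desk-scale orchestration of the full study: simulate -> preprocess ->
# erp -> forward -> inverse -> stats -> report, with one config, derived
# seeds, a run manifest with input/output hashes, and stage caching.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Unknown arguments are
#' rejected. The default scale (12 subjects, 12 mm source grid) completes
#' a desktop demonstration run in minutes.
#'
#' @param out_dir Root output directory.
#' @param n_subjects,n_trials_per_condition,fs_hz,epoch_ms,master_seed
#'   Study design; see [study_design()].
#' @param shell_radii,shell_conductivities Head model; see [make_head()].
#' @param n_electrodes Montage size; @param grid_spacing source-grid pitch
#'   (m); @param grid_band grey-matter band fractions.
#' @param truncation_L Forward-series truncation degree.
#' @param highpass_hz,lowpass_hz,reject_uv,max_bad_channels,min_trials_per_condition
#'   Preprocessing; see [preproc_config()].
#' @param window_ms Component window length (ms).
#' @param alpha,tol Inverse regularization fraction and convergence
#'   tolerance; see [eloreta_weights()].
#' @param fdr_level BH significance level on q.
#' @param null_effect Simulate with condition effects removed (for
#'   calibration studies).
#' @return `smeloc_config` list.
#' @export
pipeline_config <- function(out_dir,
                            n_subjects = 12L, n_trials_per_condition = 40L,
                            fs_hz = 512, epoch_ms = c(-100, 1500),
                            master_seed = 1L,
                            shell_radii = c(0.08, 0.082, 0.087, 0.092),
                            shell_conductivities = c(0.33, 1.79, 0.01, 0.43),
                            n_electrodes = 64L,
                            grid_spacing = 0.012, grid_band = c(0.55, 0.85),
                            truncation_L = 60L,
                            highpass_hz = 0.1, lowpass_hz = 30,
                            reject_uv = 200, max_bad_channels = 8L,
                            min_trials_per_condition = 10L,
                            window_ms = 50,
                            alpha = 0.05, tol = 1e-6,
                            fdr_level = 0.05,
                            null_effect = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "smeloc_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Keys must match [pipeline_config()] arguments; unknown keys are an error.
#' @param path A .yaml/.yml or .json file.
#' @return `smeloc_config`.
#' @export
load_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

pipeline_stages <- function() {
  c("simulate", "preprocess", "erp", "forward", "inverse", "stats", "report")
}

stage_requires <- function(stage) {
  switch(stage,
         simulate = character(0),
         forward = "simulate",
         preprocess = "simulate",
         erp = "preprocess",
         inverse = c("preprocess", "erp", "forward"),
         stats = "inverse",
         report = "stats",
         stopf("unknown stage '%s'", stage))
}

stage_dir <- function(config, stage) {
  switch(stage,
         simulate = file.path(config$out_dir, "data"),
         file.path(config$out_dir, stage))
}

manifest_path <- function(config) file.path(config$out_dir, "run_manifest.json")

read_run_manifest <- function(config) {
  p <- manifest_path(config)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

write_run_manifest <- function(config, manifest) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  atomic_write(manifest_path(config), function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA))
}

# Parameters that feed a stage (echoed into the manifest so a run never
# silently changes defaults).
stage_params <- function(config, stage) {
  keep <- switch(stage,
    simulate = c("n_subjects", "n_trials_per_condition", "fs_hz", "epoch_ms",
                 "master_seed", "shell_radii", "shell_conductivities",
                 "n_electrodes", "grid_spacing", "grid_band", "null_effect"),
    forward = c("shell_radii", "shell_conductivities", "truncation_L"),
    preprocess = c("highpass_hz", "lowpass_hz", "reject_uv",
                   "max_bad_channels", "min_trials_per_condition"),
    erp = c("window_ms"),
    inverse = c("alpha", "tol", "window_ms"),
    stats = c("fdr_level"),
    report = c("fdr_level"))
  config[keep]
}

stage_input_files <- function(config, stage) {
  dd <- stage_dir(config, "simulate")
  switch(stage,
    simulate = character(0),
    forward = file.path(dd, c("montage.sfp", "masks.json")),
    preprocess = list.files(dd, pattern = "epochs\\.(bin|json)$",
                            recursive = TRUE, full.names = TRUE),
    erp = list.files(stage_dir(config, "preprocess"), full.names = TRUE),
    inverse = c(list.files(stage_dir(config, "preprocess"), full.names = TRUE),
                file.path(stage_dir(config, "erp"), "windows.json"),
                file.path(stage_dir(config, "forward"),
                          c("leadfield.bin", "leadfield.json"))),
    stats = file.path(stage_dir(config, "inverse"), "roi_cdr.tsv"),
    report = file.path(stage_dir(config, "stats"), "stat_table.tsv"))
}

# Rebuild study-level geometry objects from the config (deterministic).
config_geometry <- function(config) {
  head <- make_head(config$shell_radii, config$shell_conductivities)
  montage <- make_montage(head, config$n_electrodes)
  source_space <- make_source_space(head, config$grid_spacing,
                                    config$grid_band)
  masks <- make_roi_masks(source_space)
  list(head = head, montage = montage, source_space = source_space,
       masks = masks)
}

#' Run one pipeline stage
#'
#' Checks that the producing stages have run, executes the stage, writes
#' its outputs atomically and records parameters, input/output hashes,
#' wall time and warnings in the run manifest. A completed stage whose
#' inputs and parameters are unchanged is skipped unless `force = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @param stage One of simulate, preprocess, erp, forward, inverse, stats,
#'   report.
#' @param force Re-run even when cached.
#' @return Invisibly, the stage's manifest entry.
#' @export
run_stage <- function(config, stage, force = FALSE) {
  stopifnot(inherits(config, "smeloc_config"))
  stage <- match.arg(stage, pipeline_stages())
  manifest <- read_run_manifest(config)
  for (dep in stage_requires(stage)) {
    if (is.null(manifest[[dep]]))
      stopf("missing inputs for '%s'; run '%s' first", stage, dep)
  }
  inputs <- stage_input_files(config, stage)
  inputs <- inputs[file.exists(inputs)]
  in_hash <- hash_files(inputs, rel_to = config$out_dir)
  params <- stage_params(config, stage)
  prev <- manifest[[stage]]
  prev_in <- unlist(prev$input_hashes)
  same_inputs <- (length(prev_in) == 0 && length(in_hash) == 0) ||
    identical(prev_in, in_hash)
  if (!force && !is.null(prev) &&
      identical(jsonlite::toJSON(prev$params, auto_unbox = TRUE, digits = NA),
                jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)) &&
      same_inputs &&
      all(file.exists(file.path(stage_dir(config, stage),
                                names(unlist(prev$output_hashes)))))) {
    message(sprintf("stage '%s' is up to date; skipping", stage))
    return(invisible(prev))
  }
  t0 <- Sys.time()
  warns <- character(0)
  withCallingHandlers(
    stage_impl(config, stage),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  out_files <- list.files(stage_dir(config, stage), full.names = TRUE,
                          recursive = TRUE)
  entry <- list(params = params,
                input_hashes = as.list(in_hash),
                output_hashes = as.list(hash_files(out_files,
                                                   rel_to = stage_dir(config, stage))),
                hash_algo = "md5",
                wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                warnings = warns)
  manifest[[stage]] <- entry
  write_run_manifest(config, manifest)
  invisible(entry)
}

stage_impl <- function(config, stage) {
  geo <- config_geometry(config)
  dd <- stage_dir(config, "simulate")
  sdir <- stage_dir(config, stage)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = {
      design <- study_design(config$n_subjects, config$n_trials_per_condition,
                             config$fs_hz, config$epoch_ms,
                             config$master_seed)
      truth <- make_ground_truth(geo$masks)
      if (config$null_effect) truth <- null_truth(truth)
      lf <- compute_leadfield(geo$head, geo$source_space, geo$montage,
                              config$truncation_L)
      simulate_study(design, dd, geo$head, geo$montage, geo$source_space,
                     geo$masks, truth, leadfield = lf, overwrite = TRUE)
    },
    forward = {
      lf <- compute_leadfield(geo$head, geo$source_space, geo$montage,
                              config$truncation_L)
      write_leadfield(lf, file.path(sdir, "leadfield"))
    },
    preprocess = {
      cfg <- preproc_config(config$highpass_hz, config$lowpass_hz,
                            config$reject_uv, config$max_bad_channels,
                            config$min_trials_per_condition)
      subs <- list.dirs(dd, recursive = FALSE)
      subs <- subs[grepl("sub-", basename(subs))]
      reports <- list()
      for (sd in subs) {
        ep <- read_epochs(file.path(sd, "epochs"))
        res <- preprocess(ep, cfg, geo$montage)
        reports[[ep$subject_id]] <- res$report
        if (!res$report$excluded)
          write_epochs(res$epochs, file.path(sdir, paste0(ep$subject_id,
                                                          "_clean")))
      }
      atomic_write(file.path(sdir, "exclusion_report.json"), function(p)
        jsonlite::write_json(lapply(reports, function(r) {
          r$trials_per_condition <- as.list(r$trials_per_condition)
          r
        }), p, auto_unbox = TRUE, digits = NA))
    },
    erp = {
      pre <- stage_dir(config, "preprocess")
      stems <- sub("\\.json$", "",
                   list.files(pre, pattern = "_clean\\.json$", full.names = TRUE))
      eps <- lapply(stems, read_epochs)
      if (!length(eps)) stopf("no included subjects after preprocessing")
      loc <- collapsed_localizer(eps, geo$montage)
      windows <- list()
      cm_p2 <- list(); cm_lsw <- list()
      for (ep in eps) {
        w_p2 <- locate_p2_window(ep, geo$montage, loc$p2_range_ms,
                                 config$window_ms)
        w_lsw <- locate_lsw_window(config$window_ms,
                                   epoch_ms = config$epoch_ms)
        windows[[ep$subject_id]] <- list(
          p2_center_ms = w_p2$center_ms, lsw_center_ms = w_lsw$center_ms,
          p2_low_confidence = w_p2$low_confidence)
        cm_p2[[ep$subject_id]] <- cluster_means(rebaseline(ep, w_p2), w_p2,
                                                geo$montage)
        cm_lsw[[ep$subject_id]] <- cluster_means(rebaseline(ep, w_lsw), w_lsw,
                                                 geo$montage)
      }
      atomic_write(file.path(sdir, "windows.json"), function(p)
        jsonlite::write_json(windows, p, auto_unbox = TRUE, digits = NA))
      for (comp in c("P2", "LSW")) {
        amp <- amplitude_table(if (comp == "P2") cm_p2 else cm_lsw)
        write_tsv(amp, file.path(sdir, sprintf("amplitudes_%s.tsv", comp)))
        an <- rm_anova_2x3x3(amp)
        write_tsv(an$effects, file.path(sdir, sprintf("anova_%s.tsv", comp)))
        write_tsv(emm_tukey_posthoc(an),
                  file.path(sdir, sprintf("posthoc_%s.tsv", comp)))
      }
    },
    inverse = {
      pre <- stage_dir(config, "preprocess")
      lf <- read_leadfield(file.path(stage_dir(config, "forward"), "leadfield"))
      windows <- jsonlite::read_json(file.path(stage_dir(config, "erp"),
                                               "windows.json"),
                                     simplifyVector = TRUE)
      w <- eloreta_weights(lf, config$alpha, config$tol)
      inv <- make_inverse_operator(lf, w)
      stems <- sub("\\.json$", "",
                   list.files(pre, pattern = "_clean\\.json$", full.names = TRUE))
      rows <- list()
      for (stem in stems) {
        ep <- read_epochs(stem)
        win <- windows[[ep$subject_id]]
        for (comp in c("P2", "LSW")) {
          cw <- if (comp == "P2")
            component_window("P2", win$p2_center_ms, config$window_ms,
                             epoch_ms = config$epoch_ms)
          else locate_lsw_window(config$window_ms, epoch_ms = config$epoch_ms)
          epb <- rebaseline(ep, cw)
          for (cond in unique(epb$condition)) {
            mom <- apply_inverse_window(inv, epb, cw, cond)
            agg <- roi_aggregate(cdr_scores(mom), geo$masks)
            agg$subject <- ep$subject_id
            agg$component <- comp
            agg$condition <- cond
            rows[[length(rows) + 1L]] <- agg
          }
        }
      }
      cdr <- do.call(rbind, rows)
      write_tsv(cdr, file.path(sdir, "roi_cdr.tsv"))
    },
    stats = {
      cdr <- read_tsv(file.path(stage_dir(config, "inverse"), "roi_cdr.tsv"))
      rep <- build_stat_report(cdr, config$fdr_level)
      write_tsv(rep$table, file.path(sdir, "stat_table.tsv"))
    },
    report = {
      tab <- read_tsv(file.path(stage_dir(config, "stats"), "stat_table.tsv"))
      rep <- structure(list(table = tab, fdr_level = config$fdr_level),
                       class = "smeloc_stat_report")
      truth_path <- file.path(dd, "truth.json")
      truth <- if (file.exists(truth_path)) read_truth(truth_path) else NULL
      atomic_write(file.path(sdir, "report.md"), function(p)
        writeLines(format_stat_report(rep, truth), p))
    })
  invisible(NULL)
}

#' Run the whole pipeline
#'
#' Executes all stages in dependency order; any stage failure aborts with
#' the stage named in the error.
#'
#' @param config A [pipeline_config()].
#' @param force Re-run cached stages.
#' @return Invisibly, the final run manifest.
#' @export
run_all <- function(config, force = FALSE) {
  for (stage in pipeline_stages()) {
    tryCatch(run_stage(config, stage, force = force),
             error = function(e) stopf("stage '%s' failed: %s", stage,
                                       conditionMessage(e)))
  }
  invisible(read_run_manifest(config))
}
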