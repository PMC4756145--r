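#' Configure a full pipeline run
#'
#' Bundles every tunable of the pipeline into one serializable object. The
#' global `seed` fans out to deterministic child seeds for the simulation,
#' ICA and SVM stages, so one integer fixes the whole run.
#'
#' @param sim a [sim_config()].
#' @param ica an [ica_config()].
#' @param svm an [svm_config()].
#' @param qc list of QC thresholds: `max_cumulative_mm`, `max_p2p_trans_mm`,
#'   `max_p2p_rot_deg`.
#' @param band band-pass edges in Hz, `c(low, high)`.
#' @param n_discard initial volumes to drop (default 3).
#' @param clean_network_tcs also band-pass + nuisance-regress the
#'   back-reconstructed network time courses (default FALSE: only ROI
#'   courses receive the temporal cleanup).
#' @param match_method template matching score, `"regression"` or
#'   `"correlation"`.
#' @param sidedness of the paired binomial comparisons (`"one"` or `"two"`).
#' @param out_dir optional output directory; enables stage caching and
#'   artifact files.
#' @param seed global integer seed.
#' @return A `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       ica = ica_config(n_group_components =
                                          sim$n_latent_networks + 4L),
                       svm = svm_config(),
                       qc = list(max_cumulative_mm = 3,
                                 max_p2p_trans_mm = 0.15,
                                 max_p2p_rot_deg = 0.1),
                       band = c(low = 0.009, high = 0.08),
                       n_discard = 3L,
                       clean_network_tcs = FALSE,
                       match_method = "regression",
                       sidedness = "one",
                       out_dir = NULL,
                       seed = 1L) {
  seed <- as.integer(seed)
  sim$seed <- child_seed(seed, 1L)
  ica$seed <- child_seed(seed, 2L)
  svm$seed <- child_seed(seed, 3L)
  structure(list(sim = sim, ica = ica, svm = svm, qc = qc, band = band,
                 n_discard = as.integer(n_discard),
                 clean_network_tcs = isTRUE(clean_network_tcs),
                 match_method = match_method, sidedness = sidedness,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

# Stage cache: keyed by a hash of the stage name and every config section the
# stage depends on. Only used when out_dir is set.
cache_stage <- function(config, stage, depends, compute) {
  if (is.null(config$out_dir)) return(compute())
  dir.create(file.path(config$out_dir, "cache"), showWarnings = FALSE,
             recursive = TRUE)
  key <- rlang::hash(list(stage = stage, depends = depends))
  path <- file.path(config$out_dir, "cache", paste0(stage, "-", key, ".rds"))
  if (file.exists(path)) {
    message(sprintf("[%s] cached result reused", stage))
    return(readRDS(path))
  }
  out <- compute()
  saveRDS(out, path)
  out
}

#' Run the full pipeline: simulate, QC, preprocess, ICA, connect, classify,
#' compare
#'
#' Executes every stage in order on a synthetic cohort and returns a
#' deterministic report: per-family classification summaries, the pairwise
#' paired-binomial comparison table, QC exclusions and provenance. Subjects
#' excluded by QC are dropped from every downstream stage. With `out_dir`
#' set, stage results downstream of the (cheap, deterministic) simulation are
#' cached on disk and reused on reruns with an unchanged configuration.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pre-generated `bold_cohort` (e.g. loaded from
#'   disk); must match `config$sim`.
#' @param verbose print stage progress (default TRUE).
#' @return A `run_report`.
#' @export
run_pipeline <- function(config, cohort = NULL, verbose = TRUE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    say("[%s] done (%.1f s)", stage, t1 - t0)
    t0 <<- t1
  }

  generated <- is.null(cohort)
  if (generated) cohort <- generate_cohort(config$sim)
  truth <- cohort$truth
  tick("simulate")

  n_all <- length(cohort$subjects)
  series <- vector("list", n_all)
  names(series) <- names(cohort$subjects)
  for (s in seq_len(n_all)) {
    series[[s]] <- discard_initial(cohort$subjects[[s]],
                                   n = config$n_discard)
    # internally generated raw volumes are not needed again; release them
    # as we go to keep the peak footprint at one copy of the cohort
    if (generated) cohort$subjects[[s]] <- list(released = TRUE)
  }
  motion <- lapply(cohort$motion, trim_motion, n = config$n_discard)
  qc <- lapply(seq_len(n_all), function(s)
    qc_motion(motion[[s]], series[[s]],
              max_cumulative_mm = config$qc$max_cumulative_mm,
              max_p2p_trans_mm = config$qc$max_p2p_trans_mm,
              max_p2p_rot_deg = config$qc$max_p2p_rot_deg))
  excluded <- vapply(qc, `[[`, TRUE, "excluded")
  keep <- which(!excluded)
  if (length(keep) < 4L)
    stopf("QC excluded %d of %d subjects; too few remain", sum(excluded),
          n_all)
  ids <- truth$subject_ids[keep]
  groups <- truth$group_labels[keep]
  tick("qc")

  dep_pre <- config[c("sim", "qc", "band", "n_discard")]
  roi_tcs <- cache_stage(config, "preprocess", dep_pre, function() {
    lapply(keep, function(s)
      preprocess_subject(series[[s]], motion[[s]], truth$roi_masks,
                         truth$nuisance$masks,
                         low_hz = config$band[["low"]],
                         high_hz = config$band[["high"]]))
  })
  tick("preprocess")

  dep_ica <- config[c("sim", "qc", "band", "n_discard", "ica",
                      "match_method", "clean_network_tcs")]
  ica_out <- cache_stage(config, "ica", dep_ica, function() {
    data <- lapply(series[keep], `[[`, "data")
    red <- concat_reduce(data, config$ica)
    comps <- icasso_stability(t(red$X), config$ica)
    templates <- zscore_rows(truth$network_maps)
    rownames(templates) <- sprintf("network_%02d",
                                   seq_len(nrow(templates)))
    assignment <- match_templates(comps, templates,
                                  method = config$match_method)
    sel <- new_component_set(comps$maps[assignment$component, ,
                                        drop = FALSE],
                             stability = comps$stability[
                               assignment$component])
    rownames(sel$maps) <- assignment$template
    subj <- back_reconstruct(sel, data)
    nw_tcs <- lapply(seq_along(subj), function(i) {
      tc <- subj[[i]]$timecourses
      colnames(tc) <- assignment$template
      if (config$clean_network_tcs) {
        tc <- bandpass(tc, config$band[["low"]], config$band[["high"]],
                       config$sim$tr_seconds)
        tc <- zscore_cols(tc)
      }
      tc
    })
    list(assignment = assignment, stability = comps$stability,
         nw_tcs = nw_tcs)
  })
  tick("ica")

  fams <- all_feature_families(unique(config$sim$roi_table$system))
  sys_of <- setNames(config$sim$roi_table$system, config$sim$roi_table$name)
  dep_conn <- c(dep_ica, config["svm"])
  features <- cache_stage(config, "connect", dep_ica, function()
    lapply(fams, function(f)
      build_feature_matrix(roi_tcs, ica_out$nw_tcs, f, ids, groups,
                           roi_systems_of = sys_of)))
  tick("connect")

  cls <- cache_stage(config, "classify", dep_conn, function()
    lapply(features, loocv, cfg = config$svm))
  tick("classify")

  outcomes <- lapply(cls, `[[`, "outcomes")
  comparisons <- compare_all_families(outcomes, sidedness = config$sidedness)
  tick("compare")

  summaries <- do.call(rbind, lapply(names(cls), function(f) {
    s <- cls[[f]]$summary
    data.frame(family = f, accuracy = s$accuracy,
               sensitivity = s$sensitivity, specificity = s$specificity,
               n_features = ncol(features[[f]]$values), n_subjects = s$n,
               stringsAsFactors = FALSE)
  }))
  report <- structure(list(
    families = summaries,
    comparisons = comparisons,
    outcomes = outcomes,
    qc = list(excluded_ids = truth$subject_ids[excluded],
              reasons = lapply(qc[excluded], `[[`, "reasons"),
              n_analyzed = length(keep)),
    ica = list(assignment = ica_out$assignment,
               stability = ica_out$stability),
    provenance = list(
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
      seed = config$seed,
      stage_seeds = c(sim = config$sim$seed, ica = config$ica$seed,
                      svm = config$svm$seed),
      package_version = as.character(utils::packageVersion("netconsist")))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report_files(report, config$out_dir)
  report
}

write_report_files <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$families, file.path(dir, "classification_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_comparison_table(report$comparisons,
                         file.path(dir, "comparisons.csv"))
  for (f in names(report$outcomes))
    write_outcomes(report$outcomes[[f]],
                   file.path(dir, sprintf("outcomes_%s.csv",
                                          gsub("[^A-Za-z0-9]+", "_", f))))
  writeLines(format_comparison_markdown(report$comparisons),
             file.path(dir, "comparisons.md"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Classification consistency report ==\n")
  cat(sprintf("subjects analyzed: %d (excluded by QC: %d)\n",
              x$qc$n_analyzed, length(x$qc$excluded_ids)))
  df <- x$families
  df$accuracy <- sprintf("%.1f%%", 100 * df$accuracy)
  df$sensitivity <- sprintf("%.2f", df$sensitivity)
  df$specificity <- sprintf("%.2f", df$specificity)
  print(df, row.names = FALSE)
  cat("\nPairwise paired-binomial comparisons (W wins of family_a):\n")
  cp <- x$comparisons
  cp$accuracy_a <- sprintf("%.3f", cp$accuracy_a)
  cp$accuracy_b <- sprintf("%.3f", cp$accuracy_b)
  cp$p_value <- sprintf("%.4f", cp$p_value)
  print(as.data.frame(cp), row.names = FALSE)
  invisible(x)
}

#' Write / read a run configuration as JSON
#'
#' Round-trips every tunable of [run_config()] (the grid, the ROI table and
#' all stage sub-configurations) through a single JSON file.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  sim <- config$sim
  obj <- list(
    seed = config$seed,
    n_discard = config$n_discard,
    band = as.list(config$band),
    qc = config$qc,
    clean_network_tcs = config$clean_network_tcs,
    match_method = config$match_method,
    sidedness = config$sidedness,
    sim = list(
      n_per_group = sim$n_per_group, n_volumes = sim$n_volumes,
      tr_seconds = sim$tr_seconds,
      grid = list(dims = sim$grid$dims, vox_mm = sim$grid$vox_mm,
                  origin_mm = sim$grid$origin_mm),
      n_latent_networks = sim$n_latent_networks,
      roi_table = sim$roi_table,
      baseline_coupling = sim$baseline_coupling,
      effect_size_per_system = as.list(sim$effect_size_per_system),
      within_group_sd = sim$within_group_sd,
      nuisance_amplitudes = as.list(sim$nuisance_amplitudes),
      network_amplitude = sim$network_amplitude,
      roi_amplitude = sim$roi_amplitude, noise_sd = sim$noise_sd,
      baseline_intensity = sim$baseline_intensity,
      motion_step = as.list(sim$motion_step)),
    ica = unclass(config$ica)[c("n_group_components", "n_subject_pcs",
                                "n_icasso_runs", "learning_rate",
                                "max_iter", "tol", "bootstrap")],
    svm = unclass(config$svm)[c("C", "tol", "max_passes",
                                "standardize_in_fold")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- o$sim
  sim <- sim_config(
    n_per_group = s$n_per_group, n_volumes = s$n_volumes,
    tr_seconds = s$tr_seconds,
    grid = bold_grid(s$grid$dims, s$grid$vox_mm, s$grid$origin_mm),
    n_latent_networks = s$n_latent_networks,
    roi_table = as.data.frame(s$roi_table),
    baseline_coupling = s$baseline_coupling,
    effect_size_per_system = unlist(s$effect_size_per_system),
    within_group_sd = s$within_group_sd,
    nuisance_amplitudes = unlist(s$nuisance_amplitudes),
    network_amplitude = s$network_amplitude,
    roi_amplitude = s$roi_amplitude, noise_sd = s$noise_sd,
    baseline_intensity = s$baseline_intensity,
    motion_step = unlist(s$motion_step))
  ica <- do.call(ica_config, o$ica)
  svm <- do.call(svm_config, o$svm)
  run_config(sim = sim, ica = ica, svm = svm, qc = o$qc,
             band = unlist(o$band), n_discard = o$n_discard,
             clean_network_tcs = o$clean_network_tcs,
             match_method = o$match_method, sidedness = o$sidedness,
             seed = o$seed)
}
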