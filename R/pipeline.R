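#' Default pipeline configuration
#'
#' A nested list with one section per stage; every entry can be overridden by
#' a YAML config file. The defaults are the full study conditions: 20
#' subjects, 4 runs of 179 volumes at TR 2.5 s, physiological-noise-model
#' nuisance orders 4/4/2 with heart rate and RVT, 2 mm smoothing, 90 s
#' high-pass, and linear multiclass SVM decoding with leave-one-subject-out
#' folds.
#'
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "somatopipe-out",
    simulate = list(
      n_subjects = 20L, runs_per_subject = 4L,
      grid_shape = c(20L, 20L, 18L), voxel_size_mm = 1.8,
      tr_s = 2.5, n_volumes = 179L,
      snr = c(s1 = 2, thalamus = 0.4, brainstem = 0.15),
      pattern_overlap = 0.5, subject_variability = 0.6, amplitude = 2,
      jitter = 0.05),
    design = list(highpass_s = 90),
    physio = list(cardiac_order = 4L, resp_order = 4L, interaction_order = 2L,
                  extras = c("heart_rate", "rvt")),
    glm = list(fwhm_mm = 2),
    stats = list(n_perm = 5000L, variance_smooth_mm = 5,
                 rois = c("left_cuneate", "right_cuneate",
                          "spinal_trigeminal_left", "spinal_trigeminal_right")),
    mvpa = list(roi_masks = c("s1", "thalamus", "brainstem"),
                searchlight_mask = "brainstem", radius_mm = 3,
                n_perm = 1000L)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys (at the top level or within a section) are rejected; known
#' keys override the defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(user), names(defaults))) {
    if (is.list(defaults[[sec]]) && is.list(user[[sec]])) {
      bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
      if (length(bad))
        stop(sprintf("unknown config keys in section '%s': %s", sec,
                     paste(bad, collapse = ", ")))
    }
  }
  out <- utils::modifyList(defaults, user)
  class(out) <- "pipeline_config"
  out
}

# Deterministic polynomial hash of the deparsed config, for log lines
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# ROI -> the condition whose afferents it relays (planned-contrast target)
.roi_targets <- c(
  left_cuneate = "left_hand", right_cuneate = "right_hand",
  spinal_trigeminal_left = "face", spinal_trigeminal_right = "face",
  vpl_left = "right_hand", vpl_right = "left_hand", vpm = "face",
  s1_hand_left = "right_hand", s1_hand_right = "left_hand", s1_face = "face"
)

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate, first-level GLM with physiological regressors and run
#' exclusion, fixed-effects combination, ROI statistics, sign-flip group
#' inference with TFCE, whole-ROI decoding with a permutation null, and
#' searchlight decoding with cluster-size correction. Writes to
#' `config$out_dir`: the fully resolved configuration
#' (`resolved_config.yaml`), a machine-readable stage log (`log.jsonl`), and
#' a `summary.tsv` of every headline quantity. All randomness derives from
#' `config$seed`.
#'
#' @param config a [default_pipeline_config()]-shaped list.
#' @return Invisibly, a list with the stage results and the `summary` data
#'   frame.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  chash <- config_hash(config)
  log_stage <- function(stage, ...) {
    rec <- list(stage = stage, config_hash = chash, seed = config$seed, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
        file = log_path, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed (config %s): %s",
                   stage, chash, conditionMessage(e)), call. = FALSE))
    log_stage(stage, elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }
  yaml::write_yaml(unclass(config),
                   file.path(config$out_dir, "resolved_config.yaml"))
  sm <- list()
  add <- function(metric, value, digits = 1)
    sm[[length(sm) + 1L]] <<- data.frame(metric = metric,
                                         value = round(value, digits))

  cs <- config$simulate
  cohort <- run_stage("simulate", {
    atlas <- build_phantom_atlas(
      volume_grid(cs$grid_shape, cs$voxel_size_mm))
    effect <- effect_spec(snr = unlist(cs$snr),
                          pattern_overlap = cs$pattern_overlap,
                          subject_variability = cs$subject_variability,
                          amplitude = cs$amplitude)
    generate_cohort(cs$n_subjects, atlas, effect, seed = config$seed,
                    runs_per_subject = cs$runs_per_subject,
                    tr_s = cs$tr_s, n_volumes = cs$n_volumes,
                    jitter = cs$jitter)
  })
  atlas <- attr(cohort, "atlas")

  schedules <- lapply(cohort[[1]]$runs, `[[`, "schedule")
  vols <- nominal_volume_counts(schedules)
  ph <- phase_series(cohort[[1]]$runs[[1]]$trace, cs$n_volumes, cs$tr_s)
  nuis <- do.call(retroicor_regressors,
                  c(list(phases = ph, trace = cohort[[1]]$runs[[1]]$trace),
                    config$physio))
  add("pnm_regressor_columns", ncol(nuis))
  add("task_structure_s", schedule_duration(schedules[[1]]))
  add("trials_per_condition",
      cs$runs_per_subject * sum(schedules[[1]]$condition == "left_hand"))
  add("movement_volumes_per_condition", unname(vols["left_hand"]))
  add("rest_volumes", unname(vols["rest"]))

  glm_res <- run_stage("glm", {
    analyse_cohort_glm(cohort, fwhm_mm = config$glm$fwhm_mm,
                       highpass_s = config$design$highpass_s,
                       physio_config = config$physio)
  })
  excl <- attr(glm_res, "exclusion_report")
  add("runs_excluded", sum(excl$excluded))

  run_stage("roi_stats", {
    z_maps <- lapply(glm_res, function(s) lapply(s$combined, `[[`, "z"))
    roi_tbl <- extract_roi_means(z_maps, atlas, config$stats$rois)
    write.table(roi_tbl, file.path(config$out_dir, "roi_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    reports <- lapply(config$stats$rois, function(roi) {
      tbl <- roi_tbl[roi_tbl$roi == roi, ]
      rm_anova_with_gates(tbl, target = .roi_targets[[roi]])
    })
    names(reports) <- config$stats$rois
    for (roi in config$stats$rois)
      add(paste0("roi_", roi, "_p"), reports[[roi]]$p, digits = 4)
    reports
  })

  group <- run_stage("group_test", {
    face_maps <- lapply(glm_res, function(s) s$combined$face$effect)
    sign_flip_group_test(face_maps, atlas$masks$brainstem, atlas$grid,
                         n_perm = config$stats$n_perm,
                         variance_smooth_mm = config$stats$variance_smooth_mm,
                         seed = config$seed + 1L)
  })
  add("group_face_suprathreshold_voxels", sum(group$p_fwe < 0.05))

  decode <- run_stage("decode", {
    out <- lapply(config$mvpa$roi_masks, function(roi) {
      samples <- assemble_beta_samples(glm_res, atlas$masks[[roi]])
      res <- loso_decode(samples)
      null <- permutation_pvalue(samples, n_perm = config$mvpa$n_perm,
                                 seed = config$seed + 2L,
                                 observed = res$accuracy)
      list(samples = samples, result = res, null = null)
    })
    names(out) <- config$mvpa$roi_masks
    out
  })
  add("decoding_samples", nrow(decode[[1]]$samples$X))
  for (roi in config$mvpa$roi_masks) {
    add(paste0("accuracy_", roi), decode[[roi]]$result$accuracy)
    add(paste0("null_mean_", roi), mean(decode[[roi]]$null$accuracies))
  }

  sl <- run_stage("searchlight", {
    samples <- assemble_beta_samples(
      glm_res, atlas$masks[[config$mvpa$searchlight_mask]])
    obs <- searchlight_map(samples, config$mvpa$radius_mm)
    perms <- searchlight_null_maps(samples, config$mvpa$radius_mm,
                                   n_perm = config$mvpa$n_perm,
                                   seed = config$seed + 3L)
    suppressWarnings(cluster_correct_searchlight(obs, perms))
  })
  add("searchlight_accuracy_cutoff", sl$accuracy_cutoff)
  add("searchlight_cluster_size_cutoff", sl$cluster_size_cutoff)
  add("searchlight_surviving_clusters", nrow(sl$clusters))

  summary_df <- do.call(rbind, sm)
  write.table(summary_df, file.path(config$out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("done")
  invisible(list(cohort = cohort, glm = glm_res, group = group,
                 decode = decode, searchlight = sl, summary = summary_df))
}
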