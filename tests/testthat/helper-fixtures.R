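# Shared fixtures, built once per test run and cached in-process.
# Cohorts are slimmed after the GLM (images and traces dropped) to keep the
# cache small; decoding and ROI statistics only need betas and combined maps.

.fix <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

slim_cohort_glm <- function(cg) {
  out <- lapply(cg, function(subj) {
    subj$runs <- lapply(subj$runs, function(r) r["betas"])
    subj
  })
  attributes(out) <- attributes(cg)
  out
}

# Compact phantom: brainstem of 180 voxels, nuclei 48 active voxels
atlas_compact <- function() cached("atlas_compact", function()
  build_phantom_atlas(volume_grid(c(14L, 10L, 9L), 1.8)))

# Medium phantom used for the accuracy-gradient checks
atlas_medium <- function() cached("atlas_medium", function()
  build_phantom_atlas(volume_grid(c(20L, 20L, 18L), 1.8)))

# 10 subjects x 2 runs on the medium phantom, analysed end to end
fx_medium <- function() cached("fx_medium", function() {
  atlas <- atlas_medium()
  cohort <- generate_cohort(10L, atlas, effect_spec(), seed = 11L,
                            runs_per_subject = 2L)
  glm <- analyse_cohort_glm(cohort)
  list(atlas = atlas, glm = slim_cohort_glm(glm),
       patterns = attr(cohort, "patterns"))
})

# 12 subjects x 2 runs on the compact phantom plus its searchlight map
fx_compact <- function() cached("fx_compact", function() {
  atlas <- atlas_compact()
  cohort <- generate_cohort(12L, atlas, effect_spec(), seed = 11L,
                            runs_per_subject = 2L)
  glm <- slim_cohort_glm(analyse_cohort_glm(cohort))
  samples <- assemble_beta_samples(glm, atlas$masks$brainstem)
  sl <- searchlight_map(samples, radius_mm = 3)
  gt <- attr(cohort, "patterns")$support
  active <- (gt$left_hand | gt$right_hand | gt$face) & atlas$masks$brainstem
  list(atlas = atlas, glm = glm, samples = samples, searchlight = sl,
       active = active)
})

# Synthetic decoding sample set with controllable class separation; features
# live on a small 3-D grid so searchlight machinery can run on it
make_synth_samples <- function(n_subjects, runs_per_subject, shape = c(4, 3, 2),
                               separation = 1, seed = 1, subject_sd = 0.2) {
  n_feat <- prod(shape)
  conds <- c("left_hand", "right_hand", "face")
  withr::with_seed(seed, {
    centroids <- matrix(rnorm(3 * n_feat, 0, separation), 3)
    rows <- list(); labels <- character(); subjects <- character(); runs <- integer()
    for (s in seq_len(n_subjects)) {
      shift <- rnorm(n_feat, 0, subject_sd)
      for (r in seq_len(runs_per_subject)) for (ci in 1:3) {
        rows[[length(rows) + 1L]] <- centroids[ci, ] + shift + rnorm(n_feat)
        labels <- c(labels, conds[ci])
        subjects <- c(subjects, sprintf("sub-%02d", s))
        runs <- c(runs, r)
      }
    }
    structure(list(X = do.call(rbind, rows), labels = factor(labels),
                   subjects = subjects, runs = runs,
                   mask = array(TRUE, dim = shape),
                   grid = volume_grid(shape, 1)),
              class = "beta_sample_set")
  })
}

# Minimal cohort skeleton carrying only displacements (for exclusion tests)
displacement_cohort <- function(disp_matrix) {
  structure(lapply(seq_len(nrow(disp_matrix)), function(s) {
    structure(list(subject_id = sprintf("sub-%02d", s),
                   runs = lapply(disp_matrix[s, ], function(d)
                     list(mean_abs_displacement_mm = d))),
              class = "subject_dataset")
  }), class = "somato_cohort")
}
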