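#' Effect specification for the synthetic cohort
#'
#' Collects the scalars that control how strong and how distinct the simulated
#' condition responses are. `snr` is the ratio of the condition response
#' amplitude to the thermal noise standard deviation in each region; the
#' defaults encode the gradient of signal quality from cortex down to the
#' brainstem (S1 >> thalamus > brainstem) that is characteristic of 3T fMRI of
#' deep structures. `pattern_overlap` is the fraction of a nucleus's active
#' voxels that its neighbour's condition pattern also occupies: at 0 the hand
#' and face patterns occupy disjoint voxels, at 1 they share the same voxels
#' and differ only in their per-voxel weights (so mean activity cannot
#' separate the conditions but multivoxel pattern geometry still can).
#' `subject_variability` is the standard deviation of the per-voxel
#' multiplicative and additive perturbation applied to the shared template to
#' produce each subject's pattern. `amplitude` is the peak condition response
#' in percent signal change of the baseline.
#'
#' @param snr named positive numeric vector with entries `s1`, `thalamus`,
#'   `brainstem`.
#' @param pattern_overlap real in `[0, 1]`.
#' @param subject_variability real `>= 0`.
#' @param amplitude percent signal change, `> 0`.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(snr = c(s1 = 2, thalamus = 0.4, brainstem = 0.15),
                        pattern_overlap = 0.5,
                        subject_variability = 0.6,
                        amplitude = 2) {
  req <- c("s1", "thalamus", "brainstem")
  if (!all(req %in% names(snr)))
    stop("'snr' must be named with entries: ", paste(req, collapse = ", "))
  if (any(snr <= 0)) stop("all SNR values must be > 0")
  if (length(pattern_overlap) != 1L || is.na(pattern_overlap) ||
      pattern_overlap < 0 || pattern_overlap > 1)
    stop("'pattern_overlap' must be a single value in [0, 1]")
  if (subject_variability < 0) stop("'subject_variability' must be >= 0")
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  structure(list(snr = snr[req], pattern_overlap = pattern_overlap,
                 subject_variability = subject_variability,
                 amplitude = amplitude),
            class = "effect_spec")
}

#' Generate condition activity patterns for a cohort
#'
#' Builds, for each movement condition (left hand, right hand, face), a
#' template amplitude map supported on the somatotopically wired nuclei of the
#' phantom atlas, then perturbs the template per subject. Templates carry
#' heterogeneous per-voxel weights (log-normal, unit mean within each nucleus)
#' so that two conditions occupying the same voxels still differ in pattern
#' geometry. A fraction `pattern_overlap` of each cuneate / spinal trigeminal
#' nucleus's voxels is shared with the neighbouring condition's pattern,
#' emulating partial spatial mixing of adjacent hand and face representations.
#'
#' Templates depend only on the atlas, the effect spec, and `template_seed`;
#' the `seed` argument drives only the subject-level perturbations, so
#' different cohorts drawn with different seeds share the same underlying
#' group-level patterns (the property that makes across-subject decoding
#' possible).
#'
#' @param atlas a [build_phantom_atlas()] result.
#' @param effect an [effect_spec()].
#' @param n_subjects number of subjects to draw patterns for.
#' @param seed integer seed for the subject-level perturbations.
#' @param pattern_jitter_sd sd (log scale) of the per-voxel template weights.
#' @param template_seed seed for the shared template draw.
#' @return A `condition_patterns` object: `template` and `subjects[[s]]` are
#'   named lists of 3-D amplitude arrays (baseline units, baseline = 100) per
#'   condition; `support` holds the template support masks.
#' @export
make_condition_patterns <- function(atlas, effect, n_subjects, seed,
                                    pattern_jitter_sd = 0.5,
                                    template_seed = 20L) {
  stopifnot(inherits(atlas, "phantom_atlas"), inherits(effect, "effect_spec"))
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1")
  conditions <- names(atlas$wiring)
  amp <- effect$amplitude             # baseline fixed at 100 => % == units

  templates <- withr::with_seed(template_seed, {
    tl <- lapply(conditions, function(cond) {
      map <- empty_volume(atlas$grid)
      for (nuc in atlas$wiring[[cond]]) {
        idx <- which(atlas$masks[[nuc]])
        w <- exp(rnorm(length(idx), 0, pattern_jitter_sd))
        map[idx] <- amp * w / mean(w)
      }
      map
    })
    names(tl) <- conditions
    # pattern leak between adjacent nuclei: the neighbour's condition gains
    # weight on a seeded fraction of this nucleus's voxels
    if (effect$pattern_overlap > 0) {
      owner_of <- function(nuc) {
        conditions[vapply(atlas$wiring, function(w) nuc %in% w, logical(1))][1]
      }
      for (pair in atlas$adjacent_pairs) for (k in 1:2) {
        nuc <- pair[k]; neighbour <- pair[3L - k]
        own_cond <- owner_of(nuc); other_cond <- owner_of(neighbour)
        idx <- which(atlas$masks[[nuc]])
        n_shared <- round(effect$pattern_overlap * length(idx))
        if (n_shared > 0) {
          shared <- sample(idx, n_shared)
          w <- exp(rnorm(n_shared, 0, pattern_jitter_sd))
          tl[[other_cond]][shared] <- amp * w / mean(w)
        }
      }
    }
    tl
  })
  support <- lapply(templates, function(m) m != 0)

  subjects <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_subjects), function(s) {
      maps <- lapply(conditions, function(cond) {
        m <- templates[[cond]]
        idx <- which(support[[cond]])
        m[idx] <- m[idx] * (1 + rnorm(length(idx), 0, effect$subject_variability)) +
          rnorm(length(idx), 0, effect$subject_variability * amp)
        m
      })
      names(maps) <- conditions
      maps
    })
  })

  structure(list(template = templates, subjects = subjects, support = support,
                 grid = atlas$grid, conditions = conditions, effect = effect),
            class = "condition_patterns")
}
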