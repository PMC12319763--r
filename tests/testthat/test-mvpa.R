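# cohort_glm-shaped skeleton carrying only beta maps
fake_cohort_glm <- function(n_subjects, runs_per_subject, shape,
                            drop_one = FALSE, seed = 1) {
  conds <- c("left_hand", "right_hand", "face")
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_subjects), function(s) {
      runs <- lapply(seq_len(runs_per_subject), function(r) {
        betas <- lapply(conds, function(cc) array(rnorm(prod(shape)), shape))
        names(betas) <- conds
        if (drop_one && s == 1 && r == 1) betas$face <- NULL
        list(betas = betas)
      })
      list(subject_id = sprintf("sub-%02d", s), runs = runs)
    })
  })
  structure(out, atlas = list(grid = volume_grid(shape, 1)),
            class = "cohort_glm")
}

test_that("beta-sample bookkeeping counts subjects x runs x conditions", {
  shape <- c(10, 10, 5)
  mask <- array(FALSE, shape); mask[seq_len(500)] <- TRUE
  one <- assemble_beta_samples(fake_cohort_glm(1, 1, shape), mask)
  expect_equal(nrow(one$X), 3)
  expect_equal(ncol(one$X), 500)
  many <- assemble_beta_samples(fake_cohort_glm(4, 2, shape), mask)
  expect_equal(nrow(many$X), 4 * 2 * 3)
  expect_true(all(table(many$subjects, many$labels) == 2))
  expect_error(
    assemble_beta_samples(fake_cohort_glm(3, 2, shape, drop_one = TRUE), mask),
    "balanced")
})

test_that("a separable sample set decodes perfectly with subject folds", {
  s <- make_synth_samples(6, 2, separation = 20, seed = 2)
  r <- loso_decode(s)
  expect_equal(r$accuracy, 100)
  expect_equal(r$n_folds, 6)
  expect_length(r$fold_accuracies, 6)
  # confusion-matrix consistency
  expect_equal(100 * sum(diag(r$confusion)) / sum(r$confusion), r$accuracy)
  expect_true(all(rowSums(r$confusion) == 12))
  expect_error(loso_decode(make_synth_samples(1, 4)), "2 subjects")
})

test_that("shuffled labels decode at the three-class chance level", {
  s <- make_synth_samples(30, 6, separation = 5, seed = 3)
  shuffled <- s
  shuffled$labels <- withr::with_seed(4, sample(s$labels))
  r <- loso_decode(shuffled)
  expect_lt(abs(r$accuracy - 100 / 3), 3)
})

test_that("relabelling classes permutes the confusion matrix accordingly", {
  s <- make_synth_samples(5, 2, separation = 20, seed = 6)
  r1 <- loso_decode(s)
  perm <- c(left_hand = "face", right_hand = "left_hand", face = "right_hand")
  s2 <- s
  s2$labels <- factor(unname(perm[as.character(s$labels)]),
                      levels = levels(s$labels))
  r2 <- loso_decode(s2)
  for (a in levels(s$labels)) for (b in levels(s$labels))
    expect_equal(r2$confusion[perm[[a]], perm[[b]]], r1$confusion[a, b])
})

test_that("permutation p values follow the proportion-with-floor rule", {
  s <- make_synth_samples(6, 2, separation = 20, seed = 7)
  pn <- permutation_pvalue(s, n_perm = 10, seed = 8)
  expect_length(pn$accuracies, 10)
  expect_equal(pn$observed, 100)
  expect_equal(pn$p, 1 / 10)   # observed beats every shuffle: floored
  # a mid-ranking observation gets an interior p value
  mid <- permutation_pvalue(s, n_perm = 10, seed = 8,
                            observed = median(pn$accuracies))
  expect_gt(mid$p, 0); expect_lt(mid$p, 1)
  null_mean <- mean(pn$accuracies)
  expect_lt(abs(null_mean - 100 / 3), 6)
})

test_that("sphere offsets match exhaustive lattice enumeration", {
  expect_equal(nrow(sphere_offsets(0, 1)), 1)
  # independent oracle: enumerate the full lattice cube and filter
  oracle <- function(radius, vox) {
    n <- 0L
    for (x in -5:5) for (y in -5:5) for (z in -5:5)
      if (sqrt((x * vox)^2 + (y * vox)^2 + (z * vox)^2) <= radius + 1e-9)
        n <- n + 1L
    n
  }
  expect_equal(nrow(sphere_offsets(3, 1)), oracle(3, 1))
  expect_equal(nrow(sphere_offsets(3, 1)), 123)
  expect_equal(nrow(sphere_offsets(1.8, 1.8)), 7)
  expect_equal(nrow(sphere_offsets(2.5, c(1.8, 1.8, 1.8))), 7)
})

test_that("a whole-mask searchlight reproduces the ROI decoding everywhere", {
  s <- make_synth_samples(6, 2, shape = c(4, 3, 2), separation = 2, seed = 9)
  whole <- loso_decode(s)$accuracy
  sl <- searchlight_map(s, radius_mm = 100)
  expect_true(all(abs(sl[s$mask] - whole) < 1e-9))
  expect_true(all(sl[s$mask] >= 0 & sl[s$mask] <= 100))
})

test_that("a signal-free searchlight map is centred on chance", {
  s <- make_synth_samples(14, 3, shape = c(4, 3, 2), separation = 0, seed = 10)
  sl <- searchlight_map(s, radius_mm = 1)
  expect_lt(abs(mean(sl[s$mask]) - 100 / 3), 2)
})

test_that("searchlight accuracy concentrates on the active nuclei", {
  fx <- fx_compact()
  sl <- fx$searchlight
  inactive <- fx$atlas$masks$brainstem & !fx$active
  expect_gt(mean(sl[fx$active]), mean(sl[inactive]))
  cun <- fx$atlas$masks$left_cuneate | fx$atlas$masks$right_cuneate
  expect_gt(mean(sl[cun]), 100 / 3)
})

test_that("cluster correction is exchangeable-null safe and self-consistent", {
  shape <- c(10, 10, 6)
  mask <- array(TRUE, shape)
  smooth_noise <- function(seed, bump = 0) {
    withr::with_seed(seed, {
      m <- array(rnorm(prod(shape), 100 / 3, 3), shape)
      m <- smooth_volume(m, 2.5, grid = volume_grid(shape, 1.8))
      if (bump > 0) m[4:6, 4:6, 3:4] <- m[4:6, 4:6, 3:4] + bump
      m
    })
  }
  # observed identical to every permutation map: nothing may survive
  base <- smooth_noise(1)
  same <- suppressWarnings(cluster_correct_searchlight(
    base, replicate(30, base, simplify = FALSE), mask = mask))
  expect_equal(nrow(same$clusters), 0)

  # an injected hotspot against noise permutations survives and respects
  # the declared cutoffs
  obs <- smooth_noise(2, bump = 15)
  perms <- lapply(3:62, smooth_noise)
  cc <- suppressWarnings(cluster_correct_searchlight(obs, perms, mask = mask))
  expect_gt(nrow(cc$clusters), 0)
  expect_true(all(cc$clusters$size > cc$cluster_size_cutoff))
  expect_true(all(obs[cc$surviving_mask] >= cc$accuracy_cutoff))
  expect_true(cc$clusters$peak_accuracy[1] >= cc$accuracy_cutoff)
})

test_that("decoding accuracy is non-decreasing in the effect SNR", {
  atlas <- atlas_compact()
  base <- effect_spec()
  acc <- vapply(c(0.4, 1, 2.5), function(scale) {
    eff <- effect_spec(snr = base$snr * scale)
    cohort <- generate_cohort(8, atlas, eff, seed = 29, runs_per_subject = 2,
                              n_volumes = 120L, blocks_per_condition = 4L)
    glm <- analyse_cohort_glm(cohort)
    loso_decode(assemble_beta_samples(glm, atlas$masks$brainstem))$accuracy
  }, numeric(1))
  expect_gte(acc[2], acc[1] - 2)
  expect_gte(acc[3], acc[2] - 2)
  expect_gt(acc[3], acc[1])
})

test_that("full pattern overlap defeats mean contrasts but not decoding", {
  atlas <- atlas_compact()
  eff <- effect_spec(pattern_overlap = 1)
  cohort <- generate_cohort(10, atlas, eff, seed = 19, runs_per_subject = 2,
                            n_volumes = 120L, blocks_per_condition = 4L)
  basis <- hrf_basis(2.5)
  cun <- atlas$masks$left_cuneate | atlas$masks$right_cuneate
  tri <- atlas$masks$spinal_trigeminal_left | atlas$masks$spinal_trigeminal_right
  zs <- unlist(lapply(cohort, function(subj) {
    vapply(subj$runs, function(run) {
      fit <- fit_glm(run$image, build_design_matrix(run$schedule, basis))
      cz <- contrast_z(fit, c(left_hand.canonical = 1, face.canonical = -1))
      mean(cz$z[cun])
    }, numeric(1))
  }))
  expect_length(zs, 20)
  expect_lt(abs(mean(zs)), 0.2)
  # the same voxels still support above-chance decoding via pattern geometry
  glm <- analyse_cohort_glm(cohort, fwhm_mm = 0)
  acc <- loso_decode(assemble_beta_samples(glm, cun | tri))$accuracy
  expect_gt(acc, 100 / 3 + 5)
})
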