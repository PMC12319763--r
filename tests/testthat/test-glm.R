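test_that("Gaussian smoothing preserves means and respects fwhm = 0", {
  g <- volume_grid(c(12, 12, 12), 2)
  img <- array(rnorm(12^3), dim = c(12, 12, 12))
  attr(img, "grid") <- g
  expect_identical(smooth_volume(img, 0), img)
  sm <- smooth_volume(img, 4)
  expect_equal(mean(sm), mean(img), tolerance = 1e-6)
  expect_lt(sd(sm), sd(img))
  const <- array(3, dim = c(12, 12, 12))
  expect_equal(smooth_volume(const, 4, grid = g), const, tolerance = 1e-12)
})

test_that("voxelwise OLS matches an independent pseudo-inverse oracle", {
  withr::with_seed(11, {
    n <- 60; p <- 6; v <- 50
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- paste0("c", 1:p)
    Xd <- structure(X, class = c("design_matrix", "matrix"))
    Y <- matrix(rnorm(n * v), n)
    img <- array(t(Y), dim = c(v, 1, 1, n))
    fit <- fit_glm(img, Xd)
    oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
    expect_lt(max(abs(fit$beta - oracle)), 1e-8)
    # residual variance with dof correction
    res <- Y - X %*% oracle
    expect_equal(fit$sigma2, colSums(res^2) / (n - p), tolerance = 1e-10)
    expect_equal(fit$dof, n - p)
  })
})

test_that("all-zero data give all-zero betas and rank problems are named", {
  sched <- make_block_schedule(1, 3, n_volumes = 60L, blocks_per_condition = 2L)
  X <- build_design_matrix(sched, hrf_basis(2.5), highpass_s = NULL)
  img <- array(0, dim = c(3, 3, 3, 60))
  fit <- fit_glm(img, X)
  expect_true(all(fit$beta == 0))
  Xbad <- cbind(X, dup = X[, 1])
  expect_error(fit_glm(img, structure(Xbad, class = class(X))), "dup")
  expect_error(fit_glm(img, X[1:10, ]), "volumes")
})

test_that("orthogonal nuisance columns leave task betas unchanged", {
  withr::with_seed(4, {
    sched <- make_block_schedule(1, 3, n_volumes = 80L, blocks_per_condition = 3L)
    X <- build_design_matrix(sched, hrf_basis(2.5), highpass_s = NULL)
    img <- array(rnorm(27 * 80), dim = c(3, 3, 3, 80))
    fit0 <- fit_glm(img, X)
    extra <- rnorm(80)
    # orthogonalise the extra column against the existing design
    extra <- extra - X %*% solve(crossprod(X), crossprod(X, extra))
    X1 <- structure(cbind(unclass(X), ortho = extra), class = class(X))
    fit1 <- fit_glm(img, X1)
    task <- attr(X, "task_cols")
    expect_lt(max(abs(fit0$beta[task, ] - fit1$beta[task, ])), 1e-8)
  })
})

test_that("null-simulation z statistics are standard normal", {
  withr::with_seed(9, {
    sched <- make_block_schedule(1, 2, n_volumes = 100L, blocks_per_condition = 4L)
    X <- build_design_matrix(sched, hrf_basis(2.5))
    img <- array(rnorm(28 * 28 * 26 * 100), dim = c(28, 28, 26, 100))
    fit <- fit_glm(img, X)
    cz <- contrast_z(fit, vs_rest_weights("face"))
    z <- as.vector(cz$z)
    expect_gt(length(z), 20000)
    expect_lt(abs(mean(z)), 0.05)
    expect_lt(abs(sd(z) - 1), 0.05)
  })
})

test_that("contrast weights must spare the derivative columns", {
  sched <- make_block_schedule(1, 3, n_volumes = 60L, blocks_per_condition = 2L)
  X <- build_design_matrix(sched, hrf_basis(2.5), highpass_s = NULL)
  img <- array(rnorm(8 * 60), dim = c(2, 2, 2, 60))
  fit <- fit_glm(img, X)
  expect_error(contrast_z(fit, c(left_hand.temporal_derivative = 1)),
               "derivative")
  z0 <- contrast_z(fit, rep(0, ncol(X)))
  expect_true(all(z0$z == 0))
  expect_error(contrast_z(fit, c(nonexistent = 1)), "unknown")
})

test_that("a movement-vs-all contrast localises the active condition", {
  atlas <- atlas_compact()
  eff <- effect_spec(subject_variability = 0, pattern_overlap = 0)
  pat <- make_condition_patterns(atlas, eff, 1, seed = 5)
  only_left <- list(left_hand = pat$subjects[[1]]$left_hand)
  sched <- make_block_schedule(1, 7)
  trace <- simulate_physio(447.5, 1, 0.3, 0, seed = 2)
  img <- simulate_run(only_left, sched, trace, atlas, eff,
                      noise = noise_config(thermal_scale = 0.02,
                                           cardiac_amp = 0, resp_amp = 0,
                                           drift_amp = 0, background_sd = 0),
                      seed = 3)
  fit <- fit_glm(img, build_design_matrix(sched, hrf_basis(2.5)))
  cz <- contrast_z(fit, movement_vs_all_weights("left_hand"))
  expect_true(all(cz$z[atlas$masks$left_cuneate] > 3))
})

test_that("the displacement rule excludes runs strictly above 1 mm", {
  coh <- displacement_cohort(matrix(c(0.2, 0.9, 1.0, 1.1), nrow = 1))
  ex <- exclude_runs(coh)
  expect_equal(ex$n_excluded, 1)
  expect_equal(length(ex$cohort[[1]]$runs), 3)
  coh2 <- displacement_cohort(matrix(runif(8, 0, 0.9), nrow = 2))
  expect_equal(exclude_runs(coh2)$n_excluded, 0)
  # a cohort built with exactly 4 of 80 runs above threshold reports 4
  disp <- matrix(0.3, nrow = 20, ncol = 4)
  disp[cbind(c(3, 7, 12, 18), c(1, 4, 2, 3))] <- c(1.2, 1.05, 1.4, 2.0)
  ex80 <- exclude_runs(displacement_cohort(disp))
  expect_equal(nrow(ex80$report), 80)
  expect_equal(ex80$n_excluded, 4)
})

test_that("fixed-effects combination is inverse-variance weighting", {
  mk <- function(e, v) {
    structure(list(effect = array(e, c(2, 2, 2)),
                   variance = array(v, c(2, 2, 2)),
                   z = array(e / sqrt(v), c(2, 2, 2)), dof = 100,
                   weights = c(x = 1), mask = array(TRUE, c(2, 2, 2)),
                   grid = NULL), class = "contrast_map")
  }
  one <- fixed_effects_combine(list(mk(2, 1)))
  expect_equal(one$effect, array(2, c(2, 2, 2)))
  eq <- fixed_effects_combine(list(mk(1, 0.5), mk(3, 0.5)))
  expect_equal(eq$effect, array(2, c(2, 2, 2)))
  k <- 5
  many <- fixed_effects_combine(lapply(1:k, function(i) mk(1, 0.8)))
  expect_equal(many$variance, array(0.8 / k, c(2, 2, 2)))
})

test_that("amplitudes are recovered within 15% at brainstem noise levels", {
  atlas <- atlas_compact()
  eff <- effect_spec(subject_variability = 0)
  pat <- make_condition_patterns(atlas, eff, 1, seed = 5)
  bs <- atlas$masks$brainstem
  basis <- hrf_basis(2.5)
  conds <- c("left_hand", "right_hand", "face")
  # each "cohort" contributes four runs; recovery is assessed on the mean
  # over cohorts of the per-cohort mean recovered-to-injected ratio at the
  # brainstem noise level (the noisiest region of the phantom)
  ratios <- vapply(1:10, function(coh) {
    mean(vapply(1:4, function(r) {
      i <- (coh - 1) * 4 + r
      sched <- make_block_schedule(r, order_seed = coh)
      trace <- simulate_physio(447.5, 1, 0.3, 0.05, seed = 60 + i)
      img <- simulate_run(pat$subjects[[1]], sched, trace, atlas, eff,
                          seed = 700 + i, basis = basis)
      nuis <- retroicor_regressors(phase_series(trace, 179, 2.5),
                                   trace = trace)
      fit <- fit_glm(img, build_design_matrix(sched, basis, nuisance = nuis))
      betas <- canonical_betas(fit)
      mean(vapply(conds, function(cc) {
        truth <- pat$subjects[[1]][[cc]]
        idx <- which(truth != 0 & bs)
        mean(betas[[cc]][idx]) / mean(truth[idx])
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.15)
})
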