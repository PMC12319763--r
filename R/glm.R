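#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing with per-axis sigma `fwhm / (2 sqrt(2 ln 2))`
#' converted from millimetres to voxel units, using reflective boundary
#' handling (the kernel is normalised, so a constant image and the image mean
#' are preserved).
#'
#' @param image 3-D array, or 4-D array (each volume smoothed independently).
#' @param grid the [volume_grid()] of the image (for mm-to-voxel conversion);
#'   defaults to the image's `grid` attribute.
#' @param fwhm_mm full width at half maximum of the kernel (mm); 0 returns
#'   the input unchanged.
#' @return Array of the same shape as the input.
#' @export
smooth_volume <- function(image, fwhm_mm = 2, grid = attr(image, "grid")) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(image)
  if (is.null(grid)) stop("no grid: pass 'grid' or an image with a grid attribute")
  if (length(dim(image)) == 4L) {
    out <- image
    for (tt in seq_len(dim(image)[4]))
      out[, , , tt] <- smooth_volume(image[, , , tt], fwhm_mm, grid)
    return(out)
  }
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  out <- image
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis_reflect(out, k, ax)
  }
  attributes(out) <- attributes(image)
  out
}

# 1-D convolution along one axis of a 3-D array with half-sample symmetric
# (edge-including) reflection; this padding preserves the image sum for any
# symmetric normalised kernel
convolve_axis_reflect <- function(x, kernel, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  idx <- c(pmin(n, rev(seq_len(r))), seq_len(n),
           pmax(1L, n + 1L - seq_len(r)))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

#' Fit a voxelwise first-level GLM
#'
#' Ordinary least squares at every voxel against a shared design matrix, with
#' residual variance corrected for the design's degrees of freedom. No
#' prewhitening is applied (the simulator's thermal noise is white by
#' default).
#'
#' @param run_image 4-D array `(x, y, z, time)`.
#' @param design a [build_design_matrix()] result with `n_volumes` rows.
#' @param mask optional logical 3-D array restricting the fit.
#' @return A `glm_result`: list with `beta` (P x V matrix, V = fitted
#'   voxels), `sigma2` (residual variance per voxel), `dof`, `xtx_inv`,
#'   `design` (column names and attributes), `mask`, `grid`.
#' @export
fit_glm <- function(run_image, design, mask = NULL) {
  d <- dim(run_image)
  if (length(d) != 4L) stop("'run_image' must be 4-D (x, y, z, time)")
  X <- unclass(design)
  if (nrow(X) != d[4])
    stop(sprintf("design rows (%d) do not match run volumes (%d)",
                 nrow(X), d[4]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  dof <- nrow(X) - ncol(X)
  if (dof <= 0) stop("no residual degrees of freedom")

  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  Y <- t(matrix(run_image, ncol = d[4])[as.vector(mask), , drop = FALSE])
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / dof
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = sigma2, dof = dof,
                 xtx_inv = chol2inv(qr.R(qrX)),
                 design = design, mask = mask,
                 grid = attr(run_image, "grid")),
            class = "glm_result")
}

# Reshape a per-voxel vector from a glm_result back into a 3-D map
unmask_map <- function(values, mask, fill = 0) {
  out <- array(fill, dim = dim(mask))
  out[mask] <- values
  out
}

#' Extract canonical-HRF beta maps per condition
#'
#' @param fit a [fit_glm()] result.
#' @return Named list of 3-D beta maps, one per movement condition.
#' @export
canonical_betas <- function(fit) {
  cols <- attr(fit$design, "canonical_cols")
  maps <- lapply(cols, function(cn) unmask_map(fit$beta[cn, ], fit$mask))
  names(maps) <- names(cols)
  maps
}

#' Contrast effect, variance, and z maps
#'
#' Computes `t = w'beta / sqrt(sigma2 * w' (X'X)^-1 w)` per voxel and converts
#' it to a z statistic through the t distribution with the fit's degrees of
#' freedom. Only canonical-HRF columns may carry weight: nonzero weights on
#' temporal or dispersion derivative columns violate the inference contract
#' and raise an error.
#'
#' @param fit a [fit_glm()] result.
#' @param weights numeric contrast vector. Either full length P (design
#'   columns, in order) or a named vector over a subset of columns
#'   (unnamed/omitted columns get weight 0).
#' @return A `contrast_map`: list of 3-D arrays `effect`, `variance`, `z`,
#'   plus `weights` and `mask`.
#' @export
contrast_z <- function(fit, weights) {
  cols <- rownames(fit$beta)
  if (!is.null(names(weights))) {
    unknown <- setdiff(names(weights), cols)
    if (length(unknown))
      stop("unknown design columns in weights: ",
           paste(unknown, collapse = ", "))
    w <- setNames(numeric(length(cols)), cols)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != length(cols))
      stop(sprintf("weights length (%d) != design columns (%d)",
                   length(weights), length(cols)))
    w <- setNames(as.numeric(weights), cols)
  }
  deriv <- grepl("\\.(temporal|dispersion)_derivative$", cols)
  if (any(w[deriv] != 0))
    stop("contrast weights on derivative columns must be zero; ",
         "only the canonical regressor is carried to inference")

  eff <- drop(crossprod(w, fit$beta))
  wvw <- drop(crossprod(w, fit$xtx_inv %*% w))
  varmap <- fit$sigma2 * wvw
  tmap <- ifelse(varmap > 0, eff / sqrt(varmap), 0)
  zmap <- t_to_z(tmap, fit$dof)
  structure(list(effect = unmask_map(eff, fit$mask),
                 variance = unmask_map(varmap, fit$mask),
                 z = unmask_map(zmap, fit$mask),
                 dof = fit$dof, weights = w, mask = fit$mask,
                 grid = fit$grid),
            class = "contrast_map")
}

# Tail-stable t -> z probability transform
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  pos <- t >= 0
  z[pos] <- -qnorm(pt(t[pos], df, lower.tail = FALSE, log.p = TRUE),
                   log.p = TRUE)
  z[!pos] <- qnorm(pt(t[!pos], df, lower.tail = TRUE, log.p = TRUE),
                   log.p = TRUE)
  z
}

#' Movement-versus-all contrast weights
#'
#' `+1` on the target condition's canonical column and `-1/2` on each other
#' movement condition's canonical column.
#'
#' @param target one of `"left_hand"`, `"right_hand"`, `"face"`.
#' @param conditions the movement conditions present in the design.
#' @return Named weight vector for [contrast_z()].
#' @export
movement_vs_all_weights <- function(target,
                                    conditions = .movement_conditions) {
  if (!target %in% conditions) stop("unknown target condition: ", target)
  w <- setNames(rep(-0.5, length(conditions)),
                paste0(conditions, ".canonical"))
  w[paste0(target, ".canonical")] <- 1
  w
}

#' Condition-versus-rest contrast weights
#'
#' `+1` on the target's canonical column; rest is the implicit baseline.
#'
#' @inheritParams movement_vs_all_weights
#' @return Named weight vector for [contrast_z()].
#' @export
vs_rest_weights <- function(target) {
  setNames(1, paste0(target, ".canonical"))
}

#' Apply the head-motion run-exclusion rule
#'
#' Drops runs whose mean absolute displacement exceeds 1 mm (strictly
#' greater; a run at exactly 1 mm is retained).
#'
#' @param cohort a [generate_cohort()] result.
#' @param threshold_mm exclusion threshold (mm).
#' @return List with `cohort` (runs removed; atlas/effect attributes kept)
#'   and `report`, a data frame of subject, run, displacement, excluded.
#' @export
exclude_runs <- function(cohort, threshold_mm = 1) {
  report <- do.call(rbind, lapply(cohort, function(subj) {
    data.frame(subject = subj$subject_id,
               run = seq_along(subj$runs),
               mean_abs_displacement_mm = vapply(
                 subj$runs, `[[`, numeric(1), "mean_abs_displacement_mm"),
               stringsAsFactors = FALSE)
  }))
  report$excluded <- report$mean_abs_displacement_mm > threshold_mm
  pruned <- lapply(cohort, function(subj) {
    keep <- vapply(subj$runs, function(r)
      r$mean_abs_displacement_mm <= threshold_mm, logical(1))
    subj$runs <- subj$runs[keep]
    subj
  })
  attributes(pruned) <- attributes(cohort)
  list(cohort = pruned, report = report,
       n_excluded = sum(report$excluded))
}

#' Fixed-effects combination of run-level contrasts
#'
#' Inverse-variance-weighted average of run effects: combined effect
#' `sum(e_i / v_i) / sum(1 / v_i)`, combined variance `1 / sum(1 / v_i)`, and
#' z recomputed as `effect / sqrt(variance)` (normal reference, as in
#' fixed-effects run averaging).
#'
#' @param run_contrasts list of [contrast_z()] results (>= 1) on one grid.
#' @return A `contrast_map` with combined `effect`, `variance`, `z`.
#' @export
fixed_effects_combine <- function(run_contrasts) {
  if (!length(run_contrasts)) stop("need at least one run contrast")
  if (length(run_contrasts) == 1L) return(run_contrasts[[1L]])
  eff <- lapply(run_contrasts, `[[`, "effect")
  v <- lapply(run_contrasts, `[[`, "variance")
  wsum <- Reduce(`+`, lapply(v, function(x) ifelse(x > 0, 1 / x, 0)))
  num <- Reduce(`+`, mapply(function(e, x)
    ifelse(x > 0, e / x, 0), eff, v, SIMPLIFY = FALSE))
  combined_var <- ifelse(wsum > 0, 1 / wsum, 0)
  combined_eff <- ifelse(wsum > 0, num / wsum, 0)
  zmap <- ifelse(combined_var > 0, combined_eff / sqrt(combined_var), 0)
  structure(list(effect = combined_eff, variance = combined_var, z = zmap,
                 dof = Inf, weights = run_contrasts[[1L]]$weights,
                 mask = run_contrasts[[1L]]$mask,
                 grid = run_contrasts[[1L]]$grid),
            class = "contrast_map")
}

#' First- and second-level GLM analysis of a cohort
#'
#' For each run of each subject: build the design (canonical + derivative
#' task regressors, RETROICOR nuisance regressors from the run's physio
#' trace, DCT drift), optionally smooth, fit the GLM, and compute
#' condition-versus-rest contrasts. Within each subject, runs are combined by
#' fixed effects; the >1 mm head-motion exclusion rule applies to this
#' combination step only, so every run still yields beta maps for decoding
#' (as in a pipeline whose decoding GLM retains all acquired runs).
#'
#' @param cohort a [generate_cohort()] result.
#' @param fwhm_mm smoothing kernel FWHM (mm); 0 disables.
#' @param highpass_s DCT high-pass cutoff (s).
#' @param physio_config list of arguments for [retroicor_regressors()]
#'   (orders and extras); `NULL` omits physiological regressors.
#' @param mask optional logical analysis mask.
#' @param exclude_threshold_mm displacement above which a run is left out of
#'   the fixed-effects combination; `Inf` retains all runs.
#' @return A `cohort_glm`: list per subject with `subject_id`, `runs` (each
#'   with `fit`, per-condition `betas`, `retained`), and `combined`
#'   (per-condition fixed-effects `contrast_map`s over retained runs);
#'   exclusion report attached as an attribute.
#' @export
analyse_cohort_glm <- function(cohort, fwhm_mm = 2, highpass_s = 90,
                               physio_config = list(), mask = NULL,
                               exclude_threshold_mm = 1) {
  atlas <- attr(cohort, "atlas")
  excl <- exclude_runs(cohort, threshold_mm = exclude_threshold_mm)
  basis_cache <- new.env(parent = emptyenv())
  out <- lapply(cohort, function(subj) {
    runs <- lapply(subj$runs, function(run) {
      tr <- attr(run$schedule, "tr_s")
      n_vol <- attr(run$schedule, "n_volumes")
      key <- format(tr)
      if (is.null(basis_cache[[key]])) basis_cache[[key]] <- hrf_basis(tr)
      basis <- basis_cache[[key]]
      nuis <- NULL
      if (!is.null(physio_config)) {
        ph <- phase_series(run$trace, n_vol, tr)
        nuis <- do.call(retroicor_regressors,
                        c(list(phases = ph, trace = run$trace), physio_config))
      }
      design <- build_design_matrix(run$schedule, basis, nuisance = nuis,
                                    highpass_s = highpass_s)
      img <- run$image
      if (fwhm_mm > 0) img <- smooth_volume(img, fwhm_mm, grid = atlas$grid)
      fit <- fit_glm(img, design, mask = mask)
      list(fit = fit, betas = canonical_betas(fit),
           retained = run$mean_abs_displacement_mm <= exclude_threshold_mm)
    })
    retained <- vapply(runs, `[[`, logical(1), "retained")
    if (!any(retained))
      stop("all runs of ", subj$subject_id,
           " exceed the displacement threshold")
    combined <- lapply(.movement_conditions, function(cond) {
      fixed_effects_combine(lapply(runs[retained], function(r)
        contrast_z(r$fit, vs_rest_weights(cond))))
    })
    names(combined) <- .movement_conditions
    list(subject_id = subj$subject_id, runs = runs, combined = combined)
  })
  structure(out, exclusion_report = excl$report, atlas = atlas,
            class = "cohort_glm")
}
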