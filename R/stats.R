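#' Threshold-free cluster enhancement
#'
#' For each voxel, integrates `extent(h)^E * h^H * dh` over thresholds `h`
#' from `dh` to the map maximum in steps of `dh`, where `extent(h)` is the
#' size of the suprathreshold (`value >= h`) connected component containing
#' the voxel. Only positive map values are enhanced.
#'
#' @param stat_map numeric 3-D array.
#' @param mask optional logical 3-D array; enhancement is computed within it.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; defaults to `max(stat_map) / 100`.
#' @param connectivity component connectivity, 26 (default) or 6.
#' @return Enhanced map (3-D array, 0 outside the mask).
#' @export
tfce <- function(stat_map, mask = NULL, E = 0.5, H = 2, dh = NULL,
                 connectivity = 26L) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(stat_map))
  pos <- stat_map * (stat_map > 0) * mask
  peak <- max(pos)
  out <- array(0, dim = dim(stat_map))
  if (peak <= 0) return(out)
  if (is.null(dh)) dh <- peak / 100
  if (dh <= 0) stop("'dh' must be > 0")
  lab <- NULL
  n_prev <- -1L
  for (h in seq(dh, peak, by = dh)) {
    supra <- pos >= h
    n_supra <- sum(supra)
    if (n_supra == 0L) break
    # suprathreshold sets are nested, so an unchanged count means an
    # unchanged set: reuse the previous labelling
    if (n_supra != n_prev) {
      lab <- label_components(supra, connectivity)
      n_prev <- n_supra
    }
    sizes <- attr(lab, "sizes")
    inside <- lab > 0L
    out[inside] <- out[inside] + sizes[lab[inside]]^E * h^H * dh
  }
  out
}

#' Mean ROI statistic per subject and condition
#'
#' Averages each subject's per-condition z (or effect) map over each named
#' ROI mask of the atlas.
#'
#' @param subject_maps list over subjects; each element a named list of 3-D
#'   maps per condition (e.g. the `combined` z maps of
#'   [analyse_cohort_glm()]).
#' @param atlas a [build_phantom_atlas()] result.
#' @param roi_names character vector of atlas mask names.
#' @return A `roi_stats_table` data frame: `subject`, `roi`, `condition`,
#'   `value` (one row per combination).
#' @export
extract_roi_means <- function(subject_maps, atlas, roi_names) {
  for (roi in roi_names) {
    if (is.null(atlas$masks[[roi]]))
      stop("unknown ROI: ", roi)
    if (!any(atlas$masks[[roi]]))
      stop("empty ROI mask: ", roi)
  }
  rows <- list()
  for (s in seq_along(subject_maps)) {
    maps <- subject_maps[[s]]
    for (roi in roi_names) {
      m <- atlas$masks[[roi]]
      for (cond in names(maps)) {
        if (!identical(dim(maps[[cond]]), dim(m)))
          stop("map and atlas grids differ for ROI ", roi)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, roi = roi, condition = cond,
          value = mean(maps[[cond]][m]), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("roi_stats_table", "data.frame")
  out
}

#' Replace extreme values by the cell mean
#'
#' Single-pass rule: the mean and standard deviation are computed on the full
#' cell, and entries farther than `n_sd` standard deviations from the mean
#' are replaced by that mean.
#'
#' @param x numeric vector (one condition cell across subjects), length >= 3.
#' @param n_sd replacement threshold in standard deviations.
#' @return List with `values` (adjusted vector) and `n_replaced`.
#' @export
replace_outliers <- function(x, n_sd = 2.5) {
  if (length(x) < 3L) stop("need at least 3 values per cell")
  m <- mean(x)
  s <- sd(x)
  out <- if (s > 0) abs(x - m) > n_sd * s else rep(FALSE, length(x))
  x[out] <- m
  list(values = x, n_replaced = sum(out))
}

# Greenhouse-Geisser epsilon from the condition covariance matrix
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  C <- diag(k) - 1 / k
  B <- C %*% S %*% C
  sum(diag(B))^2 / ((k - 1) * sum(B * B))
}

#' Repeated-measures ROI test with normality and sphericity gates
#'
#' Implements the gated testing procedure for one ROI's subject-by-condition
#' table: per-cell outlier replacement (2.5 sd rule), Shapiro-Wilk normality
#' per condition cell, then either (a) repeated-measures ANOVA (via
#' `aov(value ~ condition + Error(subject/condition))`) with partial eta
#' squared, Mauchly's sphericity test and Greenhouse-Geisser correction when
#' sphericity fails, and paired-t planned contrasts of the target condition
#' against each non-target with Bonferroni correction; or (b), when any cell
#' violates normality, Friedman's test with Kendall's W and Dunn's post-hoc
#' z-tests of the target against each non-target.
#'
#' @param tbl data frame with columns `subject`, `condition`, `value` (one
#'   ROI; >= 3 subjects, >= 2 conditions, complete cells).
#' @param target the condition whose planned contrasts are reported.
#' @param alpha_gate significance level of the normality/sphericity gates.
#' @param outlier_sd threshold for [replace_outliers()]; `NULL` disables.
#' @return A `test_report`: list with `method`, `statistic`, `df`, `p`,
#'   `effect_size` (named `eta2_p` or `kendall_w`), `normality`,
#'   `sphericity`, `contrasts` (data frame with `p` and `p_corrected`),
#'   `n_outliers_replaced`.
#' @export
rm_anova_with_gates <- function(tbl, target, alpha_gate = 0.05,
                                outlier_sd = 2.5) {
  conds <- unique(tbl$condition)
  if (length(conds) < 2L) stop("need at least 2 conditions")
  if (!target %in% conds) stop("target condition not in table: ", target)
  wide <- tapply(tbl$value, list(tbl$subject, tbl$condition), mean)
  wide <- wide[, conds, drop = FALSE]
  if (anyNA(wide)) stop("incomplete subject x condition table")
  n <- nrow(wide); k <- ncol(wide)
  if (n < 3L) stop("need at least 3 subjects")

  n_out <- 0L
  if (!is.null(outlier_sd)) {
    for (j in seq_len(k)) {
      r <- replace_outliers(wide[, j], outlier_sd)
      wide[, j] <- r$values
      n_out <- n_out + r$n_replaced
    }
  }

  shapiro_p <- apply(wide, 2, function(v) {
    if (sd(v) == 0) return(NA_real_)
    shapiro.test(v)$p.value
  })
  normal <- all(is.na(shapiro_p) | shapiro_p >= alpha_gate)
  others <- setdiff(conds, target)

  if (normal) {
    # degenerate table: no within-subject variation between conditions
    scale_sd <- sd(as.vector(wide))
    if (max(abs(wide - rowMeans(wide))) <= 1e-10 * max(scale_sd, 1)) {
      contrasts <- data.frame(comparison = paste(target, "vs", others),
                              statistic = 0, p = 1, p_corrected = 1,
                              stringsAsFactors = FALSE)
      report <- list(method = "rm_anova", statistic = 0,
                     df = c(df1 = k - 1, df2 = (n - 1) * (k - 1)), p = 1,
                     effect_size = c(eta2_p = 0),
                     sphericity = list(test = NA_real_, p = NA_real_,
                                       epsilon = 1, corrected = FALSE),
                     normality = shapiro_p, normal = normal,
                     contrasts = contrasts, n_outliers_replaced = n_out)
      class(report) <- "test_report"
      return(report)
    }
    long <- data.frame(subject = factor(rep(rownames(wide), k)),
                       condition = factor(rep(colnames(wide), each = n)),
                       value = as.vector(wide))
    fit <- aov(value ~ condition + Error(subject/condition), data = long)
    smry <- summary(fit)[["Error: subject:condition"]][[1]]
    ss_cond <- smry["condition", "Sum Sq"]
    ss_err <- smry["Residuals", "Sum Sq"]
    Fval <- smry["condition", "F value"]
    df1 <- k - 1; df2 <- (n - 1) * (k - 1)
    if (!is.finite(Fval)) { Fval <- 0; p <- 1 } else
      p <- smry["condition", "Pr(>F)"]
    eta2 <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0

    sphericity <- list(test = NA_real_, p = NA_real_, epsilon = 1,
                       corrected = FALSE)
    if (k > 2L && all(apply(wide, 2, sd) > 0)) {
      mlm <- lm(wide ~ 1)
      mt <- tryCatch(mauchly.test(mlm, X = ~1), error = function(e) NULL)
      if (!is.null(mt)) {
        sphericity$test <- unname(mt$statistic)
        sphericity$p <- mt$p.value
        if (mt$p.value < alpha_gate) {
          eps <- gg_epsilon(wide)
          sphericity$epsilon <- eps
          sphericity$corrected <- TRUE
          if (Fval > 0)
            p <- stats::pf(Fval, eps * df1, eps * df2, lower.tail = FALSE)
        }
      }
    }
    contrasts <- do.call(rbind, lapply(others, function(cd) {
      tt <- tryCatch(stats::t.test(wide[, target], wide[, cd], paired = TRUE),
                     error = function(e) list(statistic = 0, p.value = 1))
      data.frame(comparison = paste(target, "vs", cd),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
    contrasts$p_corrected <- pmin(1, contrasts$p * length(others))
    report <- list(method = "rm_anova", statistic = Fval,
                   df = c(df1 = df1, df2 = df2), p = p,
                   effect_size = c(eta2_p = eta2),
                   sphericity = sphericity)
  } else {
    ft <- friedman.test(wide)
    chi2 <- unname(ft$statistic)
    W <- chi2 / (n * (k - 1))
    ranks <- t(apply(wide, 1, rank))
    rbar <- colMeans(ranks)
    se <- sqrt(k * (k + 1) / (6 * n))
    contrasts <- do.call(rbind, lapply(others, function(cd) {
      z <- (rbar[target] - rbar[cd]) / se
      data.frame(comparison = paste(target, "vs", cd),
                 statistic = z, p = 2 * pnorm(-abs(z)),
                 stringsAsFactors = FALSE)
    }))
    contrasts$p_corrected <- pmin(1, contrasts$p * length(others))
    report <- list(method = "friedman", statistic = chi2,
                   df = c(df = unname(ft$parameter)), p = ft$p.value,
                   effect_size = c(kendall_w = W),
                   sphericity = list(test = NA_real_, p = NA_real_,
                                     epsilon = NA_real_, corrected = FALSE))
  }
  report$normality <- shapiro_p
  report$normal <- normal
  report$contrasts <- contrasts
  report$n_outliers_replaced <- n_out
  class(report) <- "test_report"
  report
}

#' Sign-flip one-sample group test with TFCE and FWE correction
#'
#' Computes a pseudo-t map (subject mean over smoothed variance), enhances it
#' with TFCE, and builds the familywise null by randomly sign-flipping the
#' subject maps `n_perm` times, recording the maximum TFCE value within the
#' mask for each flip. Voxelwise FWE-corrected p values are the proportion of
#' the max-TFCE null at or above each observed enhanced value, floored at
#' `1/n_perm`.
#'
#' @param subject_maps list of 3-D effect maps (>= 2 subjects, same shape).
#' @param mask logical 3-D array.
#' @param grid the [volume_grid()] (for variance smoothing in mm).
#' @param n_perm number of sign-flip permutations.
#' @param variance_smooth_mm FWHM of the Gaussian applied to the variance
#'   map (mm).
#' @param seed integer seed.
#' @param E,H,dh,connectivity TFCE parameters (see [tfce()]); `dh` defaults
#'   to 1/100 of the observed pseudo-t maximum and is reused for all
#'   permutations.
#' @return A `group_permutation_result`: list with `stat_map` (pseudo-t),
#'   `tfce_map`, `p_fwe` (1 outside the mask), `null_max`, `n_perm`, `mask`.
#' @export
sign_flip_group_test <- function(subject_maps, mask, grid, n_perm = 5000L,
                                 variance_smooth_mm = 5, seed = 1L,
                                 E = 0.5, H = 2, dh = NULL,
                                 connectivity = 26L) {
  n <- length(subject_maps)
  if (n < 2L) stop("need at least 2 subject maps")
  shape <- dim(subject_maps[[1]])
  for (m in subject_maps)
    if (!identical(dim(m), shape)) stop("subject maps differ in shape")
  if (n_perm < 100L)
    warning("n_perm < 100: FWE p values will be very coarse")

  M <- vapply(subject_maps, function(m) m[mask], numeric(sum(mask)))
  M <- t(M)                                # subjects x voxels
  ss <- colSums(M^2)

  pseudo_t <- function(signs) {
    mf <- colMeans(signs * M)
    vf <- (ss - n * mf^2) / (n - 1)
    vmap <- unmask_map(vf, mask)
    svf <- smooth_volume(vmap, variance_smooth_mm, grid = grid)[mask]
    ifelse(svf > 0, mf / sqrt(svf / n), 0)
  }

  t_obs <- pseudo_t(rep(1, n))
  stat_map <- unmask_map(t_obs, mask)
  if (is.null(dh)) {
    peak <- max(stat_map)
    dh <- if (peak > 0) peak / 100 else 0.01
  }
  tfce_obs <- tfce(stat_map, mask, E = E, H = H, dh = dh,
                   connectivity = connectivity)

  null_max <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      tm <- unmask_map(pseudo_t(signs), mask)
      max(tfce(tm, mask, E = E, H = H, dh = dh,
               connectivity = connectivity))
    }, numeric(1))
  })

  obs_vals <- tfce_obs[mask]
  p <- vapply(obs_vals, function(v) mean(null_max >= v), numeric(1))
  p <- pmax(p, 1 / n_perm)
  p_map <- unmask_map(p, mask, fill = 1)
  structure(list(stat_map = stat_map, tfce_map = tfce_obs, p_fwe = p_map,
                 null_max = null_max, n_perm = as.integer(n_perm),
                 mask = mask, dh = dh),
            class = "group_permutation_result")
}
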