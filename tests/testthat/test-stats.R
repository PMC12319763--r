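test_that("ROI means agree with an exhaustive voxel loop", {
  atlas <- build_phantom_atlas(volume_grid(c(12, 10, 9), 1))
  withr::with_seed(3, {
    maps <- list(list(face = array(rnorm(prod(atlas$grid$shape)),
                                   dim = atlas$grid$shape),
                      left_hand = array(rnorm(prod(atlas$grid$shape)),
                                        dim = atlas$grid$shape)))
  })
  tbl <- extract_roi_means(maps, atlas, c("left_cuneate", "vpm"))
  for (i in seq_len(nrow(tbl))) {
    m <- atlas$masks[[tbl$roi[i]]]
    vox <- which(m, arr.ind = TRUE)
    acc <- 0
    for (j in seq_len(nrow(vox)))
      acc <- acc + maps[[1]][[tbl$condition[i]]][vox[j, 1], vox[j, 2], vox[j, 3]]
    expect_equal(tbl$value[i], acc / nrow(vox))
  }
  const <- list(list(face = array(7, dim = atlas$grid$shape)))
  expect_true(all(extract_roi_means(const, atlas, "vpm")$value == 7))
  two <- atlas
  expect_equal(extract_roi_means(
    list(list(face = {
      a <- array(0, atlas$grid$shape)
      a[atlas$masks$vpm] <- c(1, 3, rep(2, sum(atlas$masks$vpm) - 2)); a
    })), atlas, "vpm")$value, 2)
  expect_error(extract_roi_means(maps, atlas, "nonexistent"), "unknown ROI")
})

test_that("the 2.5-sd outlier rule is single-pass on the full cell", {
  r <- replace_outliers(c(1, 2, 3, 2, 1))
  expect_equal(r$n_replaced, 0)
  expect_equal(r$values, c(1, 2, 3, 2, 1))
  # a lone extreme value inflates the full-cell sd enough to mask itself:
  # sd = sqrt(8000/4) = 44.7, |100 - 20| = 80 < 2.5 * 44.7
  r2 <- replace_outliers(c(0, 0, 0, 0, 100))
  expect_equal(r2$n_replaced, 0)
  expect_equal(r2$values, c(0, 0, 0, 0, 100))
  # same masking with a smaller cell: sd = 2.04, |5 - 0.83| = 4.17 < 5.1
  x <- c(0.1, 0.0, -0.1, 0.05, -0.05, 5.0)
  r3 <- replace_outliers(x)
  expect_equal(r3$n_replaced, 0)
  # in a larger cell the same extreme exceeds the inflated threshold:
  # mean = 1, sd = sqrt(90/9) = 3.16, |10 - 1| = 9 > 2.5 * 3.16 = 7.9
  x4 <- c(rep(0, 9), 10)
  r4 <- replace_outliers(x4)
  expect_equal(r4$n_replaced, 1)
  expect_equal(r4$values[10], 1)
  expect_error(replace_outliers(c(1, 2)), "3 values")
})

test_that("repeated-measures F matches the textbook sum-of-squares split", {
  tbl <- data.frame(subject = rep(1:3, each = 3),
                    condition = rep(c("a", "b", "c"), 3),
                    value = c(4.1, 5.3, 6.0,
                              3.8, 5.1, 5.7,
                              4.4, 5.6, 6.5))
  rep_ <- rm_anova_with_gates(tbl, target = "c", outlier_sd = NULL)
  expect_equal(rep_$method, "rm_anova")
  # brute-force partition of sums of squares
  wide <- matrix(tbl$value, 3, 3, byrow = TRUE)
  gm <- mean(wide)
  ss_cond <- 3 * sum((colMeans(wide) - gm)^2)
  ss_subj <- 3 * sum((rowMeans(wide) - gm)^2)
  ss_tot <- sum((wide - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_oracle <- (ss_cond / 2) / (ss_err / 4)
  expect_equal(unname(rep_$statistic), F_oracle, tolerance = 1e-10)
  expect_equal(unname(rep_$effect_size["eta2_p"]),
               ss_cond / (ss_cond + ss_err), tolerance = 1e-10)
  expect_equal(nrow(rep_$contrasts), 2)
  expect_true(all(rep_$contrasts$p_corrected >= rep_$contrasts$p))
})

test_that("constant condition effects give a null F and p of 1", {
  tbl <- data.frame(subject = rep(1:4, each = 3),
                    condition = rep(c("a", "b", "c"), 4),
                    value = rep(c(1.2, 0.4, 2.2, 1.7), each = 3))
  rep_ <- rm_anova_with_gates(tbl, target = "a", outlier_sd = NULL)
  expect_equal(unname(rep_$statistic), 0)
  expect_equal(rep_$p, 1)
})

test_that("non-normal cells route to Friedman with a rank-sum oracle", {
  wide <- rbind(c(1.0, 2.0, 3.5),
                c(0.5, 1.8, 2.9),
                c(1.1, 2.4, 3.0),
                c(0.2, 1.1, 2.5),
                c(0.9, 2.6, 3.3))
  tbl <- data.frame(subject = rep(1:5, times = 3),
                    condition = rep(c("a", "b", "c"), each = 5),
                    value = as.vector(wide))
  rep_ <- rm_anova_with_gates(tbl, target = "c", alpha_gate = 1,
                              outlier_sd = NULL)
  expect_equal(rep_$method, "friedman")
  # exhaustive rank-based oracle on the 5x3 table
  R <- t(apply(wide, 1, rank))
  n <- 5; k <- 3
  chi_oracle <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  expect_equal(unname(rep_$statistic), chi_oracle, tolerance = 1e-10)
  expect_equal(unname(rep_$effect_size["kendall_w"]),
               chi_oracle / (n * (k - 1)), tolerance = 1e-10)
  z_oracle <- (mean(R[, 3]) - mean(R[, 1])) / sqrt(k * (k + 1) / (6 * n))
  i <- which(rep_$contrasts$comparison == "c vs a")
  expect_equal(rep_$contrasts$statistic[i], z_oracle, tolerance = 1e-10)
  expect_true(all(rep_$contrasts$p_corrected >= rep_$contrasts$p))
  expect_true(all(rep_$contrasts$p_corrected <= 1))
})

test_that("a strong target effect is detected in nearly all replicates", {
  hits <- withr::with_seed(21, {
    vapply(1:100, function(i) {
      wide <- cbind(rnorm(20, 0), rnorm(20, 0), rnorm(20, 2))
      tbl <- data.frame(subject = rep(1:20, times = 3),
                        condition = rep(c("a", "b", "target"), each = 20),
                        value = as.vector(wide))
      rep_ <- rm_anova_with_gates(tbl, target = "target")
      all(rep_$contrasts$p_corrected < 0.05)
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("TFCE enhances by the threshold-integral definition", {
  zero <- array(0, c(4, 4, 4))
  expect_equal(tfce(zero), zero)
  single <- array(0, c(5, 5, 5)); single[3, 3, 3] <- 1
  expect_equal(tfce(single, dh = 0.5)[3, 3, 3],
               sqrt(1) * 0.5^2 * 0.5 + sqrt(1) * 1^2 * 0.5)
  # doubling the map never decreases any enhanced value
  withr::with_seed(5, {
    for (i in 1:5) {
      m <- array(pmax(rnorm(6^3), 0), c(6, 6, 6))
      e1 <- tfce(m, dh = max(m) / 50)
      e2 <- tfce(2 * m, dh = max(m) / 50)
      expect_true(all(e2 >= e1 - 1e-12))
    }
  })
})

test_that("TFCE with unit exponents converges to its Riemann integrals", {
  withr::with_seed(8, {
    m <- array(abs(rnorm(5^3)) + 0.5, c(5, 5, 5))
    # E = 0 removes the extent term, leaving the integral of h^H over
    # thresholds below the voxel value: H = 0 recovers the map itself,
    # H = 1 recovers value^2 / 2
    e0 <- tfce(m, E = 0, H = 0, dh = max(m) / 1000)
    expect_lt(max(abs(e0 - m) / m), 0.02)
    e1 <- tfce(m, E = 0, H = 1, dh = max(m) / 1000)
    expect_lt(max(abs(e1 - m^2 / 2) / (m^2 / 2)), 0.02)
  })
})

test_that("sign-flip inference is silent on null data and finds true effects", {
  mask <- atlas_compact()$masks$brainstem
  grid <- atlas_compact()$grid
  zero_maps <- lapply(1:6, function(i) array(0, dim = dim(mask)))
  r0 <- suppressWarnings(sign_flip_group_test(zero_maps, mask, grid,
                                              n_perm = 50, seed = 2))
  expect_true(all(r0$p_fwe >= 0.05))
  expect_length(r0$null_max, 50)

  withr::with_seed(13, {
    eff_maps <- lapply(1:12, function(i) {
      a <- array(rnorm(prod(dim(mask)), 0, 0.4), dim = dim(mask))
      a[atlas_compact()$masks$left_cuneate] <-
        a[atlas_compact()$masks$left_cuneate] + 1
      a
    })
  })
  r1 <- sign_flip_group_test(eff_maps, mask, grid, n_perm = 100, seed = 3)
  cun <- atlas_compact()$masks$left_cuneate
  recall <- sum(r1$p_fwe < 0.05 & cun) / sum(cun)
  expect_gte(recall, 0.5)
  expect_true(all(r1$p_fwe[mask] >= 1 / 100))
  # corrected p is monotone in the enhanced statistic
  v <- r1$tfce_map[mask]; p <- r1$p_fwe[mask]
  o <- order(v)
  expect_true(all(diff(p[o]) <= 1e-12))
})

test_that("familywise error of the sign-flip test is controlled", {
  mask <- array(TRUE, c(6, 6, 6))
  grid <- volume_grid(c(6, 6, 6), 1.8)
  fp <- withr::with_seed(17, {
    vapply(1:20, function(r) {
      maps <- lapply(1:10, function(i)
        array(rnorm(6^3), dim = c(6, 6, 6)))
      res <- suppressWarnings(sign_flip_group_test(maps, mask, grid,
                                                   n_perm = 60,
                                                   seed = 300 + r))
      any(res$p_fwe < 0.05)
    }, logical(1))
  })
  expect_lte(mean(fp), 0.10)
})
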