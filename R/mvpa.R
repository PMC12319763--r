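#' Assemble the decoding feature table
#'
#' Collects one feature vector per (subject, run, condition): the
#' canonical-HRF beta values at the mask voxels. All voxels inside the mask
#' are retained regardless of intensity. Labels must be balanced within every
#' subject (each condition once per retained run).
#'
#' @param cohort_glm an [analyse_cohort_glm()] result.
#' @param mask logical 3-D array selecting the feature voxels.
#' @return A `beta_sample_set`: list with `X` (n_samples x n_features),
#'   `labels` (factor), `subjects`, `runs`, `mask`, `grid`.
#' @export
assemble_beta_samples <- function(cohort_glm, mask) {
  if (!any(mask)) stop("empty feature mask")
  grid <- attr(cohort_glm, "atlas")$grid
  rows <- list(); labels <- character(); subjects <- character(); runs <- integer()
  for (subj in cohort_glm) {
    for (r in seq_along(subj$runs)) {
      betas <- subj$runs[[r]]$betas
      for (cond in names(betas)) {
        rows[[length(rows) + 1L]] <- betas[[cond]][mask]
        labels <- c(labels, cond)
        subjects <- c(subjects, subj$subject_id)
        runs <- c(runs, r)
      }
    }
  }
  X <- do.call(rbind, rows)
  tab <- table(subjects, labels)
  if (any(apply(tab, 1, function(x) length(unique(x)) != 1L)))
    stop("condition labels are not balanced within every subject")
  if (anyNA(X)) stop("missing values in feature matrix")
  structure(list(X = X, labels = factor(labels), subjects = subjects,
                 runs = runs, mask = mask, grid = grid),
            class = "beta_sample_set")
}

# Leave-one-subject-out multiclass linear SVM (C = 1); returns per-fold
# accuracies and the pooled confusion matrix
loso_engine <- function(X, labels, subjects) {
  folds <- unique(subjects)
  classes <- levels(labels)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(length(folds))
  for (i in seq_along(folds)) {
    test <- subjects == folds[i]
    ytr <- droplevels(labels[!test])
    if (nlevels(ytr) < length(classes))
      stop("a class is absent from the training data in fold ", folds[i])
    # one global scalar from the training fold keeps the features on a
    # numerically friendly scale without per-feature renormalisation
    s <- sd(X[!test, ])
    if (!is.finite(s) || s == 0) s <- 1
    fit <- e1071::svm(X[!test, , drop = FALSE] / s, ytr,
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(fit, X[test, , drop = FALSE] / s)
    yte <- labels[test]
    fold_acc[i] <- 100 * mean(as.character(pred) == as.character(yte))
    for (j in seq_along(yte))
      conf[as.character(yte[j]), as.character(pred[j])] <-
        conf[as.character(yte[j]), as.character(pred[j])] + 1L
  }
  list(fold_acc = fold_acc, confusion = conf,
       accuracy = 100 * sum(diag(conf)) / sum(conf))
}

#' Across-subject multiclass decoding with leave-one-subject-out folds
#'
#' Trains a linear multiclass support vector machine (C = 1, no feature
#' scaling, no tuning) on all subjects but one and tests on the held-out
#' subject's samples; every subject is held out once. The reported accuracy
#' is the pooled accuracy derived from the unnormalised confusion matrix
#' (equal to the mean fold accuracy when subjects contribute equally many
#' samples).
#'
#' @param samples a [assemble_beta_samples()] result (>= 2 subjects).
#' @return A `decoding_result`: list with `accuracy` (%), `fold_accuracies`,
#'   `confusion` (rows true, columns predicted), `n_folds`, `config`.
#' @export
loso_decode <- function(samples) {
  if (length(unique(samples$subjects)) < 2L)
    stop("need at least 2 subjects for leave-one-subject-out folds")
  res <- loso_engine(samples$X, samples$labels, samples$subjects)
  structure(list(accuracy = res$accuracy, fold_accuracies = res$fold_acc,
                 confusion = res$confusion,
                 n_folds = length(unique(samples$subjects)),
                 config = list(classifier = "linear SVM", cost = 1,
                               scale = FALSE)),
            class = "decoding_result")
}

# One within-subject permutation of the labels
shuffle_within_subject <- function(labels, subjects) {
  out <- labels
  for (s in unique(subjects)) {
    i <- which(subjects == s)
    out[i] <- labels[i][sample.int(length(i))]
  }
  out
}

#' Permutation null and empirical p value for decoding accuracy
#'
#' Shuffles the condition labels within each subject (preserving the
#' subject/run structure that leave-one-subject-out folds assume
#' exchangeable), refits the full LOSO decoder for each shuffle, and reports
#' the empirical p value: the proportion of null accuracies at or above the
#' observed accuracy, floored at `1/n_perm`.
#'
#' @param samples a [assemble_beta_samples()] result.
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed.
#' @param observed observed accuracy (%); computed via [loso_decode()] if
#'   `NULL`.
#' @return A `permutation_null`: list with `accuracies`, `n_perm`,
#'   `observed`, `p`, `seed`.
#' @export
permutation_pvalue <- function(samples, n_perm = 1000L, seed = 1L,
                               observed = NULL) {
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  if (is.null(observed)) observed <- loso_decode(samples)$accuracy
  acc <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      yp <- shuffle_within_subject(samples$labels, samples$subjects)
      loso_engine(samples$X, yp, samples$subjects)$accuracy
    }, numeric(1))
  })
  p <- max(mean(acc >= observed), 1 / n_perm)
  structure(list(accuracies = acc, n_perm = as.integer(n_perm),
                 observed = observed, p = p, seed = as.integer(seed)),
            class = "permutation_null")
}

#' Integer voxel offsets of a searchlight sphere
#'
#' All integer offsets `v` with `||v * voxel_size||_2 <= radius_mm`.
#'
#' @param radius_mm sphere radius (mm), >= 0.
#' @param voxel_size_mm voxel size (mm), scalar or length 3.
#' @return Integer matrix with one offset (dx, dy, dz) per row; radius 0
#'   yields only the centre.
#' @export
sphere_offsets <- function(radius_mm, voxel_size_mm) {
  if (radius_mm < 0) stop("'radius_mm' must be >= 0")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  r <- floor(radius_mm / voxel_size_mm)
  g <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3]))
  d2 <- (g[, 1] * voxel_size_mm[1])^2 + (g[, 2] * voxel_size_mm[2])^2 +
    (g[, 3] * voxel_size_mm[3])^2
  g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

# Precompute, per mask voxel, the feature-column indices inside its sphere
searchlight_neighbourhoods <- function(mask, grid, radius_mm) {
  offs <- sphere_offsets(radius_mm, grid$voxel_size_mm)
  d <- dim(mask)
  feat_id <- array(0L, dim = d)
  feat_id[mask] <- seq_len(sum(mask))
  centres <- which(mask, arr.ind = TRUE)
  lapply(seq_len(nrow(centres)), function(i) {
    nb <- sweep(offs, 2, centres[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    ids <- feat_id[nb[ok, , drop = FALSE]]
    ids[ids > 0L]
  })
}

# Decode every searchlight once per element of `label_sets` (list of factors)
searchlight_engine <- function(samples, radius_mm, label_sets) {
  hoods <- searchlight_neighbourhoods(samples$mask, samples$grid, radius_mm)
  n_centres <- length(hoods)
  acc <- matrix(NA_real_, n_centres, length(label_sets))
  skipped <- integer(0)
  for (v in seq_len(n_centres)) {
    ids <- hoods[[v]]
    if (length(ids) < 1L) { skipped <- c(skipped, v); next }
    Xv <- samples$X[, ids, drop = FALSE]
    for (j in seq_along(label_sets))
      acc[v, j] <- loso_engine(Xv, label_sets[[j]], samples$subjects)$accuracy
  }
  list(acc = acc, skipped = skipped)
}

#' Searchlight decoding accuracy map
#'
#' Slides a sphere of `radius_mm` over every mask voxel; at each centre the
#' features are the sphere-and-mask voxels and the same LOSO multiclass SVM
#' as [loso_decode()] is fit. The centre voxel stores the decoding accuracy.
#'
#' @param samples a [assemble_beta_samples()] result over the search mask.
#' @param radius_mm searchlight radius (mm).
#' @return 3-D accuracy map (percent; `NA` outside the mask), with the mask,
#'   radius, and any skipped centres as attributes.
#' @export
searchlight_map <- function(samples, radius_mm = 3) {
  res <- searchlight_engine(samples, radius_mm,
                            label_sets = list(samples$labels))
  out <- array(NA_real_, dim = dim(samples$mask))
  out[samples$mask] <- res$acc[, 1]
  attr(out, "mask") <- samples$mask
  attr(out, "radius_mm") <- radius_mm
  attr(out, "skipped") <- res$skipped
  out
}

#' Permutation searchlight maps under within-subject label shuffling
#'
#' Draws `n_perm` within-subject label shuffles; each shuffle is applied
#' identically at every searchlight centre, producing one full permutation
#' accuracy map per shuffle.
#'
#' @inheritParams searchlight_map
#' @param n_perm number of permutation maps.
#' @param seed integer seed.
#' @return List of 3-D accuracy maps.
#' @export
searchlight_null_maps <- function(samples, radius_mm = 3, n_perm = 100L,
                                  seed = 1L) {
  label_sets <- withr::with_seed(as.integer(seed), {
    replicate(n_perm,
              shuffle_within_subject(samples$labels, samples$subjects),
              simplify = FALSE)
  })
  res <- searchlight_engine(samples, radius_mm, label_sets)
  lapply(seq_len(n_perm), function(j) {
    out <- array(NA_real_, dim = dim(samples$mask))
    out[samples$mask] <- res$acc[, j]
    out
  })
}

#' Cluster-size correction of a searchlight map against permutation maps
#'
#' Pooled-null voxel thresholding followed by permutation cluster-size
#' correction: the voxelwise accuracy cutoff is the `1 - alpha_voxel`
#' quantile of all voxels' accuracies pooled across all permutation maps;
#' observed and permutation maps are thresholded at that cutoff; the
#' cluster-size cutoff is the `1 - alpha_cluster` quantile of each
#' permutation map's maximum suprathreshold cluster size; observed clusters
#' strictly larger than the cutoff survive.
#'
#' @param observed searchlight accuracy map ([searchlight_map()]).
#' @param perm_maps list of permutation maps ([searchlight_null_maps()]);
#'   fewer than 100 triggers a warning.
#' @param mask logical 3-D array (defaults to the observed map's mask).
#' @param alpha_voxel,alpha_cluster voxel- and cluster-level alpha.
#' @param connectivity cluster connectivity, 26 (default) or 6.
#' @return A `searchlight_result`: list with `accuracy_map`,
#'   `accuracy_cutoff`, `cluster_size_cutoff`, `clusters` (data frame: id,
#'   size, peak accuracy, centroid), `cluster_voxels`, `surviving_mask`,
#'   `radius_mm`.
#' @export
cluster_correct_searchlight <- function(observed, perm_maps,
                                        mask = attr(observed, "mask"),
                                        alpha_voxel = 0.05,
                                        alpha_cluster = 0.05,
                                        connectivity = 26L) {
  if (length(perm_maps) < 100L)
    warning("fewer than 100 permutation maps: cutoffs will be coarse")
  if (is.null(mask)) stop("no mask available")
  pooled <- unlist(lapply(perm_maps, function(m) m[mask]))
  cutoff <- unname(quantile(pooled, 1 - alpha_voxel, na.rm = TRUE))

  max_cluster <- vapply(perm_maps, function(m) {
    supra <- !is.na(m) & m >= cutoff & mask
    sizes <- attr(label_components(supra, connectivity), "sizes")
    if (length(sizes)) max(sizes) else 0L
  }, numeric(1))
  k_cutoff <- unname(quantile(max_cluster, 1 - alpha_cluster))

  supra <- !is.na(observed) & observed >= cutoff & mask
  lab <- label_components(supra, connectivity)
  sizes <- attr(lab, "sizes")
  keep <- which(sizes > k_cutoff)
  surviving <- array(FALSE, dim = dim(mask))
  cluster_voxels <- list()
  rows <- list()
  for (ci in seq_along(keep)) {
    vox <- which(lab == keep[ci], arr.ind = TRUE)
    lin <- which(lab == keep[ci])
    surviving[lin] <- TRUE
    cluster_voxels[[ci]] <- vox
    rows[[ci]] <- data.frame(id = ci, size = nrow(vox),
                             peak_accuracy = max(observed[lin]),
                             cx = mean(vox[, 1]), cy = mean(vox[, 2]),
                             cz = mean(vox[, 3]))
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), size = integer(0),
               peak_accuracy = numeric(0), cx = numeric(0), cy = numeric(0),
               cz = numeric(0))
  structure(list(accuracy_map = observed, accuracy_cutoff = cutoff,
                 cluster_size_cutoff = k_cutoff, clusters = clusters,
                 cluster_voxels = cluster_voxels, surviving_mask = surviving,
                 radius_mm = attr(observed, "radius_mm"),
                 n_perm = length(perm_maps)),
            class = "searchlight_result")
}
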