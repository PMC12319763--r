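.movement_conditions <- c("left_hand", "right_hand", "face")

#' Build a counterbalanced block schedule for one run
#'
#' Produces the block timing of one task run: 8 blocks of each movement
#' condition (left hand, right hand, face), each 12 s long and each followed
#' by a 6 s rest block, in a pseudo-random order with the constraints that no
#' condition occurs three or more times in a row and that every condition
#' appears at least once in each ordinal quarter of the run. Orders differ
#' between runs drawn from the same `order_seed`. A lead-in rest pads the
#' schedule so that the task structure plus lead-in fills exactly
#' `n_volumes * tr_s` seconds (15.5 s at the defaults).
#'
#' @param run_index run number (1-based); runs from one seed get distinct
#'   orders.
#' @param order_seed integer seed for the block order.
#' @param tr_s repetition time in seconds.
#' @param n_volumes volumes acquired in the run.
#' @param block_s movement block duration (s).
#' @param rest_s interleaved rest duration (s).
#' @param blocks_per_condition movement blocks per condition.
#' @return A `block_schedule`: data frame with columns `condition`, `onset_s`,
#'   `duration_s` (movement and interleaved rest rows), with attributes
#'   `tr_s`, `n_volumes`, `lead_in_rest_s`, `run_index`.
#' @export
make_block_schedule <- function(run_index = 1L, order_seed = 1L,
                                tr_s = 2.5, n_volumes = 179L,
                                block_s = 12, rest_s = 6,
                                blocks_per_condition = 8L) {
  n_blocks <- 3L * blocks_per_condition
  task_s <- n_blocks * (block_s + rest_s)
  total_s <- n_volumes * tr_s
  lead_in <- total_s - task_s
  if (lead_in < 0)
    stop("run too short: task structure (", task_s,
         " s) exceeds n_volumes * tr (", total_s, " s)")

  orders <- withr::with_seed(as.integer(order_seed), {
    out <- list()
    for (r in seq_len(run_index)) {
      repeat {
        ord <- draw_block_order(blocks_per_condition)
        if (!any(vapply(out, identical, logical(1), y = ord))) break
      }
      out[[r]] <- ord
    }
    out
  })
  ord <- orders[[run_index]]

  onsets <- lead_in + (seq_len(n_blocks) - 1L) * (block_s + rest_s)
  sched <- data.frame(
    condition = as.vector(rbind(ord, "rest")),
    onset_s = as.vector(rbind(onsets, onsets + block_s)),
    duration_s = rep(c(block_s, rest_s), n_blocks),
    stringsAsFactors = FALSE
  )
  structure(sched, tr_s = tr_s, n_volumes = as.integer(n_volumes),
            lead_in_rest_s = lead_in, run_index = as.integer(run_index),
            class = c("block_schedule", "data.frame"))
}

# Rejection-sample a condition order: no 3 consecutive repeats, and (when the
# run is long enough for the constraint to be satisfiable) every condition
# present in each ordinal quarter.
draw_block_order <- function(blocks_per_condition) {
  conds <- .movement_conditions
  n <- 3L * blocks_per_condition
  q <- split(seq_len(n), ceiling(4 * seq_len(n) / n))
  check_quarters <- blocks_per_condition >= 4L
  repeat {
    ord <- sample(rep(conds, blocks_per_condition))
    runs3 <- n >= 3L && any(ord[1:(n - 2L)] == ord[2:(n - 1L)] &
                              ord[2:(n - 1L)] == ord[3:n])
    quarters_ok <- !check_quarters ||
      all(vapply(q, function(i) all(conds %in% ord[i]), logical(1)))
    if (!runs3 && quarters_ok) return(ord)
  }
}

#' Duration of the task structure of a schedule
#'
#' Sums movement block durations together with their interleaved rest blocks,
#' excluding any lead-in rest. The default run yields 432 s (7 min 12 s).
#'
#' @param schedule a [make_block_schedule()] result.
#' @return Seconds of task structure.
#' @export
schedule_duration <- function(schedule) {
  if (nrow(schedule) == 0L) return(0)
  sum(schedule$duration_s)
}

#' Nominal per-condition volume bookkeeping
#'
#' Reproduces the acquisition bookkeeping in which every movement block
#' contributes `ceiling(block_duration / tr)` volumes and all remaining
#' volumes count as rest. Four default runs give 160 volumes per movement
#' condition and 236 rest volumes. This is a counting convention, distinct
#' from how simulated samples fall on the acquisition grid.
#'
#' @param schedules list of [make_block_schedule()] results (the runs).
#' @return Named vector of volume counts (one per movement condition, plus
#'   `rest`).
#' @export
nominal_volume_counts <- function(schedules) {
  if (inherits(schedules, "block_schedule")) schedules <- list(schedules)
  trs <- vapply(schedules, attr, numeric(1), "tr_s")
  nvols <- vapply(schedules, attr, integer(1), "n_volumes")
  if (length(unique(trs)) != 1L || length(unique(nvols)) != 1L)
    stop("all runs must share tr_s and n_volumes")
  counts <- setNames(numeric(length(.movement_conditions)), .movement_conditions)
  for (s in schedules) {
    mv <- s[s$condition != "rest", , drop = FALSE]
    for (cond in .movement_conditions) {
      counts[cond] <- counts[cond] +
        sum(ceiling(mv$duration_s[mv$condition == cond] / trs[1]))
    }
  }
  c(counts, rest = length(schedules) * nvols[1] - sum(counts))
}

#' Haemodynamic response basis: canonical double-gamma plus derivatives
#'
#' Samples three basis functions on an oversampled time grid: the canonical
#' double-gamma haemodynamic response (response gamma with shape 6, scale 1;
#' undershoot gamma with shape 16, scale 1, weighted 1/6; peak near 5 s), its
#' temporal derivative (central finite difference), and its dispersion
#' derivative (numerical derivative with respect to the response dispersion
#' parameter). Each basis function is normalised to unit peak absolute value.
#'
#' @param tr_s repetition time (s), `> 0`.
#' @param oversampling samples per TR on the fine grid.
#' @param duration_s support of the basis (s).
#' @return An `hrf_basis`: list with `time` (fine grid), `basis` (matrix,
#'   columns `canonical`, `temporal_derivative`, `dispersion_derivative`),
#'   `dt`, `tr_s`, `oversampling`.
#' @export
hrf_basis <- function(tr_s = 2.5, oversampling = 16L, duration_s = 32) {
  if (tr_s <= 0) stop("'tr_s' must be > 0")
  dt <- tr_s / oversampling
  t <- seq(0, duration_s, by = dt)
  dg <- function(t, dispersion = 1) {
    dgamma(t, shape = 6 / dispersion, scale = dispersion) -
      dgamma(t, shape = 16, rate = 1) / 6
  }
  canonical <- dg(t)
  # central difference; one-sided at the ends
  tderiv <- c(diff(canonical[1:2]) / dt,
              (canonical[-(1:2)] - canonical[seq_len(length(t) - 2L)]) / (2 * dt),
              diff(canonical[length(t) - 1:0]) / dt)
  dd <- 0.01
  dderiv <- (dg(t, 1 + dd) - canonical) / dd
  basis <- cbind(canonical = canonical / max(abs(canonical)),
                 temporal_derivative = tderiv / max(abs(tderiv)),
                 dispersion_derivative = dderiv / max(abs(dderiv)))
  structure(list(time = t, basis = basis, dt = dt, tr_s = tr_s,
                 oversampling = as.integer(oversampling)),
            class = "hrf_basis")
}

# Boxcar for one condition on the basis's fine grid, over the full run
condition_boxcar <- function(schedule, basis, condition) {
  n_fine <- attr(schedule, "n_volumes") * basis$oversampling
  t_fine <- (seq_len(n_fine) - 1L) * basis$dt
  u <- numeric(n_fine)
  rows <- schedule[schedule$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(rows)))
    u[t_fine >= rows$onset_s[i] & t_fine < rows$onset_s[i] + rows$duration_s[i]] <- 1
  u
}

# Convolve a fine-grid boxcar with one basis column and sample at volume
# onsets. `scale` divides out the plateau response of a reference block so
# that a unit regressor weight corresponds to the plateau percent signal
# change of one block.
convolve_and_sample <- function(u, h, dt, oversampling, n_volumes, scale = 1) {
  full <- convolve(u, rev(h), type = "open")[seq_along(u)] * dt
  idx <- (seq_len(n_volumes) - 1L) * oversampling + 1L
  full[idx] / scale
}

# Plateau height of the canonical response to one reference movement block
reference_block_scale <- function(schedule, basis) {
  mv <- schedule[schedule$condition != "rest", , drop = FALSE]
  block_s <- if (nrow(mv)) median(mv$duration_s) else 12
  n_fine <- ceiling((block_s + 40) / basis$dt)
  u <- as.numeric((seq_len(n_fine) - 1L) * basis$dt < block_s)
  resp <- convolve(u, rev(basis$basis[, "canonical"]), type = "open")[seq_len(n_fine)] * basis$dt
  max(resp)
}

#' Build a first-level design matrix
#'
#' Task columns are condition boxcars convolved with each basis function and
#' sampled at volume acquisition times; the canonical column of each condition
#' is scaled so a regression weight of 1 corresponds to the plateau response
#' of a single movement block (all three basis columns of a condition share
#' the scale). Drift is modelled as a discrete cosine set with periods longer
#' than `highpass_s` plus an intercept; physiological nuisance columns are
#' appended unchanged.
#'
#' @param schedule a [make_block_schedule()] result.
#' @param basis an [hrf_basis()].
#' @param nuisance optional nuisance matrix with `n_volumes` rows (e.g.
#'   [retroicor_regressors()]).
#' @param highpass_s high-pass cutoff in seconds (DCT drift regressors with
#'   longer periods are included); `NULL` or `Inf` disables drift cosines
#'   (the intercept always remains).
#' @return A `design_matrix`: numeric matrix `n_volumes x P` with column
#'   labels and attributes `tr_s`, `conditions`, `task_cols`,
#'   `canonical_cols`.
#' @export
build_design_matrix <- function(schedule, basis, nuisance = NULL,
                                highpass_s = 90) {
  n_volumes <- attr(schedule, "n_volumes")
  tr_s <- attr(schedule, "tr_s")
  if (!isTRUE(all.equal(tr_s, basis$tr_s)))
    stop("schedule and basis disagree on tr_s")
  conditions <- intersect(.movement_conditions, unique(schedule$condition))
  scale <- reference_block_scale(schedule, basis)

  task <- list()
  for (cond in conditions) {
    u <- condition_boxcar(schedule, basis, cond)
    for (b in colnames(basis$basis)) {
      task[[paste(cond, b, sep = ".")]] <- convolve_and_sample(
        u, basis$basis[, b], basis$dt, basis$oversampling, n_volumes, scale)
    }
  }
  task <- do.call(cbind, task)
  if (any(apply(abs(task), 2, max) == 0))
    stop("all-zero task column: a condition has no blocks inside the run")

  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes)
      stop(sprintf("nuisance rows (%d) do not match n_volumes (%d)",
                   nrow(nuisance), n_volumes))
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
  }

  drift <- matrix(1, n_volumes, 1, dimnames = list(NULL, "drift.intercept"))
  if (!is.null(highpass_s) && is.finite(highpass_s)) {
    total_s <- n_volumes * tr_s
    K <- floor(2 * total_s / highpass_s)
    if (K > 0) {
      i <- seq_len(n_volumes)
      dct <- vapply(seq_len(K), function(k)
        cos(pi * (i - 0.5) * k / n_volumes), numeric(n_volumes))
      colnames(dct) <- paste0("drift.cos", seq_len(K))
      drift <- cbind(drift, dct)
    }
  }

  X <- cbind(task, nuisance, drift)
  structure(X, tr_s = tr_s, conditions = conditions,
            task_cols = colnames(task),
            canonical_cols = setNames(paste0(conditions, ".canonical"), conditions),
            nuisance_cols = colnames(nuisance),
            class = c("design_matrix", class(X)))
}
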