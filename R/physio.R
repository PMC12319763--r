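#' Cardiac phase at query times
#'
#' Assigns each query time a phase in `[0, 2*pi)` that advances linearly
#' between consecutive cardiac peaks: `phi = 2*pi * (t - t_k) / (t_{k+1} -
#' t_k)` for the bracketing peaks. Times outside the recorded peak span are
#' assigned the phase of the nearest interval extended periodically and
#' flagged in the `extrapolated` attribute.
#'
#' @param peaks strictly increasing cardiac peak times (s), length >= 2.
#' @param t_query numeric vector of query times (s).
#' @return Phases in `[0, 2*pi)` with attribute `extrapolated` (logical).
#' @export
cardiac_phase <- function(peaks, t_query) {
  if (length(peaks) < 2L || any(diff(peaks) <= 0))
    stop("'peaks' must be at least 2 strictly increasing times")
  outside <- t_query < peaks[1] | t_query >= peaks[length(peaks)]
  k <- findInterval(t_query, peaks, all.inside = TRUE)
  phi <- 2 * pi * (t_query - peaks[k]) / (peaks[k + 1L] - peaks[k])
  phi <- phi %% (2 * pi)
  attr(phi, "extrapolated") <- outside
  phi
}

#' Respiratory phase at query times
#'
#' Histogram-equalised respiratory phase: with `F` the empirical cumulative
#' amplitude distribution of the waveform, inhaling samples (`db/dt > 0`) get
#' `phi = pi * F(b)` and exhaling samples get `phi = 2*pi - pi * F(b)`, so the
#' phase sweeps `0 -> pi` over an inhalation and `pi -> 2*pi` over an
#' exhalation regardless of the waveform's amplitude distribution.
#'
#' @param waveform sampled respiratory belt signal (non-constant).
#' @param sampling_rate_hz sampling rate of `waveform`, `> 0`.
#' @param t_query query times (s) relative to the first sample.
#' @return Phases in `[0, 2*pi)`.
#' @export
respiratory_phase <- function(waveform, sampling_rate_hz, t_query) {
  if (sampling_rate_hz <= 0) stop("'sampling_rate_hz' must be > 0")
  if (length(unique(waveform)) < 2L)
    stop("degenerate respiratory waveform: signal is constant")
  t_samp <- (seq_along(waveform) - 1L) / sampling_rate_hz
  b <- approx(t_samp, waveform, t_query, rule = 2)$y
  slope <- approx(t_samp[-1L] - 0.5 / sampling_rate_hz, diff(waveform),
                  t_query, rule = 2)$y
  Fb <- ecdf(waveform)(b)
  phi <- ifelse(slope >= 0, pi * Fb, 2 * pi - pi * Fb)
  phi %% (2 * pi)
}

#' Per-volume physiological phases for a run
#'
#' Evaluates cardiac and respiratory phase at each volume's mid-acquisition
#' time, `(i - 1/2) * tr`.
#'
#' @param trace a `physio_trace` (see [simulate_physio()]): list with
#'   `cardiac_peaks_s`, `resp_waveform`, `sampling_rate_hz`.
#' @param n_volumes,tr_s run geometry.
#' @return A `phase_series`: list with `cardiac` and `respiratory` phase
#'   vectors and `volume_times_s`.
#' @export
phase_series <- function(trace, n_volumes, tr_s) {
  t_vol <- (seq_len(n_volumes) - 0.5) * tr_s
  structure(list(
    cardiac = as.numeric(cardiac_phase(trace$cardiac_peaks_s, t_vol)),
    respiratory = respiratory_phase(trace$resp_waveform,
                                    trace$sampling_rate_hz, t_vol),
    volume_times_s = t_vol), class = "phase_series")
}

#' RETROICOR-style physiological nuisance regressors
#'
#' Builds the Fourier expansion of cardiac and respiratory phase:
#' `sin(k*phi_c), cos(k*phi_c)` for `k = 1..cardiac_order`, likewise for the
#' respiratory phase, plus multiplicative interaction terms `sin/cos(m*phi_c
#' +/- n*phi_r)` for every pair `m, n = 1..interaction_order` (4 columns per
#' pair), plus optional slow regressors: smoothed heart rate, respiration
#' volume per time (RVT), and heart-rate variability. Column count is
#' `2*cardiac_order + 2*resp_order + 4*interaction_order^2 + n_extras`; the
#' physiological-noise-model configuration used for denoising (orders 4/4/2
#' with heart rate and RVT) therefore yields 34 regressors.
#'
#' @param phases a [phase_series()].
#' @param cardiac_order,resp_order,interaction_order harmonic orders (>= 0).
#' @param extras character subset of `c("heart_rate", "rvt", "hrv")`; these
#'   require `trace`.
#' @param trace the `physio_trace` the phases came from (needed for extras).
#' @return A `nuisance_matrix`: numeric matrix `n_volumes x K` with labelled
#'   columns and a `config` attribute.
#' @export
retroicor_regressors <- function(phases,
                                 cardiac_order = 4L, resp_order = 4L,
                                 interaction_order = 2L,
                                 extras = c("heart_rate", "rvt"),
                                 trace = NULL) {
  if (cardiac_order < 0 || resp_order < 0 || interaction_order < 0)
    stop("harmonic orders must be >= 0")
  extras <- unique(as.character(extras))
  bad <- setdiff(extras, c("heart_rate", "rvt", "hrv"))
  if (length(bad)) stop("unknown extras: ", paste(bad, collapse = ", "))
  pc <- phases$cardiac; pr <- phases$respiratory
  n <- length(pc)
  cols <- list()
  for (k in seq_len(cardiac_order)) {
    cols[[paste0("cardiac_sin", k)]] <- sin(k * pc)
    cols[[paste0("cardiac_cos", k)]] <- cos(k * pc)
  }
  for (k in seq_len(resp_order)) {
    cols[[paste0("resp_sin", k)]] <- sin(k * pr)
    cols[[paste0("resp_cos", k)]] <- cos(k * pr)
  }
  for (m in seq_len(interaction_order)) for (k in seq_len(interaction_order)) {
    tag <- paste0(m, k)
    cols[[paste0("int_sum_sin", tag)]] <- sin(m * pc + k * pr)
    cols[[paste0("int_sum_cos", tag)]] <- cos(m * pc + k * pr)
    cols[[paste0("int_diff_sin", tag)]] <- sin(m * pc - k * pr)
    cols[[paste0("int_diff_cos", tag)]] <- cos(m * pc - k * pr)
  }
  if (length(extras)) {
    if (is.null(trace))
      stop("extras ", paste(extras, collapse = ", "),
           " require the physio trace")
    t_vol <- phases$volume_times_s
    if ("heart_rate" %in% extras)
      cols[["heart_rate"]] <- heart_rate_series(trace$cardiac_peaks_s, t_vol)
    if ("rvt" %in% extras)
      cols[["rvt"]] <- rvt_series(trace$resp_waveform, trace$sampling_rate_hz,
                                  t_vol)
    if ("hrv" %in% extras)
      cols[["hrv"]] <- hrv_series(trace$cardiac_peaks_s, t_vol)
  }
  M <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = n, ncol = 0)
  structure(M, config = list(cardiac_order = cardiac_order,
                             resp_order = resp_order,
                             interaction_order = interaction_order,
                             extras = extras),
            class = c("nuisance_matrix", class(M)))
}

running_mean <- function(x, k = 5L) {
  n <- length(x)
  half <- k %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

# Smoothed instantaneous heart rate (beats/min) interpolated to volume times
heart_rate_series <- function(peaks, t_vol) {
  ibi <- diff(peaks)
  mid <- peaks[-length(peaks)] + ibi / 2
  hr <- running_mean(60 / ibi)
  approx(mid, hr, t_vol, rule = 2)$y
}

# Moving sd of inter-beat intervals (6-beat window) at volume times
hrv_series <- function(peaks, t_vol) {
  ibi <- diff(peaks)
  mid <- peaks[-length(peaks)] + ibi / 2
  n <- length(ibi)
  v <- vapply(seq_len(n), function(i) {
    w <- ibi[max(1L, i - 3L):min(n, i + 2L)]
    if (length(w) > 1L) sd(w) else 0
  }, numeric(1))
  approx(mid, v, t_vol, rule = 2)$y
}

# Local maxima with a minimum separation, for breath segmentation
find_peaks <- function(x, min_sep = 1L) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  keep <- cand[1]
  for (p in cand[-1]) {
    if (p - keep[length(keep)] < min_sep) {
      if (x[p] > x[keep[length(keep)]]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  keep
}

# Respiration volume per time: breath amplitude / breath period, per breath,
# interpolated to volume times
rvt_series <- function(waveform, sampling_rate_hz, t_vol) {
  min_sep <- max(1L, round(sampling_rate_hz))   # breaths slower than 1 Hz
  pk <- find_peaks(waveform, min_sep)
  if (length(pk) < 2L)
    stop("could not segment breaths from the respiratory waveform")
  t_pk <- (pk - 1L) / sampling_rate_hz
  vals <- numeric(length(pk) - 1L)
  mids <- numeric(length(pk) - 1L)
  for (i in seq_len(length(pk) - 1L)) {
    seg <- waveform[pk[i]:pk[i + 1L]]
    period <- t_pk[i + 1L] - t_pk[i]
    vals[i] <- (max(seg) - min(seg)) / period
    mids[i] <- (t_pk[i] + t_pk[i + 1L]) / 2
  }
  approx(mids, vals, t_vol, rule = 2)$y
}
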