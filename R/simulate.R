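#' Simulate a physiological recording
#'
#' Generates a cardiac peak train and a respiratory belt waveform for one run.
#' Cardiac peaks are spaced at jittered multiples of the mean inter-beat
#' interval; the respiratory waveform is a frequency- and amplitude-jittered
#' sinusoid sampled at `sampling_rate_hz` (496 Hz by default, matching a
#' typical bellows recording).
#'
#' @param duration_s recording length (s), `> 0`.
#' @param cardiac_rate_hz mean heart rate (Hz), `> 0`.
#' @param resp_rate_hz mean breathing rate (Hz), `> 0`.
#' @param jitter relative sd of cycle-to-cycle variability (0 = deterministic).
#' @param seed integer seed.
#' @param sampling_rate_hz respiratory sampling rate (Hz).
#' @return A `physio_trace`: list with `cardiac_peaks_s` (strictly
#'   increasing), `resp_waveform` (length `floor(duration_s *
#'   sampling_rate_hz)`), `sampling_rate_hz`, `duration_s`.
#' @export
simulate_physio <- function(duration_s, cardiac_rate_hz = 1,
                            resp_rate_hz = 0.3, jitter = 0.05, seed = 1L,
                            sampling_rate_hz = 496) {
  if (duration_s <= 0 || cardiac_rate_hz <= 0 || resp_rate_hz <= 0)
    stop("duration and rates must be > 0")
  if (jitter < 0) stop("'jitter' must be >= 0")
  withr::with_seed(as.integer(seed), {
    n_beats <- ceiling(duration_s * cardiac_rate_hz * (1 + 5 * jitter)) + 2L
    ibi <- (1 / cardiac_rate_hz) * pmax(0.2, 1 + rnorm(n_beats, 0, jitter))
    peaks <- cumsum(c(0, ibi))
    peaks <- peaks[peaks <= duration_s]

    n_samp <- floor(duration_s * sampling_rate_hz)
    t <- (seq_len(n_samp) - 1L) / sampling_rate_hz
    if (jitter > 0) {
      knots <- seq(0, duration_s, by = 1)
      fmod <- approx(knots, rnorm(length(knots), 0, jitter), t, rule = 2)$y
      amod <- approx(knots, rnorm(length(knots), 0, jitter), t, rule = 2)$y
    } else fmod <- amod <- numeric(n_samp)
    inst_rate <- resp_rate_hz * (1 + fmod)
    phase <- 2 * pi * cumsum(inst_rate) / sampling_rate_hz
    wav <- (1 + amod) * sin(phase)
    structure(list(cardiac_peaks_s = peaks, resp_waveform = wav,
                   sampling_rate_hz = sampling_rate_hz,
                   duration_s = duration_s),
              class = "physio_trace")
  })
}

#' Noise configuration for the run simulator
#'
#' @param baseline baseline image intensity (signal amplitudes are percent of
#'   this, with baseline 100 one intensity unit = 1 percent signal change).
#' @param background_sd thermal noise sd outside the labelled regions.
#' @param cardiac_amp,resp_amp sd of the per-voxel cardiac / respiratory
#'   modulation amplitude (intensity units; 0 disables).
#' @param drift_amp sd of the per-voxel linear and slow-cosine drift
#'   coefficients (0 disables).
#' @param ar1 lag-1 autocorrelation of the thermal noise (0 = white, the
#'   default; the analysis GLM assumes white noise).
#' @param thermal_scale multiplier on the thermal noise sd everywhere (1 =
#'   the SNR-implied level; 0 disables thermal noise for noiseless
#'   round-trip checks).
#' @return A `noise_config` list.
#' @export
noise_config <- function(baseline = 100, background_sd = 1,
                         cardiac_amp = 0.5, resp_amp = 0.5,
                         drift_amp = 1, ar1 = 0, thermal_scale = 1) {
  if (background_sd < 0 || cardiac_amp < 0 || resp_amp < 0 || drift_amp < 0 ||
      thermal_scale < 0)
    stop("noise amplitudes must be >= 0")
  if (ar1 < 0 || ar1 >= 1) stop("'ar1' must be in [0, 1)")
  structure(list(baseline = baseline, background_sd = background_sd,
                 cardiac_amp = cardiac_amp, resp_amp = resp_amp,
                 drift_amp = drift_amp, ar1 = ar1,
                 thermal_scale = thermal_scale),
            class = "noise_config")
}

#' Noise configuration with every noise source disabled
#'
#' @return A [noise_config()] with zero thermal, physiological, and drift
#'   components (constant baseline plus signal only).
#' @export
noiseless_config <- function() {
  noise_config(background_sd = 0, cardiac_amp = 0, resp_amp = 0,
               drift_amp = 0, thermal_scale = 0)
}

# Per-voxel thermal noise sd: amplitude / SNR inside each region,
# background_sd elsewhere
thermal_sd_map <- function(atlas, effect, background_sd) {
  sd_map <- empty_volume(atlas$grid, background_sd)
  for (region in atlas$regions)
    sd_map[atlas$masks[[region]]] <- effect$amplitude / effect$snr[[region]]
  sd_map
}

#' Simulate one BOLD run
#'
#' The signal at each voxel is the subject's per-condition amplitude map
#' multiplied by the condition's boxcar convolved with the canonical
#' haemodynamic response (the same regressor the design module builds, so a
#' noiseless simulation is recovered exactly by the GLM). Additive components:
#' thermal Gaussian noise whose sd is `amplitude / SNR` inside each region of
#' the phantom and `background_sd` elsewhere; cardiac and respiratory
#' modulation as per-voxel random combinations of `sin`/`cos` of the
#' instantaneous physiological phase (so first-order RETROICOR harmonics span
#' them exactly); and per-voxel linear plus slow-cosine drift.
#'
#' @param patterns named list of per-condition 3-D amplitude maps (one
#'   subject's ground truth, e.g. `make_condition_patterns()$subjects[[s]]`).
#' @param schedule a [make_block_schedule()] result.
#' @param trace a [simulate_physio()] result covering the run.
#' @param atlas the [build_phantom_atlas()] the patterns live on.
#' @param effect the [effect_spec()] (supplies per-region SNR and amplitude).
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @param basis an [hrf_basis()]; defaults to the schedule's TR.
#' @return 4-D array `(x, y, z, time)` with attributes `grid` and
#'   `task_regressors` (the sampled canonical regressors used).
#' @export
simulate_run <- function(patterns, schedule, trace, atlas, effect,
                         noise = noise_config(), seed = 1L,
                         basis = hrf_basis(attr(schedule, "tr_s"))) {
  grid <- atlas$grid
  for (nm in names(patterns))
    if (!identical(dim(patterns[[nm]]), as.integer(grid$shape)))
      stop(sprintf("pattern '%s' dimensions do not match the atlas grid", nm))
  n_vol <- attr(schedule, "n_volumes")
  tr <- attr(schedule, "tr_s")
  V <- prod(grid$shape)

  conds <- intersect(.movement_conditions, names(patterns))
  scale <- reference_block_scale(schedule, basis)
  xreg <- vapply(conds, function(cond)
    convolve_and_sample(condition_boxcar(schedule, basis, cond),
                        basis$basis[, "canonical"], basis$dt,
                        basis$oversampling, n_vol, scale), numeric(n_vol))

  Y <- matrix(noise$baseline, V, n_vol)
  for (j in seq_along(conds))
    Y <- Y + tcrossprod(as.vector(patterns[[conds[j]]]), xreg[, j])

  withr::with_seed(as.integer(seed), {
    in_brain <- as.vector(atlas$masks$brainstem | atlas$masks$thalamus |
                            atlas$masks$s1)
    nb <- sum(in_brain)
    t_vol <- (seq_len(n_vol) - 0.5) * tr

    if (noise$drift_amp > 0) {
      lin <- seq(-1, 1, length.out = n_vol)
      slow <- cos(2 * pi * t_vol / (n_vol * tr))
      Y <- Y + tcrossprod(rnorm(V, 0, noise$drift_amp), lin) +
        tcrossprod(rnorm(V, 0, noise$drift_amp), slow)
    }
    if (noise$cardiac_amp > 0 || noise$resp_amp > 0) {
      ph <- phase_series(trace, n_vol, tr)
      if (noise$cardiac_amp > 0)
        Y[in_brain, ] <- Y[in_brain, ] +
          tcrossprod(rnorm(nb, 0, noise$cardiac_amp), sin(ph$cardiac)) +
          tcrossprod(rnorm(nb, 0, noise$cardiac_amp), cos(ph$cardiac))
      if (noise$resp_amp > 0)
        Y[in_brain, ] <- Y[in_brain, ] +
          tcrossprod(rnorm(nb, 0, noise$resp_amp), sin(ph$respiratory)) +
          tcrossprod(rnorm(nb, 0, noise$resp_amp), cos(ph$respiratory))
    }
    sd_map <- noise$thermal_scale *
      thermal_sd_map(atlas, effect, noise$background_sd)
    if (any(sd_map > 0)) {
      eps <- matrix(rnorm(V * n_vol), V, n_vol)
      if (noise$ar1 > 0) {
        for (tt in 2:n_vol)
          eps[, tt] <- noise$ar1 * eps[, tt - 1L] +
            sqrt(1 - noise$ar1^2) * eps[, tt]
      }
      Y <- Y + as.vector(sd_map) * eps
    }
  })

  img <- array(Y, dim = c(grid$shape, n_vol))
  attr(img, "grid") <- grid
  attr(img, "task_regressors") <- xreg
  img
}

#' Simulate a multi-subject cohort
#'
#' Draws per-subject condition patterns (shared template, subject
#' perturbations), then simulates each subject's runs with independent block
#' orders, physiological traces (heart and breathing rates vary across
#' subjects), and noise. Each run carries a scalar head-motion summary
#' (`mean_abs_displacement_mm`) drawn from a log-normal distribution so that
#' the >1 mm run-exclusion rule is occasionally triggered.
#'
#' @param n_subjects number of subjects, `>= 2`.
#' @param atlas a [build_phantom_atlas()] result.
#' @param effect an [effect_spec()].
#' @param seed integer seed; the cohort is a pure function of its arguments.
#' @param runs_per_subject runs per subject.
#' @param tr_s,n_volumes run geometry.
#' @param blocks_per_condition movement blocks per condition per run (8 at
#'   full scale; smaller values shorten desk-scale runs).
#' @param noise a [noise_config()].
#' @param displacement list with `meanlog`, `sdlog` of the per-run
#'   displacement distribution (mm).
#' @param jitter physiological cycle jitter passed to [simulate_physio()].
#' @return A `somato_cohort`: list of `subject_dataset`s, each with
#'   `subject_id`, `runs` (each run: `image`, `schedule`, `trace`,
#'   `mean_abs_displacement_mm`), and `ground_truth` (per-condition maps);
#'   the atlas and effect spec are attached as attributes.
#' @export
generate_cohort <- function(n_subjects = 20L, atlas = NULL,
                            effect = effect_spec(), seed = 1L,
                            runs_per_subject = 4L,
                            tr_s = 2.5, n_volumes = 179L,
                            blocks_per_condition = 8L,
                            noise = noise_config(),
                            displacement = list(meanlog = log(0.3), sdlog = 0.6),
                            jitter = 0.05) {
  if (n_subjects < 2L) stop("'n_subjects' must be >= 2")
  if (is.null(atlas))
    atlas <- build_phantom_atlas(volume_grid(c(20L, 20L, 18L)))
  basis <- hrf_basis(tr_s)
  duration_s <- n_volumes * tr_s

  seeds <- withr::with_seed(as.integer(seed), {
    list(patterns = sample.int(2^31 - 2, 1),
         subject = matrix(sample.int(2^31 - 2, n_subjects * (2L + 3L * runs_per_subject)),
                          nrow = n_subjects))
  })
  patterns <- make_condition_patterns(atlas, effect, n_subjects,
                                      seed = seeds$patterns)

  cohort <- lapply(seq_len(n_subjects), function(s) {
    srow <- seeds$subject[s, ]
    rates <- withr::with_seed(srow[1], {
      c(cardiac = max(0.7, rnorm(1, 1.0, 0.1)),
        resp = max(0.15, rnorm(1, 0.3, 0.03)))
    })
    disps <- withr::with_seed(srow[2], {
      rlnorm(runs_per_subject, displacement$meanlog, displacement$sdlog)
    })
    runs <- lapply(seq_len(runs_per_subject), function(r) {
      rs <- srow[2L + (r - 1L) * 3L + 1:3]
      schedule <- make_block_schedule(run_index = r, order_seed = rs[1],
                                      tr_s = tr_s, n_volumes = n_volumes,
                                      blocks_per_condition = blocks_per_condition)
      trace <- simulate_physio(duration_s, rates["cardiac"], rates["resp"],
                               jitter = jitter, seed = rs[2])
      img <- simulate_run(patterns$subjects[[s]], schedule, trace, atlas,
                          effect, noise = noise, seed = rs[3], basis = basis)
      list(image = img, schedule = schedule, trace = trace,
           mean_abs_displacement_mm = disps[r])
    })
    structure(list(subject_id = sprintf("sub-%02d", s), runs = runs,
                   ground_truth = patterns$subjects[[s]]),
              class = "subject_dataset")
  })
  structure(cohort, atlas = atlas, effect = effect, patterns = patterns,
            seed = as.integer(seed), class = "somato_cohort")
}
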