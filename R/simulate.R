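# Physics-based synthetic data generator: beat skeleton, chest displacement,
# quadrature Doppler demodulation, template ECG, and per-segment blood
# pressure coupled to cardiac durations.

#' Synthesize a beat-time skeleton
#'
#' Draws interbeat intervals around `60 / heart_rate_bpm` with multiplicative
#' Gaussian jitter of scale `hr_variability_frac` (truncated at 3 sigma so
#' intervals stay positive), places R peaks cumulatively from time 0, and sets
#' each T-wave end at `r_peak + systolic_fraction * ibi`, optionally with a
#' slow sinusoidal modulation of the systolic fraction.
#'
#' @param physiology a [physiology_params()] object.
#' @param duration_s recording duration in seconds; must exceed two mean IBIs.
#' @return an object of class `ground_truth`: R-peak times, T-end times, and a
#'   per-beat table of `(r_peak_s, t_end_s, ibi_s, systolic_s, diastolic_s)`.
#' @export
synth_beat_times <- function(physiology, duration_s) {
  stopifnot_scalar(duration_s, "duration_s")
  mean_ibi <- 60 / physiology$heart_rate_bpm
  if (duration_s <= 2 * mean_ibi)
    stop("'duration_s' must exceed two mean interbeat intervals", call. = FALSE)

  with_seed(physiology$seed, {
    n_max <- ceiling(duration_s / mean_ibi * 1.5) + 4L
    z <- pmin(3, pmax(-3, stats::rnorm(n_max)))
    ibis <- mean_ibi * (1 + physiology$hr_variability_frac * z)
    r <- c(0, cumsum(ibis))
    r <- r[r < duration_s]
    mod_phase <- stats::runif(1, 0, 2 * pi)

    nb <- length(r) - 1L                       # complete beats
    if (nb < 1L) stop("duration too short for a single beat", call. = FALSE)
    ibi <- diff(r)
    frac <- physiology$systolic_fraction +
      physiology$sys_frac_mod_amp *
      sin(2 * pi * r[seq_len(nb)] / physiology$sys_frac_mod_period_s + mod_phase)
    frac <- pmin(0.9, pmax(0.1, frac))
    t_end <- r[seq_len(nb)] + frac * ibi

    per_beat <- data.frame(
      beat = seq_len(nb),
      r_peak_s = r[seq_len(nb)],
      t_end_s = t_end,
      ibi_s = ibi,
      systolic_s = t_end - r[seq_len(nb)],
      diastolic_s = r[seq_len(nb) + 1L] - t_end
    )
    structure(list(
      r_peak_times_s = r,
      t_end_times_s = t_end,
      per_beat = per_beat,
      duration_s = duration_s,
      physiology = physiology
    ), class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d R peaks, %d complete beats over %.1f s\n",
              length(x$r_peak_times_s), nrow(x$per_beat), x$duration_s))
  cat(sprintf("  mean IBI %.3f s, mean systolic %.3f s, mean diastolic %.3f s\n",
              mean(x$per_beat$ibi_s), mean(x$per_beat$systolic_s),
              mean(x$per_beat$diastolic_s)))
  invisible(x)
}

# Hann-enveloped sinusoidal burst sampled on grid t (seconds), support
# [t0, t0 + dur]. Returns displacement contribution in metres.
.burst_wave <- function(t, t0, dur, freq, amp) {
  u <- (t - t0) / dur
  inside <- u >= 0 & u <= 1
  w <- numeric(length(t))
  w[inside] <- amp * sin(pi * u[inside])^2 * sin(2 * pi * freq * (t[inside] - t0))
  w
}

#' Chest displacement trace
#'
#' Sum of a respiration sinusoid, a raised-cosine low-frequency cardiac pulse
#' per beat, and one Hann-enveloped high-frequency vibration burst starting at
#' each R peak and each T-wave end (the mechanical signatures of ventricular
#' contraction and valve closure).
#'
#' @param truth a `ground_truth` object from [synth_beat_times()].
#' @param physiology a [physiology_params()] object.
#' @param fs sampling rate in Hz; must be at least 4x the burst frequency.
#' @param duration_s trace duration in seconds.
#' @return numeric vector of displacement in metres, length `round(fs * duration_s)`.
#' @export
chest_displacement <- function(truth, physiology, fs, duration_s) {
  if (fs < 4 * physiology$burst_center_freq_hz)
    stop("sampling rate too low for the burst centre frequency (aliasing)",
         call. = FALSE)
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1L) / fs
  x <- physiology$respiration_amplitude_m *
    sin(2 * pi * physiology$respiration_rate_hz * t)

  # low-frequency cardiac pulse: raised-cosine bump spanning each beat
  pb <- truth$per_beat
  if (physiology$cardiac_pulse_amplitude_m > 0 && nrow(pb) > 0) {
    for (i in seq_len(nrow(pb))) {
      i0 <- max(1L, floor(pb$r_peak_s[i] * fs) + 1L)
      i1 <- min(n, ceiling((pb$r_peak_s[i] + pb$ibi_s[i]) * fs) + 1L)
      if (i1 < i0) next
      u <- (t[i0:i1] - pb$r_peak_s[i]) / pb$ibi_s[i]
      u <- pmin(1, pmax(0, u))
      x[i0:i1] <- x[i0:i1] +
        physiology$cardiac_pulse_amplitude_m * 0.5 * (1 - cos(2 * pi * u))
    }
  }

  # vibration bursts: S1-like at systole onsets, S2-like at diastole onsets
  if (physiology$burst_amplitude_m > 0) {
    add_bursts <- function(x, onsets, dur, freq, amp) {
      for (t0 in onsets) {
        i0 <- max(1L, floor(t0 * fs) + 1L)
        i1 <- min(n, ceiling((t0 + dur) * fs) + 1L)
        if (i1 < i0) next
        x[i0:i1] <- x[i0:i1] + .burst_wave(t[i0:i1], t0, dur, freq, amp)
      }
      x
    }
    x <- add_bursts(x, truth$r_peak_times_s, physiology$burst_duration_s,
                    physiology$burst_center_freq_hz,
                    physiology$burst_amplitude_m)
    x <- add_bursts(x, truth$t_end_times_s,
                    physiology$burst_duration_s * physiology$t_burst_duration_scale,
                    min(30, physiology$burst_center_freq_hz *
                          physiology$t_burst_freq_scale),
                    physiology$burst_amplitude_m * physiology$t_burst_amplitude_scale)
  }
  x
}

#' Quadrature Doppler demodulation of a displacement trace
#'
#' Maps chest displacement to baseband I/Q:
#' `I = cos(theta + 4*pi*x/lambda + dphi)`, `Q = sin(theta + 4*pi*x/lambda + dphi)`,
#' with `dphi` white Gaussian phase noise, plus optional additive amplitude
#' noise on each channel.
#'
#' @param x displacement trace in metres.
#' @param radar a [radar_config()] object.
#' @param noise_phase_std_rad phase-noise standard deviation (radians).
#' @param amp_noise_std additive amplitude-noise standard deviation.
#' @param noise_seed integer seed for the noise realisation.
#' @return list with numeric elements `i` and `q`, both in `[-1-eps, 1+eps]`.
#' @export
doppler_iq <- function(x, radar, noise_phase_std_rad = 0, amp_noise_std = 0,
                       noise_seed = 1L) {
  if (any(!is.finite(x))) stop("displacement trace must be finite", call. = FALSE)
  phase <- radar$default_phase_rad + 4 * pi * x / radar$wavelength_m
  with_seed(noise_seed, {
    if (noise_phase_std_rad > 0)
      phase <- phase + stats::rnorm(length(x), sd = noise_phase_std_rad)
    i <- cos(phase)
    q <- sin(phase)
    if (amp_noise_std > 0) {
      i <- i + stats::rnorm(length(x), sd = amp_noise_std)
      q <- q + stats::rnorm(length(x), sd = amp_noise_std)
    }
    list(i = i, q = q)
  })
}

# One compact-support raised-cosine wave component added in place.
.add_wave <- function(ecg, t, center, width, amp, fs) {
  n <- length(ecg)
  i0 <- max(1L, floor((center - width / 2) * fs) + 1L)
  i1 <- min(n, ceiling((center + width / 2) * fs) + 1L)
  if (i1 < i0) return(ecg)
  u <- (t[i0:i1] - center) / width
  inside <- abs(u) <= 0.5
  ecg[i0:i1][inside] <- ecg[i0:i1][inside] +
    amp * 0.5 * (1 + cos(2 * pi * u[inside]))
  ecg
}

#' Template ECG synthesis
#'
#' Places an analytic P-QRS-T template at each beat so that the R-peak sample
#' is the local argmax and the T wave returns to baseline exactly at the
#' T-wave end (all waves are compact-support raised cosines).
#'
#' @param truth a `ground_truth` object.
#' @param fs sampling rate in Hz.
#' @param duration_s trace duration (defaults to the truth's duration).
#' @return numeric ECG trace of length `round(fs * duration_s)`.
#' @export
synth_ecg <- function(truth, fs, duration_s = truth$duration_s) {
  pb <- truth$per_beat
  if (nrow(pb) > 0 && min(pb$ibi_s) < 0.3)
    stop("interbeat interval shorter than the ECG template", call. = FALSE)
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1L) / fs
  ecg <- numeric(n)
  for (r in truth$r_peak_times_s) {
    ecg <- .add_wave(ecg, t, r - 0.16, 0.09, 0.12, fs)   # P
    ecg <- .add_wave(ecg, t, r - 0.03, 0.03, -0.10, fs)  # Q
    ecg <- .add_wave(ecg, t, r, 0.06, 1.00, fs)          # R
    ecg <- .add_wave(ecg, t, r + 0.03, 0.03, -0.12, fs)  # S
  }
  for (i in seq_len(nrow(pb))) {
    d_t <- min(0.24, max(0.08, pb$systolic_s[i] - 0.08))
    ecg <- .add_wave(ecg, t, pb$t_end_s[i] - d_t / 2, d_t, 0.30, fs)  # T
  }
  ecg
}

#' Per-segment blood pressure from cardiac durations
#'
#' Applies the linear duration-to-BP coupling to each segment's mean beat
#' durations and adds one Gaussian noise deviate per segment.
#'
#' @param truth a `ground_truth` object.
#' @param coupling a [bp_coupling()] object.
#' @param segment_boundaries data.frame with columns `start_s`, `end_s`.
#' @param seed integer seed for the noise.
#' @return data.frame with `segment_index`, `start_s`, `end_s`, `n_beats`,
#'   `mean_ibi_s`, `mean_systolic_s`, `mean_diastolic_s`, `sbp_mmHg`, `dbp_mmHg`.
#' @export
synth_bp <- function(truth, coupling, segment_boundaries, seed = 1L) {
  sb <- as.data.frame(segment_boundaries)
  pb <- truth$per_beat
  ns <- nrow(sb)
  out <- data.frame(segment_index = seq_len(ns), start_s = sb$start_s,
                    end_s = sb$end_s, n_beats = NA_integer_,
                    mean_ibi_s = NA_real_, mean_systolic_s = NA_real_,
                    mean_diastolic_s = NA_real_)
  for (k in seq_len(ns)) {
    inside <- pb$r_peak_s >= sb$start_s[k] &
      (pb$r_peak_s + pb$ibi_s) <= sb$end_s[k]
    if (!any(inside))
      stop(sprintf("segment %d contains no complete beat", k), call. = FALSE)
    out$n_beats[k] <- sum(inside)
    out$mean_ibi_s[k] <- mean(pb$ibi_s[inside])
    out$mean_systolic_s[k] <- mean(pb$systolic_s[inside])
    out$mean_diastolic_s[k] <- mean(pb$diastolic_s[inside])
  }
  with_seed(seed, {
    noise_s <- stats::rnorm(ns, sd = coupling$bp_noise_std_mmHg)
    noise_d <- stats::rnorm(ns, sd = coupling$bp_noise_std_mmHg)
    out$sbp_mmHg <- coupling$sbp_intercept +
      coupling$sbp_coeff_sys * out$mean_systolic_s +
      coupling$sbp_coeff_dia * out$mean_diastolic_s +
      coupling$sbp_coeff_ibi * out$mean_ibi_s + noise_s
    out$dbp_mmHg <- coupling$dbp_intercept +
      coupling$dbp_coeff_sys * out$mean_systolic_s +
      coupling$dbp_coeff_dia * out$mean_diastolic_s +
      coupling$dbp_coeff_ibi * out$mean_ibi_s + noise_d
  })
  out
}

#' Simulate one subject's recording
#'
#' Runs the full generator for one subject: beat skeleton, chest displacement,
#' quadrature demodulation with noise, template ECG, and per-segment BP on the
#' canonical analysis grid. The recording's `sbp`/`dbp` channels are a
#' step-function rendering of the per-segment values (held over each stride
#' block); the authoritative targets live in `truth$per_segment_bp`.
#'
#' @param subject_id subject identifier string.
#' @param physiology a [physiology_params()] object.
#' @param radar a [radar_config()] object.
#' @param coupling a [bp_coupling()] object.
#' @param duration_s recording length in seconds.
#' @param window_s,overlap_s segmentation grid used for the BP ground truth.
#' @return list with elements `recording` (see [recording()]) and `truth`.
#' @export
simulate_recording <- function(subject_id, physiology,
                               radar = radar_config(),
                               coupling = bp_coupling(),
                               duration_s = 600, window_s = 10, overlap_s = 5) {
  fs <- radar$sampling_rate_hz
  truth <- synth_beat_times(physiology, duration_s)
  x <- chest_displacement(truth, physiology, fs, duration_s)
  iq <- doppler_iq(x, radar, physiology$noise_phase_std_rad,
                   physiology$amp_noise_std,
                   noise_seed = child_seed(physiology$seed, 7L))
  ecg <- synth_ecg(truth, fs, duration_s)

  stride <- window_s - overlap_s
  starts <- seq(0, duration_s - window_s, by = stride)
  bounds <- data.frame(start_s = starts, end_s = starts + window_s)
  bp <- synth_bp(truth, coupling, bounds, seed = child_seed(physiology$seed, 11L))
  truth$per_segment_bp <- bp

  # step rendering of the per-segment BP over stride blocks
  t <- (seq_along(x) - 1L) / fs
  idx <- pmin(nrow(bp), pmax(1L, floor(t / stride) + 1L))
  rec <- recording(subject_id, fs,
                   channels = list(i = iq$i, q = iq$q, ecg = ecg,
                                   sbp = bp$sbp_mmHg[idx], dbp = bp$dbp_mmHg[idx]))
  list(recording = rec, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject physiology from resting-adult ranges (heart rate 55-85
#' bpm, beat-to-beat CV 2-8%, systolic fraction 0.30-0.40, respiration
#' 0.2-0.3 Hz at 1-3 mm, burst frequency 12-24 Hz) and simulates one
#' recording per subject. Fully reproducible from `seed`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param duration_s per-subject recording length in seconds.
#' @param seed integer master seed.
#' @param radar a [radar_config()] object shared by all subjects.
#' @param coupling a [bp_coupling()] object shared by all subjects.
#' @param window_s,overlap_s BP segmentation grid.
#' @return an object of class `radar_cohort`: a list of
#'   `list(recording, truth)` entries, one per subject.
#' @export
generate_cohort <- function(n_subjects, duration_s = 600, seed = 1L,
                            radar = radar_config(), coupling = bp_coupling(),
                            window_s = 10, overlap_s = 5) {
  if (n_subjects < 1) stop("'n_subjects' must be >= 1", call. = FALSE)
  draws <- with_seed(child_seed(seed, 1L), {
    data.frame(
      hr = stats::runif(n_subjects, 55, 85),
      hrv = stats::runif(n_subjects, 0.02, 0.08),
      frac = stats::runif(n_subjects, 0.30, 0.40),
      resp_rate = stats::runif(n_subjects, 0.2, 0.3),
      resp_amp = stats::runif(n_subjects, 1e-3, 3e-3),
      burst_freq = stats::runif(n_subjects, 12, 24),
      burst_dur = stats::runif(n_subjects, 0.06, 0.09),
      burst_amp = stats::runif(n_subjects, 7e-5, 1.2e-4)
    )
  })
  cohort <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    phys <- physiology_params(
      heart_rate_bpm = draws$hr[s], hr_variability_frac = draws$hrv[s],
      systolic_fraction = draws$frac[s],
      respiration_rate_hz = draws$resp_rate[s],
      respiration_amplitude_m = draws$resp_amp[s],
      burst_center_freq_hz = draws$burst_freq[s],
      burst_duration_s = draws$burst_dur[s],
      burst_amplitude_m = draws$burst_amp[s],
      seed = child_seed(seed, 100L + s)
    )
    cohort[[s]] <- simulate_recording(sprintf("S%02d", s), phys, radar,
                                      coupling, duration_s, window_s, overlap_s)
  }
  structure(cohort, class = "radar_cohort")
}

#' @export
print.radar_cohort <- function(x, ...) {
  cat(sprintf("<radar_cohort> %d subjects\n", length(x)))
  for (e in x)
    cat(sprintf("  %s: %.0f s @ %g Hz, %d beats\n", e$recording$subject_id,
                e$truth$duration_s, e$recording$sampling_rate_hz,
                nrow(e$truth$per_beat)))
  invisible(x)
}
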