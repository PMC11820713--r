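# Shared fixtures, built in code.

# Deterministic physiology with no noise and no slow modulation: analytic
# checks stay exact.
clean_physiology <- function(...) {
  physiology_params(sys_frac_mod_amp = 0, noise_phase_std_rad = 0,
                    amp_noise_std = 0, ...)
}

# A hand-built ground truth (no RNG) for label/beat arithmetic.
manual_truth <- function(r_peaks, frac = 0.35,
                         physiology = clean_physiology()) {
  nb <- length(r_peaks) - 1L
  ibi <- diff(r_peaks)
  t_end <- r_peaks[seq_len(nb)] + frac * ibi
  structure(list(
    r_peak_times_s = r_peaks,
    t_end_times_s = t_end,
    per_beat = data.frame(beat = seq_len(nb), r_peak_s = r_peaks[seq_len(nb)],
                          t_end_s = t_end, ibi_s = ibi,
                          systolic_s = t_end - r_peaks[seq_len(nb)],
                          diastolic_s = r_peaks[-1L] - t_end),
    duration_s = max(r_peaks),
    physiology = physiology
  ), class = "ground_truth")
}

# Random four-state cyclic model with enumerable dwell bounds (d_min >= 3
# keeps the exhaustive reference decoder tractable).
random_small_hsmm <- function(seed) {
  set.seed(seed)
  dmin <- sample(3:4, 4, replace = TRUE)
  dmax <- pmin(dmin + sample(1:4, 4, replace = TRUE), 8L)
  p <- runif(4)
  structure(list(
    n_states = 4L, pi = p / sum(p), successor = c(2L, 3L, 4L, 1L),
    durations = data.frame(state = 1:4, mean_frames = runif(4, 2, 8),
                           sd_frames = runif(4, 0.5, 3),
                           d_min = dmin, d_max = dmax),
    emissions = NULL, frame_rate_hz = 125
  ), class = "radar_hsmm")
}
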