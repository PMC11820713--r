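# Parameter containers for the radar front end, the simulated physiology and
# the duration -> blood-pressure coupling.

SPEED_OF_LIGHT <- 2.998e8  # m/s

#' Radar front-end configuration
#'
#' Describes a continuous-wave quadrature Doppler radar: carrier frequency,
#' derived wavelength, nominal target distance, demodulation phase offset and
#' sampling rate. The default 24.25 GHz carrier matches a K-band vital-sign
#' sensor observing the chest at sub-metre range.
#'
#' @param carrier_frequency_hz carrier frequency f in Hz.
#' @param nominal_distance_m nominal sensor-to-chest distance d0 in metres.
#' @param default_phase_rad demodulation phase offset theta in radians.
#' @param sampling_rate_hz baseband sampling rate in Hz.
#' @return an object of class `radar_config`.
#' @examples
#' rc <- radar_config()
#' rc$wavelength_m  # c / f, about 12.4 mm
#' @export
radar_config <- function(carrier_frequency_hz = 24.25e9,
                         nominal_distance_m = 0.5,
                         default_phase_rad = 0,
                         sampling_rate_hz = 1000) {
  stopifnot_scalar(carrier_frequency_hz, "carrier_frequency_hz")
  stopifnot_scalar(nominal_distance_m, "nominal_distance_m")
  stopifnot_scalar(sampling_rate_hz, "sampling_rate_hz")
  stopifnot_scalar(default_phase_rad, "default_phase_rad", positive = FALSE)
  structure(list(
    carrier_frequency_hz = carrier_frequency_hz,
    wavelength_m = SPEED_OF_LIGHT / carrier_frequency_hz,
    nominal_distance_m = nominal_distance_m,
    default_phase_rad = default_phase_rad,
    sampling_rate_hz = sampling_rate_hz
  ), class = "radar_config")
}

#' Simulated chest physiology parameters
#'
#' Parameters of the synthetic chest-displacement model: a respiration
#' sinusoid, a low-frequency per-beat cardiac pulse, and a brief
#' Hann-enveloped high-frequency vibration burst at each systole onset
#' (R peak) and each diastole onset (T-wave end). Displacement amplitudes are
#' literature-typical for supine resting adults (respiration a few millimetres,
#' cardiac pulse ~0.1 mm, valve-related vibrations tens of micrometres).
#'
#' @param heart_rate_bpm mean heart rate, beats per minute.
#' @param hr_variability_frac multiplicative beat-to-beat IBI jitter scale
#'   (coefficient of variation), in `[0, 0.2]`.
#' @param systolic_fraction fraction of each IBI from R peak to T-wave end.
#' @param sys_frac_mod_amp amplitude of a slow sinusoidal modulation of the
#'   systolic fraction (emulates autonomic drift; period `sys_frac_mod_period_s`).
#' @param sys_frac_mod_period_s period of that modulation in seconds.
#' @param respiration_rate_hz respiration rate in Hz (~0.2-0.3).
#' @param respiration_amplitude_m respiration displacement amplitude in metres.
#' @param cardiac_pulse_amplitude_m low-frequency cardiac pulse amplitude (m).
#' @param burst_center_freq_hz centre frequency of the systole-onset (S1-like)
#'   vibration burst, must lie inside `[8, 30]` Hz so the bursts survive the
#'   analysis band-pass.
#' @param burst_duration_s duration of the systole-onset burst in seconds.
#' @param burst_amplitude_m systole-onset burst displacement amplitude (m).
#' @param t_burst_amplitude_scale,t_burst_freq_scale,t_burst_duration_scale
#'   the diastole-onset (S2-like) burst relative to the systole-onset one:
#'   weaker, higher-pitched and shorter, as valve-closure vibrations are
#'   relative to the ventricular-contraction complex. The scaled frequency is
#'   capped at 30 Hz to stay inside the analysis band.
#' @param noise_phase_std_rad standard deviation of the white Gaussian phase
#'   noise added inside the demodulated phase.
#' @param amp_noise_std additive amplitude noise on I and Q (unitless).
#' @param seed integer seed controlling beat-time and noise realisations.
#' @return an object of class `physiology_params`.
#' @export
physiology_params <- function(heart_rate_bpm = 65,
                              hr_variability_frac = 0.05,
                              systolic_fraction = 0.35,
                              sys_frac_mod_amp = 0.02,
                              sys_frac_mod_period_s = 60,
                              respiration_rate_hz = 0.25,
                              respiration_amplitude_m = 2e-3,
                              cardiac_pulse_amplitude_m = 1e-4,
                              burst_center_freq_hz = 18,
                              burst_duration_s = 0.08,
                              burst_amplitude_m = 8e-5,
                              t_burst_amplitude_scale = 0.75,
                              t_burst_freq_scale = 1.2,
                              t_burst_duration_scale = 0.75,
                              noise_phase_std_rad = 0.03,
                              amp_noise_std = 0.005,
                              seed = 1L) {
  stopifnot_scalar(heart_rate_bpm, "heart_rate_bpm")
  if (hr_variability_frac < 0 || hr_variability_frac > 0.2)
    stop("'hr_variability_frac' must lie in [0, 0.2]", call. = FALSE)
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("'systolic_fraction' must lie in (0, 1)", call. = FALSE)
  if (burst_center_freq_hz < 8 || burst_center_freq_hz > 30)
    stop("'burst_center_freq_hz' must lie in [8, 30] Hz", call. = FALSE)
  structure(list(
    heart_rate_bpm = heart_rate_bpm,
    hr_variability_frac = hr_variability_frac,
    systolic_fraction = systolic_fraction,
    sys_frac_mod_amp = sys_frac_mod_amp,
    sys_frac_mod_period_s = sys_frac_mod_period_s,
    respiration_rate_hz = respiration_rate_hz,
    respiration_amplitude_m = respiration_amplitude_m,
    cardiac_pulse_amplitude_m = cardiac_pulse_amplitude_m,
    burst_center_freq_hz = burst_center_freq_hz,
    burst_duration_s = burst_duration_s,
    burst_amplitude_m = burst_amplitude_m,
    t_burst_amplitude_scale = t_burst_amplitude_scale,
    t_burst_freq_scale = t_burst_freq_scale,
    t_burst_duration_scale = t_burst_duration_scale,
    noise_phase_std_rad = noise_phase_std_rad,
    amp_noise_std = amp_noise_std,
    seed = as.integer(seed)
  ), class = "physiology_params")
}

#' Linear duration-to-blood-pressure coupling
#'
#' Synthetic ground-truth coupling between per-segment mean cardiac durations
#' and blood pressure:
#' `SBP = intercept + c_sys * mean_systolic + c_dia * mean_diastolic +
#'  c_ibi * mean_ibi + N(0, noise^2)` (and analogously for DBP). The default
#' negative duration coefficients encode the empirical pattern that shorter
#' systolic/diastolic durations (faster, harder-driven heart) accompany higher
#' pressure.
#'
#' @param sbp_intercept,sbp_coeff_sys,sbp_coeff_dia,sbp_coeff_ibi SBP linear
#'   terms (mmHg and mmHg/s).
#' @param dbp_intercept,dbp_coeff_sys,dbp_coeff_dia,dbp_coeff_ibi DBP analogues.
#' @param bp_noise_std_mmHg per-segment Gaussian noise standard deviation.
#' @return an object of class `bp_coupling`.
#' @export
bp_coupling <- function(sbp_intercept = 150, sbp_coeff_sys = -60,
                        sbp_coeff_dia = -20, sbp_coeff_ibi = 0,
                        dbp_intercept = 110, dbp_coeff_sys = -40,
                        dbp_coeff_dia = -25, dbp_coeff_ibi = 0,
                        bp_noise_std_mmHg = 2) {
  if (bp_noise_std_mmHg < 0)
    stop("'bp_noise_std_mmHg' must be >= 0", call. = FALSE)
  structure(list(
    sbp_intercept = sbp_intercept, sbp_coeff_sys = sbp_coeff_sys,
    sbp_coeff_dia = sbp_coeff_dia, sbp_coeff_ibi = sbp_coeff_ibi,
    dbp_intercept = dbp_intercept, dbp_coeff_sys = dbp_coeff_sys,
    dbp_coeff_dia = dbp_coeff_dia, dbp_coeff_ibi = dbp_coeff_ibi,
    bp_noise_std_mmHg = bp_noise_std_mmHg
  ), class = "bp_coupling")
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  carrier: %.4g GHz (wavelength %.3f mm)\n",
              x$carrier_frequency_hz / 1e9, x$wavelength_m * 1e3))
  cat(sprintf("  distance: %.3g m, phase offset: %.3g rad, fs: %g Hz\n",
              x$nominal_distance_m, x$default_phase_rad, x$sampling_rate_hz))
  invisible(x)
}

#' @export
print.physiology_params <- function(x, ...) {
  cat("<physiology_params>\n")
  cat(sprintf("  HR %.1f bpm (CV %.2f), systolic fraction %.2f\n",
              x$heart_rate_bpm, x$hr_variability_frac, x$systolic_fraction))
  cat(sprintf("  respiration %.2f Hz @ %.2g mm; bursts %.0f Hz, %.0f ms, %.2g um\n",
              x$respiration_rate_hz, x$respiration_amplitude_m * 1e3,
              x$burst_center_freq_hz, x$burst_duration_s * 1e3,
              x$burst_amplitude_m * 1e6))
  invisible(x)
}
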