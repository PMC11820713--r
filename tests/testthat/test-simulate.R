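# Synthetic generator: beat skeleton, displacement physics, quadrature
# demodulation, ECG template and BP coupling.

test_that("beat skeleton places R peaks and T ends analytically without jitter", {
  tr <- synth_beat_times(clean_physiology(heart_rate_bpm = 60,
                                          hr_variability_frac = 0,
                                          systolic_fraction = 0.35), 10)
  expect_equal(tr$r_peak_times_s, 0:9)
  expect_equal(tr$t_end_times_s, 0:8 + 0.35)

  tr75 <- synth_beat_times(clean_physiology(heart_rate_bpm = 75,
                                            hr_variability_frac = 0), 30)
  expect_true(all(abs(tr75$per_beat$ibi_s - 0.8) < 1e-12))
})

test_that("IBI jitter matches the stated multiplicative model", {
  tr <- synth_beat_times(clean_physiology(heart_rate_bpm = 60,
                                          hr_variability_frac = 0.05,
                                          seed = 42L), 320)
  expect_gt(nrow(tr$per_beat), 280)
  cv <- sd(tr$per_beat$ibi_s) / mean(tr$per_beat$ibi_s)
  expect_gt(cv, 0.03)
  expect_lt(cv, 0.07)
})

test_that("beat bookkeeping: systolic + diastolic = IBI, counts differ by <= 1", {
  for (seed in 1:5) {
    tr <- synth_beat_times(physiology_params(seed = seed), 60)
    expect_true(all(abs(tr$per_beat$systolic_s + tr$per_beat$diastolic_s -
                          tr$per_beat$ibi_s) < 1e-9))
    expect_lte(abs(length(tr$r_peak_times_s) - length(tr$t_end_times_s)), 1L)
  }
  expect_error(synth_beat_times(clean_physiology(), 1.5), "duration")
})

test_that("chest displacement components behave analytically", {
  phys0 <- clean_physiology(respiration_amplitude_m = 0,
                            cardiac_pulse_amplitude_m = 0,
                            burst_amplitude_m = 0)
  tr <- synth_beat_times(phys0, 10)
  expect_true(all(chest_displacement(tr, phys0, 1000, 10) == 0))

  phys_r <- clean_physiology(respiration_rate_hz = 0.25,
                             respiration_amplitude_m = 2e-3,
                             cardiac_pulse_amplitude_m = 0,
                             burst_amplitude_m = 0)
  x <- chest_displacement(tr, phys_r, 1000, 40)
  expect_equal(max(abs(x)), 2e-3, tolerance = 1e-6)
  sp <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) / 40
  expect_equal(freqs[which.max(sp[2:2000]) + 1], 0.25, tolerance = 0.026)

  phys_b <- clean_physiology(respiration_amplitude_m = 0,
                             cardiac_pulse_amplitude_m = 0,
                             burst_center_freq_hz = 18,
                             t_burst_amplitude_scale = 1,
                             t_burst_freq_scale = 1,
                             t_burst_duration_scale = 1)
  xb <- chest_displacement(tr, phys_b, 1000, 10)
  spb <- Mod(stats::fft(xb))^2
  fb <- (seq_along(xb) - 1) / 10
  half <- fb <= 500
  in_band <- half & fb >= 8 & fb <= 30
  ratio <- sum(spb[in_band]) / sum(spb[half])
  # oracle: in-band fraction of one isolated Hann-enveloped 18 Hz burst
  tt <- (0:9999) / 1000
  one <- ifelse(tt <= 0.08,
                sin(pi * tt / 0.08)^2 * sin(2 * pi * 18 * tt), 0)
  spo <- Mod(stats::fft(one))^2
  oracle <- sum(spo[in_band]) / sum(spo[half])
  expect_equal(ratio, oracle, tolerance = 0.02)
  expect_gt(ratio, 0.8)

  expect_error(chest_displacement(tr, phys_b, 50, 10), "aliasing")
})

test_that("quadrature demodulation follows the radar phase model", {
  rc <- radar_config()
  iq0 <- doppler_iq(rep(0, 50), rc)
  expect_true(all(abs(iq0$i - 1) < 1e-12) && all(abs(iq0$q) < 1e-12))

  iq8 <- doppler_iq(rep(rc$wavelength_m / 8, 50), rc)
  expect_true(all(abs(iq8$i) < 1e-12) && all(abs(iq8$q - 1) < 1e-12))

  # quadrature consistency without noise
  x <- 1e-4 * sin(2 * pi * 3 * (0:999) / 1000)
  iq <- doppler_iq(x, rc)
  expect_true(all(abs(iq$i^2 + iq$q^2 - 1) < 1e-12))

  expect_error(doppler_iq(c(0, NA), rc), "finite")
})

test_that("wavelength derivation and parameter validation hold", {
  rc <- radar_config(carrier_frequency_hz = 24.25e9)
  expect_equal(rc$wavelength_m, 2.998e8 / 24.25e9, tolerance = 1e-9)
  expect_error(radar_config(carrier_frequency_hz = -1), "positive")
  expect_error(physiology_params(systolic_fraction = 1.2), "0, 1")
  expect_error(physiology_params(burst_center_freq_hz = 40), "8, 30")
  expect_error(bp_coupling(bp_noise_std_mmHg = -1), ">= 0")
})

test_that("ECG template anchors R peaks and T ends", {
  tr1 <- manual_truth(c(1, 2))
  ecg <- synth_ecg(tr1, 1000, 2)
  expect_equal(which.max(ecg), 1001)

  phys <- clean_physiology(heart_rate_bpm = 62, hr_variability_frac = 0.04,
                           seed = 9L)
  tr <- synth_beat_times(phys, 12)
  ecg <- synth_ecg(tr, 1000, 12)
  # peak detection on clean output recovers every R peak within one sample
  for (r in tr$r_peak_times_s) {
    w <- max(1, round(r * 1000) + 1 - 50):min(length(ecg), round(r * 1000) + 1 + 50)
    expect_equal(w[which.max(ecg[w])], round(r * 1000) + 1)
  }
  # T wave returns to baseline at the T end within one sample
  for (te in tr$t_end_times_s) {
    i <- round(te * 1000) + 1
    expect_lt(abs(ecg[min(i + 1, length(ecg))]), 0.02)
  }

  empty <- manual_truth(c(0, 1))
  empty$r_peak_times_s <- numeric(0)
  empty$per_beat <- empty$per_beat[0, ]
  expect_true(all(synth_ecg(empty, 1000, 2) == 0))
  expect_error(synth_ecg(manual_truth(c(0, 0.2, 0.4)), 1000, 1), "template")
})

test_that("BP coupling is the stated linear form with per-segment noise", {
  tr <- synth_beat_times(clean_physiology(heart_rate_bpm = 60,
                                          hr_variability_frac = 0), 30)
  bounds <- data.frame(start_s = c(0, 10), end_s = c(10, 20))
  flat <- bp_coupling(sbp_intercept = 120, sbp_coeff_sys = 0,
                      sbp_coeff_dia = 0, sbp_coeff_ibi = 0,
                      bp_noise_std_mmHg = 0)
  bp <- synth_bp(tr, flat, bounds)
  expect_true(all(bp$sbp_mmHg == 120))

  # linear form: -50 mmHg/s on systole, mean systolic difference 0.04 s
  tr2 <- manual_truth(seq(0, 30, by = 1), frac = 0.30)
  tr2$per_beat$systolic_s[tr2$per_beat$r_peak_s >= 10] <- 0.34
  cp <- bp_coupling(sbp_intercept = 100, sbp_coeff_sys = -50,
                    sbp_coeff_dia = 0, sbp_coeff_ibi = 0,
                    bp_noise_std_mmHg = 0)
  bp2 <- synth_bp(tr2, cp, bounds)
  expect_equal(bp2$sbp_mmHg[1] - bp2$sbp_mmHg[2], 2.0, tolerance = 1e-9)

  # Monte-Carlo: residual std matches the configured noise
  tr3 <- synth_beat_times(clean_physiology(heart_rate_bpm = 60,
                                           hr_variability_frac = 0), 2505)
  b3 <- data.frame(start_s = seq(0, 2495, by = 5),
                   end_s = seq(0, 2495, by = 5) + 5)
  noisy <- bp_coupling(sbp_intercept = 120, sbp_coeff_sys = 0,
                       sbp_coeff_dia = 0, sbp_coeff_ibi = 0,
                       bp_noise_std_mmHg = 2)
  bp3 <- synth_bp(tr3, noisy, b3, seed = 7)
  expect_gt(sd(bp3$sbp_mmHg), 1.7)
  expect_lt(sd(bp3$sbp_mmHg), 2.3)

  expect_error(synth_bp(tr, flat, data.frame(start_s = 0, end_s = 0.5)),
               "no complete beat")
})

test_that("cohort generation is reproducible with distinct subjects", {
  co <- generate_cohort(2, 60, seed = 5)
  expect_equal(n_samples(co[[1]]$recording), 60000L)
  co2 <- generate_cohort(2, 60, seed = 5)
  expect_identical(co[[1]]$recording$channels, co2[[1]]$recording$channels)
  expect_identical(co[[2]]$truth$per_beat, co2[[2]]$truth$per_beat)
  ids <- vapply(co, function(e) e$recording$subject_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("phase-displacement round trip recovers the trace below 1e-9 m", {
  rc <- radar_config()
  phys <- clean_physiology(respiration_amplitude_m = 1e-4, seed = 3L)
  tr <- synth_beat_times(phys, 20)
  x <- chest_displacement(tr, phys, 1000, 20)
  iq <- doppler_iq(x, rc)
  xr <- demodulate_phase(iq$i, iq$q) * rc$wavelength_m / (4 * pi)
  err <- xr - x
  expect_lt(max(abs(err - mean(err))), 1e-9)
})
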