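# Beat sources, pulse-wave geometry and per-segment aggregation.

test_that("ECG-truth beats mirror the generator's beat table exactly", {
  tr <- synth_beat_times(clean_physiology(heart_rate_bpm = 60,
                                          hr_variability_frac = 0,
                                          systolic_fraction = 0.35), 20)
  beats <- ecg_truth_beats(tr)
  expect_equal(nrow(beats), length(tr$r_peak_times_s) - 1L)
  expect_true(all(abs(beats$systolic_s - 0.35) < 1e-12))
  expect_true(all(abs(beats$diastolic_s - 0.65) < 1e-12))
  expect_equal(beats$ibi_s, tr$per_beat$ibi_s)
  expect_true(all(beats$source == "ecg"))
})

test_that("the filter-based baseline reads geometry off the pulse wave", {
  fs <- 250
  t <- (0:(fs * 12 - 1)) / fs
  beats <- bpf_baseline_beats(sin(2 * pi * t), fs)
  expect_gt(nrow(beats), 8)
  expect_true(all(abs(beats$systolic_s - 0.5) < 2 / fs))
  expect_true(all(abs(beats$diastolic_s - 0.5) < 2 / fs))
  expect_true(all(abs(beats$ibi_s - 1.0) < 2 / fs))

  # asymmetric wave with a 30% fall: systolic interval 0.3 s
  ph <- (t %% 1)
  saw <- ifelse(ph < 0.7, ph / 0.7, (1 - ph) / 0.3)
  beats2 <- bpf_baseline_beats(saw, fs)
  expect_true(all(abs(beats2$systolic_s - 0.3) < 2 / fs))

  expect_warning(out <- bpf_baseline_beats(rep(0, 100), fs), "no pulse")
  expect_equal(nrow(out), 0L)
})

test_that("25% pulse width matches closed-form geometry", {
  fs <- 1000
  t <- (0:999) / fs
  one_beat <- data.frame(beat = 1L, sys_onset_s = 0, dia_onset_s = 0.35,
                         next_sys_onset_s = 0.999, systolic_s = 0.35,
                         diastolic_s = 0.649, ibi_s = 0.999, source = "ecg")

  tri <- pmax(0, 1 - abs(t - 0.4) / 0.2)     # rise 0.2 s, fall 0.2 s
  expect_equal(pulse_width_25(tri, one_beat, fs), 0.300, tolerance = 2e-3)

  rect <- as.numeric(t >= 0.3 & t < 0.55)    # width 0.25 s at any level
  expect_equal(pulse_width_25(rect, one_beat, fs), 0.25, tolerance = 4e-3)

  gauss <- exp(-(t - 0.45)^2 / (2 * 0.05^2))
  expect_equal(pulse_width_25(gauss, one_beat, fs),
               2 * 0.05 * sqrt(2 * log(4)), tolerance = 2e-3)

  expect_true(is.na(pulse_width_25(rep(1, 1000), one_beat, fs)))
})

test_that("segment aggregation averages beats inside the window", {
  beats <- data.frame(beat = 1:3,
                      sys_onset_s = c(1, 1.9, 3.0),
                      dia_onset_s = c(1.3, 2.2, 3.3),
                      next_sys_onset_s = c(1.9, 3.0, 3.9),
                      systolic_s = c(0.3, 0.3, 0.3),
                      diastolic_s = c(0.6, 0.8, 0.6),
                      ibi_s = c(0.9, 1.1, 0.9), source = "ecg")
  one <- aggregate_segment(beats[1, ], NULL, 0, 2, 120, 80)
  expect_equal(one$mean_ibi_s, 0.9)
  expect_equal(one$sbp_mmHg, 120)

  two <- aggregate_segment(beats, NULL, 0.5, 3.5)
  expect_equal(two$n_beats, 2L)
  expect_equal(two$mean_ibi_s, 1.0)

  shuffled <- aggregate_segment(beats[c(3, 1, 2), ], NULL, 0.5, 3.5)
  expect_equal(shuffled, two)

  expect_warning(out <- aggregate_segment(beats, NULL, 5, 6), "no complete")
  expect_null(out)
})

test_that("systolic and diastolic durations always sum to the IBI", {
  phys <- physiology_params(seed = 13L)
  sim <- simulate_recording("F", phys, duration_s = 30)
  pw <- pulse_wave(sim$recording)
  for (beats in list(ecg_truth_beats(sim$truth),
                     bpf_baseline_beats(pw, 1000))) {
    if (nrow(beats) == 0) next
    expect_lt(max(abs(beats$systolic_s + beats$diastolic_s - beats$ibi_s)),
              1e-9)
  }
})
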