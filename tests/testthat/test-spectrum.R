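# STFT framing, Parseval scaling and integrated-spectrum behaviour.

test_that("STFT frame geometry matches window/step arithmetic", {
  x <- rnorm(1000)
  sg <- stft(x, 1000, stft_config(window_ms = 256, step_ms = 1))
  expect_equal(nrow(sg$power), (1000 - 256) + 1)      # 745 frames
  expect_equal(sg$times_s[1], 0.128)                  # centre of first frame
  expect_equal(diff(sg$times_s)[1], 0.001)

  expect_true(all(stft(numeric(500), 1000)$power == 0))
  expect_error(stft(rnorm(100), 1000), "shorter")
})

test_that("full-band integration with a rectangular window satisfies Parseval", {
  set.seed(1)
  x <- rnorm(2000)
  sg <- stft(x, 1000, stft_config(window_function = "rect", step_ms = 50))
  en <- integrate_spectrum(sg, c(0, 500))
  starts <- seq(1, 2000 - 256 + 1, by = 50)
  direct <- vapply(starts, function(s) sum(x[s:(s + 255)]^2), numeric(1))
  expect_lt(max(abs(en$energy - direct) / direct), 1e-6)

  # also for a complex signal
  z <- complex(real = rnorm(1000), imaginary = rnorm(1000))
  sgz <- stft(z, 1000, stft_config(window_function = "rect", step_ms = 100))
  enz <- integrate_spectrum(sgz, c(0, 500))
  startsz <- seq(1, 1000 - 256 + 1, by = 100)
  directz <- vapply(startsz, function(s) sum(Mod(z[s:(s + 255)])^2), numeric(1))
  expect_lt(max(abs(enz$energy - directz) / directz), 1e-6)
})

test_that("band integration is monotone in band width and errors on empty bands", {
  set.seed(2)
  sg <- stft(rnorm(1500), 1000, stft_config(step_ms = 20))
  narrow <- integrate_spectrum(sg, c(10, 20))$energy
  wide <- integrate_spectrum(sg, c(5, 30))$energy
  full <- integrate_spectrum(sg, c(0, 500))$energy
  expect_true(all(wide >= narrow - 1e-12))
  expect_true(all(full >= wide - 1e-12))
  expect_error(integrate_spectrum(sg, c(501, 600)), "no frequency bins")
})

test_that("time shift of the input shifts the integrated spectrum by whole frames", {
  set.seed(3)
  x <- rnorm(3000)
  cfg <- stft_config(step_ms = 10)
  k <- 5                                     # shift by 5 steps = 50 samples
  e1 <- integrate_spectrum(stft(x, 1000, cfg), c(5, 30))$energy
  e2 <- integrate_spectrum(stft(c(numeric(50), x), 1000, cfg), c(5, 30))$energy
  n <- length(e1)
  expect_lt(max(abs(e2[(k + 1):(n)] - e1[1:(n - k)])), 1e-9)
})

test_that("min-max normalisation maps to [0,1] and is scale invariant", {
  isp <- structure(list(times_s = 1:3, energy = c(2, 4, 6),
                        band_hz = c(5, 30), frame_rate_hz = 1),
                   class = "integrated_spectrum")
  expect_equal(normalize_integrated(isp)$energy, c(0, 0.5, 1))
  isp$energy <- rep(3, 3)
  expect_equal(normalize_integrated(isp)$energy, c(0, 0, 0))
  isp$energy <- c(1, 5, 9)
  scaled <- isp; scaled$energy <- isp$energy * 17
  expect_equal(normalize_integrated(isp)$energy,
               normalize_integrated(scaled)$energy)
})

test_that("fixed-length resampling preserves ramps and endpoints", {
  v <- seq(0, 1, length.out = 1024)
  expect_equal(resample_to_length(v, 1024L), v)
  ramp <- seq(2, 5, length.out = 1250)
  out <- resample_to_length(ramp, 1024L)
  expect_equal(out[1], 2)
  expect_equal(out[1024], 5)
  expect_lt(max(abs(out - seq(2, 5, length.out = 1024))), 1e-9)
})

test_that("per-beat integrated-spectrum peaks align with both burst centres", {
  phys <- clean_physiology(seed = 5L)
  sim <- simulate_recording("A", phys, duration_s = 30)
  isp <- integrated_spectrum(sim$recording, cfg = stft_config(step_ms = 2))
  al <- two_peak_alignment(isp, sim$truth, tol_s = 0.03)
  expect_gt(al$fraction_aligned, 0.9)
})
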