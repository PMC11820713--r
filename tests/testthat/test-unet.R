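# U-net architecture, training engine and mask conversion.

test_that("default architecture realises the reference block shapes", {
  m <- build_model(unet_config())
  shapes <- unet_shapes(m)
  expect_equal(shapes, list(c(512L, 32L), c(256L, 64L), c(128L, 128L),
                            c(128L, 256L), c(256L, 128L), c(512L, 64L),
                            c(1024L, 32L), c(1024L, 1L)),
               ignore_attr = TRUE)
})

test_that("shapes scale with halved input length", {
  m <- build_model(unet_config(input_length = 512L))
  shapes <- unet_shapes(m)
  expect_equal(shapes[[1]], c(256, 32), ignore_attr = TRUE)
  expect_equal(shapes[[8]], c(512, 1), ignore_attr = TRUE)
  expect_error(unet_config(input_length = 100L), "divisible")
})

test_that("building is deterministic under the seed", {
  cfg <- unet_config(encoder_filters = c(4L, 8L), bottom_filters = 16L,
                     input_length = 64L, seed = 7L)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
})

test_that("backpropagation matches numerical gradients on a tiny net", {
  cfg <- unet_config(input_length = 16L, encoder_filters = c(2L, 3L),
                     bottom_filters = 4L, seed = 42L)
  m <- build_model(cfg)
  set.seed(7)
  x <- matrix(rnorm(2 * 16), 2, 16)
  y <- matrix(rbinom(2 * 16, 1, 0.5), 2, 16)
  loss <- function(params) {
    fw <- radarbp:::.unet_forward(params, cfg, x, training = TRUE)
    mean((fw$pred - y)^2)
  }
  fw <- radarbp:::.unet_forward(m$params, cfg, x, training = TRUE)
  grads <- radarbp:::.unet_backward(m$params, cfg, fw$caches,
                                    2 * (fw$pred - y) / length(y))
  eps <- 1e-5
  probes <- list(
    list(get = function(p) p$enc[[1]][[1]]$conv$W,
         set = function(p, v) { p$enc[[1]][[1]]$conv$W[] <- v; p },
         g = grads$enc[[1]][[1]]$conv$W),
    list(get = function(p) p$dec[[2]][[1]]$conv$W,
         set = function(p, v) { p$dec[[2]][[1]]$conv$W[] <- v; p },
         g = grads$dec[[2]][[1]]$conv$W),
    list(get = function(p) p$bottom[[1]]$bn$gamma,
         set = function(p, v) { p$bottom[[1]]$bn$gamma[] <- v; p },
         g = grads$bottom[[1]]$bn$gamma),
    list(get = function(p) p$final$W,
         set = function(p, v) { p$final$W[] <- v; p },
         g = grads$final$W))
  for (pr in probes) {
    p0 <- pr$get(m$params)
    for (i in sample(length(p0), min(3, length(p0)))) {
      v <- p0; v[i] <- v[i] + eps
      lp <- loss(pr$set(m$params, v))
      v <- p0; v[i] <- v[i] - eps
      lm <- loss(pr$set(m$params, v))
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(pr$g[i] - num) / max(1e-8, abs(num) + abs(pr$g[i])), 1e-5)
    }
  }
})

test_that("training drives degenerate targets to the target value", {
  cfg <- unet_config(input_length = 64L, encoder_filters = c(4L, 8L),
                     bottom_filters = 8L, epochs = 50L, batch_size = 4L,
                     learning_rate = 0.05, seed = 3L)
  set.seed(5)
  x <- matrix(runif(16 * 64), 16, 64)
  y0 <- matrix(0, 16, 64)
  fit <- unet_fit(x, y0, cfg)
  expect_equal(nrow(fit$history), 50L)
  expect_true(all(diff(fit$history$mae[40:50]) <= 0.01))
  pred <- predict(fit, x[1, ])
  expect_lt(mean(pred$values), 0.05)
})

test_that("prediction is deterministic with clipped, thresholded output", {
  cfg <- unet_config(input_length = 32L, encoder_filters = c(2L, 4L),
                     bottom_filters = 4L, epochs = 1L, batch_size = 4L,
                     seed = 2L)
  x <- matrix(runif(8 * 32), 8, 32)
  y <- matrix(rep(c(0, 1), each = 16), 8, 32, byrow = TRUE)
  fit <- unet_fit(x, y, cfg)
  p1 <- predict(fit, x[3, ])
  p2 <- predict(fit, x[3, ])
  expect_identical(p1$values, p2$values)
  expect_true(all(p1$values >= 0 & p1$values <= 1))
  expect_equal(p1$binary, as.integer(p1$values >= 0.5))
  expect_error(predict(fit, runif(33)), "input length")

  mask <- structure(list(values = c(0.2, 0.5, 0.9),
                         binary = as.integer(c(0.2, 0.5, 0.9) >= 0.5)),
                    class = "segmentation_mask")
  expect_equal(mask$binary, c(0L, 1L, 1L))
})

test_that("labels encode systole as 0 and diastole as 1", {
  tr <- manual_truth(c(0, 1), frac = 0.35)
  times <- seq(0, 0.999, by = 0.001)
  lab <- make_labels(tr, times)
  expect_equal(mean(lab == 0), 0.35, tolerance = 0.01)
  expect_true(all(lab[times < 0.35] == 0))
  expect_true(all(lab[times >= 0.35] == 1))

  # frames before the first R peak inherit the in-progress diastole
  tr2 <- manual_truth(c(0.5, 1.5, 2.5))
  lab2 <- make_labels(tr2, c(0.1, 0.4))
  expect_equal(lab2, c(1L, 1L))

  # long-window mean approximates the diastolic fraction
  tr3 <- synth_beat_times(clean_physiology(heart_rate_bpm = 72,
                                           systolic_fraction = 0.4,
                                           seed = 8L), 120)
  lab3 <- make_labels(tr3, seq(0, 119, by = 0.008))
  expect_equal(mean(lab3), 0.6, tolerance = 0.02)
})

test_that("mask-to-beat conversion inverts label generation", {
  mask <- c(rep(1, 20), rep(0, 40), rep(1, 85), rep(0, 40), rep(1, 30))
  beats <- mask_to_beats(mask, frame_rate_hz = 125)
  expect_equal(nrow(beats), 1L)
  expect_equal(beats$systolic_s, 0.320)
  expect_equal(beats$diastolic_s, 0.680)
  expect_equal(beats$ibi_s, 1.000)

  # labels -> beats round trip within one frame
  tr <- synth_beat_times(clean_physiology(heart_rate_bpm = 66, seed = 4L), 20)
  times <- seq(0, 19.99, by = 0.008)
  lab <- make_labels(tr, times)
  rb <- mask_to_beats(lab, times_s = times)
  for (k in seq_len(nrow(rb))) {
    j <- which.min(abs(tr$per_beat$r_peak_s - rb$sys_onset_s[k]))
    expect_lt(abs(rb$systolic_s[k] - tr$per_beat$systolic_s[j]), 0.009)
    expect_lt(abs(rb$ibi_s[k] - tr$per_beat$ibi_s[j]), 0.009)
  }

  # an isolated 2-frame flip inside a run does not change the beat count
  flipped <- mask
  flipped[40:41] <- 1
  expect_equal(nrow(mask_to_beats(flipped, frame_rate_hz = 125)), 1L)
  # an interior run below the physiological floor is despeckled away
  flipped2 <- mask
  flipped2[100:110] <- 0
  expect_equal(nrow(mask_to_beats(flipped2, frame_rate_hz = 125)), 1L)

  expect_warning(out <- mask_to_beats(rep(1, 100), frame_rate_hz = 125),
                 "constant")
  expect_equal(nrow(out), 0L)
})
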