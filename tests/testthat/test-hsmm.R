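# Duration-dependent HSMM: emissions, dwell distributions, decoding.

test_that("logistic emissions separate a constructed four-cluster toy", {
  set.seed(1)
  n <- 200
  centers <- cbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
  feats <- do.call(rbind, lapply(1:4, function(j)
    cbind(rnorm(n, centers[1, j], 0.3), rnorm(n, centers[2, j], 0.3))))
  colnames(feats) <- c("f1", "f2")
  labels <- rep(1:4, each = n)
  em <- fit_emissions(feats, labels, seed = 1)
  post <- radarbp:::emission_posteriors(em, feats)
  expect_gte(mean(max.col(post) == labels), 0.99)
  expect_lt(max(abs(rowSums(post) - 1)), 1e-9)

  # permuting rows leaves the fitted weights essentially unchanged
  perm <- sample(nrow(feats))
  em2 <- fit_emissions(feats[perm, ], labels[perm], seed = 1)
  expect_lt(max(abs(em$coefficients - em2$coefficients)), 1e-4)

  expect_error(fit_emissions(feats, rep(c(1, 2, 4), length.out = 800)), "3")
})

test_that("dwell distributions are fitted from uncensored run lengths", {
  labels <- rep(rep(1:4, times = c(5, 40, 5, 60)), 10)
  dp <- fit_durations(list(labels))
  expect_equal(dp$mean_frames[2], 40)
  expect_equal(dp$sd_frames[2], 2)           # floored
  for (j in 1:4) {
    tab <- radarbp:::.duration_tables(dp$mean_frames[j], dp$sd_frames[j],
                                      dp$d_min[j], dp$d_max[j])
    expect_lt(abs(sum(exp(tab$logp)) - 1), 1e-12)
  }
  expect_error(fit_durations(list(rep(c(1, 2), times = c(5, 5)))), "too few")
})

test_that("dwell fitting recovers a known Gaussian run-length law", {
  set.seed(7)
  runs <- round(rnorm(200, 50, 5))
  labels <- unlist(lapply(runs, function(d)
    rep(rep(1:4, times = c(4, 10, 4, 0)), 1) |> c(rep(4L, d))))
  dp <- fit_durations(list(labels))
  expect_lt(abs(dp$mean_frames[4] - 50), 1)
  expect_lt(abs(dp$sd_frames[4] - 5), 1)
})

test_that("forced-duration decoding yields the deterministic cycle", {
  dstar <- c(4, 7, 3, 6)
  model <- random_small_hsmm(1)
  model$durations <- data.frame(state = 1:4, mean_frames = dstar,
                                sd_frames = rep(0.1, 4), d_min = dstar,
                                d_max = dstar)
  T_len <- sum(dstar) * 2
  expected <- rep(rep(1:4, 2), times = rep(dstar, 2))
  # weakly informative emissions break the alignment tie among valid tilings
  b <- matrix(0.2, T_len, 4)
  b[cbind(seq_len(T_len), expected)] <- 0.4
  path <- viterbi_hsmm(model, b)
  expect_equal(path$states, expected)
})

test_that("emission scaling shifts the log-probability without changing the path", {
  model <- random_small_hsmm(3)
  set.seed(33)
  b <- matrix(runif(25 * 4, 0.05, 1), 25, 4)
  p1 <- viterbi_hsmm(model, b)
  p2 <- viterbi_hsmm(model, b * 0.5)
  expect_equal(p2$states, p1$states)
  expect_equal(p2$log_probability - p1$log_probability, 25 * log(0.5),
               tolerance = 1e-9)
})

test_that("exhaustive decoder is self-consistent and guarded", {
  model <- random_small_hsmm(5)
  model$durations$d_min <- rep(5L, 4)
  model$durations$d_max <- rep(5L, 4)
  set.seed(55)
  b <- matrix(runif(20 * 4), 20, 4)
  bf <- brute_force_decode(model, b)
  # tight dwell bounds: every interior run is exactly 5 frames and the state
  # order follows the fixed 4-cycle
  r <- rle(bf$states)
  if (length(r$lengths) > 2)
    expect_true(all(r$lengths[-c(1, length(r$lengths))] == 5L))
  for (k in seq_len(length(r$values) - 1L))
    expect_equal(r$values[k + 1L], model$successor[r$values[k]])
  expect_error(brute_force_decode(model, matrix(0.5, 40, 4)), "T <= 30")
})

test_that("decoded path never scores below the generating path", {
  for (seed in 1:10) {
    model <- random_small_hsmm(seed)
    set.seed(seed + 500)
    T_len <- sample(15:30, 1)
    b <- matrix(runif(T_len * 4, 0.01, 1), T_len, 4)
    v <- viterbi_hsmm(model, b)
    bf <- brute_force_decode(model, b)
    expect_gte(v$log_probability + 1e-9, bf$log_probability)
  }
})

test_that("run-length arithmetic converts paths to beats", {
  states <- c(rep(4, 10), rep(1, 5), rep(2, 35), rep(3, 5), rep(4, 80),
              rep(1, 5), rep(2, 30))
  beats <- path_to_beats(states, frame_rate_hz = 125)
  expect_equal(nrow(beats), 1L)
  expect_equal(beats$systolic_s, 0.32)
  expect_equal(beats$diastolic_s, 0.68)
  expect_equal(beats$ibi_s, 1.00)
  expect_lt(abs(beats$systolic_s + beats$diastolic_s - beats$ibi_s), 1e-9)

  expect_warning(out <- path_to_beats(c(rep(4, 10), rep(1, 90)),
                                      frame_rate_hz = 125), "complete beat")
  expect_equal(nrow(out), 0L)
})

test_that("uniform emissions reproduce the modal dwell structure", {
  model <- random_small_hsmm(9)
  model$durations$sd_frames <- rep(0.5, 4)
  modal <- round(pmin(pmax(model$durations$mean_frames,
                           model$durations$d_min), model$durations$d_max))
  b <- matrix(0.25, 60, 4)
  path <- viterbi_hsmm(model, b)
  r <- rle(path$states)
  interior <- r$lengths[-c(1, length(r$lengths))]
  interior_states <- r$values[-c(1, length(r$values))]
  expect_true(all(interior == modal[interior_states]))
})

test_that("model serialization round-trips through plain text", {
  set.seed(11)
  feats <- matrix(rnorm(400 * 3), ncol = 3,
                  dimnames = list(NULL, c("energy", "denergy", "envelope")))
  labels <- rep(rep(1:4, times = c(10, 30, 10, 50)), 4)
  model <- hsmm_fit(feats, labels, frame_rate_hz = 125, seed = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_hsmm_model(model, path)
  back <- read_hsmm_model(path)
  expect_equal(back$durations$mean_frames, model$durations$mean_frames)
  expect_equal(unname(back$emissions$coefficients),
               unname(model$emissions$coefficients), tolerance = 1e-8)
  b <- radarbp:::emission_posteriors(back$emissions, feats)
  expect_equal(viterbi_hsmm(back, b)$states,
               viterbi_hsmm(model, radarbp:::emission_posteriors(
                 model$emissions, feats))$states)
})
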