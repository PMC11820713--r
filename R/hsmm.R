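# Four-state duration-dependent hidden semi-Markov model over the integrated
# spectrum. States follow the fixed cycle
#   1 (systole-onset vibration) -> 2 (systolic interval) ->
#   3 (diastole-onset vibration) -> 4 (diastolic interval) -> 1 ...
# Emissions are multinomial-logistic posteriors; dwell times follow
# discretized truncated Gaussians; decoding is an extended Viterbi that
# maximises over dwell lengths. Boundary runs are scored with the duration
# survival function (segments cut the cycle at arbitrary phase).

HSMM_PRED <- c(4L, 1L, 2L, 3L)  # predecessor of each state in the 4-cycle
EMISSION_FLOOR <- 1e-12

#' Ground-truth frame labels for the four-state cycle
#'
#' Assigns each frame time to a state: the burst window starting at each R
#' peak is state 1, the remainder of systole state 2, the burst window at the
#' T-wave end state 3, and the remainder of diastole state 4. Frames before
#' the first R peak inherit the in-progress phase (state 4).
#'
#' @param truth a `ground_truth`.
#' @param times_s frame timestamps in seconds.
#' @param burst_duration_s systole-onset burst-window length; defaults to the
#'   generator's.
#' @param t_burst_duration_s diastole-onset burst-window length.
#' @return integer vector of states in `1..4`, one per frame.
#' @export
hsmm_frame_labels <- function(truth, times_s,
                              burst_duration_s = truth$physiology$burst_duration_s,
                              t_burst_duration_s = truth$physiology$burst_duration_s *
                                truth$physiology$t_burst_duration_scale) {
  pb <- truth$per_beat
  bounds <- numeric(0)
  states <- integer(0)
  for (b in seq_len(nrow(pb))) {
    r <- pb$r_peak_s[b]; te <- pb$t_end_s[b]
    d1 <- min(burst_duration_s, 0.8 * (te - r))
    d3 <- min(t_burst_duration_s, 0.8 * pb$diastolic_s[b])
    bounds <- c(bounds, r, r + d1, te, te + d3)
    states <- c(states, 1L, 2L, 3L, 4L)
  }
  idx <- findInterval(times_s, bounds)
  out <- ifelse(idx == 0L, 4L, states[pmax(idx, 1L)])
  as.integer(out)
}

#' Per-frame emission features from an integrated spectrum
#'
#' Three features per frame: min-max normalised energy, its first difference,
#' and a 100 ms moving-average envelope. All are invariant to positive
#' rescaling of the raw energy.
#'
#' @param ispec an `integrated_spectrum`.
#' @return numeric matrix (frames x 3) with columns
#'   `energy`, `denergy`, `envelope`.
#' @export
extract_emission_features <- function(ispec) {
  e <- normalize_integrated(ispec)$energy
  k <- max(3L, round(0.1 * ispec$frame_rate_hz))
  out <- cbind(energy = e,
               denergy = c(0, diff(e)),
               envelope = moving_average(e, k))
  if (any(!is.finite(out))) stop("non-finite emission features", call. = FALSE)
  out
}

#' Fit multinomial-logistic emissions
#'
#' Trains a 4-class multinomial logistic regression of frame state on the
#' emission features; the per-frame class posteriors serve as the observation
#' likelihood proxies `b_j(O_t)`.
#'
#' @param features numeric matrix (frames x k).
#' @param frame_labels integer states in `1..4`, one per frame.
#' @param seed integer seed (the optimiser's weight initialisation draws from
#'   the RNG).
#' @return list with the coefficient matrix (`(k+1) x 4`, reference class 1
#'   as a zero column) and the feature names.
#' @export
fit_emissions <- function(features, frame_labels, seed = 1L) {
  absent <- setdiff(1:4, unique(frame_labels))
  if (length(absent))
    stop("missing state(s) in training labels: ",
         paste(absent, collapse = ", "), call. = FALSE)
  df <- data.frame(state = factor(frame_labels, levels = 1:4), features)
  fit <- with_seed(seed,
    nnet::multinom(state ~ ., data = df, trace = FALSE, maxit = 300))
  cf <- stats::coef(fit)                      # 3 x (k+1), classes 2..4
  coefs <- cbind(`1` = 0, t(cf))              # (k+1) x 4
  list(coefficients = coefs, feature_names = colnames(features))
}

# Softmax posteriors from a fitted emission model.
emission_posteriors <- function(emissions, features) {
  eta <- cbind(1, features) %*% emissions$coefficients
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Fit per-state duration distributions from labelled frame sequences
#'
#' Collects run lengths per state (the censored first and last run of every
#' sequence are excluded) and fits a discretized Gaussian on
#' `[d_min, d_max]`, renormalised to sum to 1; the standard deviation is
#' floored at 2 frames.
#'
#' @param label_sequences list of integer state sequences.
#' @param d_bounds 4x2 matrix of `(d_min, d_max)` per state, in frames.
#' @param min_runs minimum complete runs required per state.
#' @return data.frame with `state`, `mean_frames`, `sd_frames`, `d_min`, `d_max`.
#' @export
fit_durations <- function(label_sequences,
                          d_bounds = default_duration_bounds(),
                          min_runs = 3L) {
  if (!is.list(label_sequences)) label_sequences <- list(label_sequences)
  runs <- vector("list", 4L)
  for (seq_labels in label_sequences) {
    r <- rle(as.integer(seq_labels))
    if (length(r$lengths) <= 2L) next
    keep <- 2L:(length(r$lengths) - 1L)       # censored edges excluded
    for (j in 1:4)
      runs[[j]] <- c(runs[[j]], r$lengths[keep][r$values[keep] == j])
  }
  n_runs <- vapply(runs, length, integer(1))
  if (any(n_runs < min_runs))
    stop("too few complete runs for state(s): ",
         paste(which(n_runs < min_runs), collapse = ", "), call. = FALSE)
  data.frame(
    state = 1:4,
    mean_frames = vapply(runs, mean, numeric(1)),
    sd_frames = pmax(2, vapply(runs, stats::sd, numeric(1))),
    d_min = d_bounds[, 1L],
    d_max = d_bounds[, 2L]
  )
}

#' Default dwell-time bounds (frames at 125 Hz)
#'
#' Vibration states (1, 3) last 24-200 ms. The quiescent states are capped at
#' resting-physiology maxima (systole 0.56 s, diastole 1.04 s); looser caps
#' would let the decoder absorb a whole skipped beat into one run at high
#' heart rates.
#'
#' @param frame_rate_hz frame rate the bounds are scaled to.
#' @return 4x2 integer matrix of `(d_min, d_max)` per state.
#' @export
default_duration_bounds <- function(frame_rate_hz = 125) {
  sc <- frame_rate_hz / 125
  m <- rbind(c(3, 25), c(5, 70), c(3, 25), c(5, 130)) * sc
  cbind(pmax(1L, as.integer(round(m[, 1]))), as.integer(round(m[, 2])))
}

# Discretized truncated-Gaussian log-pmf over 1..d_max (zero mass below
# d_min) and the matching log survival function P(D >= d).
.duration_tables <- function(mu, sigma, d_min, d_max) {
  d <- seq_len(d_max)
  p <- numeric(d_max)
  p[d >= d_min] <- stats::dnorm(d[d >= d_min], mu, sigma)
  if (sum(p) <= 0) p[d >= d_min] <- 1
  p <- p / sum(p)
  surv <- rev(cumsum(rev(p)))
  list(logp = log(pmax(p, 1e-300)), logS = log(pmax(surv, 1e-300)))
}

#' Fit the complete hidden semi-Markov model
#'
#' Combines [fit_emissions()] on the pooled frames with [fit_durations()] on
#' the per-sequence run lengths. The initial distribution is uniform over the
#' four states (analysis windows start at arbitrary cycle phase) and the
#' transition topology is the fixed 4-cycle.
#'
#' @param feature_list list of per-sequence feature matrices
#'   (from [extract_emission_features()]).
#' @param label_list list of per-sequence integer state labels.
#' @param frame_rate_hz frame rate in Hz.
#' @param d_bounds per-state dwell bounds; defaults scale with the frame rate.
#' @param seed integer seed for the emission fit.
#' @return an object of class `radar_hsmm`.
#' @export
hsmm_fit <- function(feature_list, label_list, frame_rate_hz = 125,
                     d_bounds = default_duration_bounds(frame_rate_hz),
                     seed = 1L) {
  if (!is.list(feature_list)) feature_list <- list(feature_list)
  if (!is.list(label_list)) label_list <- list(label_list)
  features <- do.call(rbind, feature_list)
  labels <- unlist(label_list)
  emissions <- fit_emissions(features, labels, seed = seed)
  durations <- fit_durations(label_list, d_bounds)
  structure(list(
    n_states = 4L,
    pi = rep(0.25, 4L),
    successor = c(2L, 3L, 4L, 1L),
    durations = durations,
    emissions = emissions,
    frame_rate_hz = frame_rate_hz
  ), class = "radar_hsmm")
}

#' @export
print.radar_hsmm <- function(x, ...) {
  cat("<radar_hsmm> four-state cyclic duration-dependent HSMM\n")
  cat(sprintf("  frame rate %g Hz; emission features: %s\n", x$frame_rate_hz,
              paste(x$emissions$feature_names, collapse = ", ")))
  d <- x$durations
  for (j in 1:4)
    cat(sprintf("  state %d: dwell %.1f +/- %.1f frames (bounds %d..%d)\n",
                j, d$mean_frames[j], d$sd_frames[j], d$d_min[j], d$d_max[j]))
  invisible(x)
}

#' @export
summary.radar_hsmm <- function(object, ...) {
  print(object)
  cat("  emission coefficients:\n")
  print(round(object$emissions$coefficients, 3))
  invisible(object)
}

#' Duration-dependent Viterbi decoding
#'
#' Implements the dwell-extended recursion
#' `delta_t(j) = max_d delta_{t-d}(pred(j)) * p_j(d) * prod_s b_j(O_{t-s})`
#' in the log domain with prefix-summed log-emissions (`O(T * N * d_max)`).
#' The first and last runs of the window are scored with the duration
#' survival function instead of the pmf (left/right censoring); ties are
#' broken toward the smallest dwell length.
#'
#' @param model a `radar_hsmm`.
#' @param b emission matrix (frames x 4) of per-state observation likelihood
#'   proxies in `(0, 1]`; floored at 1e-12 before taking logs.
#' @return an object of class `hsmm_path`: `states` (integer per frame),
#'   `log_probability`, and `frame_rate_hz`.
#' @export
viterbi_hsmm <- function(model, b) {
  T_len <- nrow(b)
  dd <- model$durations
  if (T_len < 1L) stop("empty emission matrix", call. = FALSE)
  logb <- log(pmax(b, EMISSION_FLOOR))
  C <- rbind(0, apply(logb, 2L, cumsum))     # C[t+1, j] = sum logb[1..t, j]
  logpi <- log(model$pi)
  tab <- lapply(1:4, function(j)
    .duration_tables(dd$mean_frames[j], dd$sd_frames[j], dd$d_min[j], dd$d_max[j]))

  V <- matrix(-Inf, T_len, 4L)
  Bd <- matrix(NA_integer_, T_len, 4L)       # chosen dwell; 0 marks first-run
  for (t in seq_len(T_len)) {
    for (j in 1:4) {
      pj <- HSMM_PRED[j]
      best <- -Inf; bd <- NA_integer_
      dmax_j <- dd$d_max[j]
      ds_hi <- min(dmax_j, t - 1L)
      if (ds_hi >= dd$d_min[j]) {
        ds <- dd$d_min[j]:ds_hi
        vals <- V[t - ds, pj] + tab[[j]]$logp[ds] + (C[t + 1L, j] - C[t - ds + 1L, j])
        k <- which.max(vals)                 # first max = smallest dwell
        if (is.finite(vals[k])) { best <- vals[k]; bd <- ds[k] }
      }
      if (t <= dmax_j) {                     # left-censored first run
        cand <- logpi[j] + tab[[j]]$logS[t] + (C[t + 1L, j] - C[1L, j])
        if (cand > best) { best <- cand; bd <- 0L }
      }
      V[t, j] <- best
      Bd[t, j] <- bd
    }
  }

  # right-censored final run (covers frames T-dL+1 .. T)
  best <- -Inf; bj <- NA_integer_; bdl <- NA_integer_; single <- FALSE
  for (j in 1:4) {
    dmax_j <- dd$d_max[j]
    for (dl in seq_len(min(dmax_j, T_len - 1L))) {
      prev <- T_len - dl
      cand <- V[prev, HSMM_PRED[j]] + tab[[j]]$logS[dl] +
        (C[T_len + 1L, j] - C[prev + 1L, j])
      if (cand > best) { best <- cand; bj <- j; bdl <- dl; single <- FALSE }
    }
    if (T_len <= dmax_j) {                   # one run spans the whole window
      cand <- logpi[j] + tab[[j]]$logS[T_len] + (C[T_len + 1L, j] - C[1L, j])
      if (cand > best) { best <- cand; bj <- j; bdl <- T_len; single <- TRUE }
    }
  }
  if (!is.finite(best))
    stop("no feasible decode: window shorter than minimum dwell structure",
         call. = FALSE)

  states <- integer(T_len)
  if (single) {
    states[] <- bj
  } else {
    states[(T_len - bdl + 1L):T_len] <- bj
    t <- T_len - bdl; j <- HSMM_PRED[bj]
    while (t > 0L) {
      d <- Bd[t, j]
      if (d == 0L) { states[1L:t] <- j; break }
      states[(t - d + 1L):t] <- j
      t <- t - d; j <- HSMM_PRED[j]
    }
  }
  structure(list(states = states, log_probability = best,
                 frame_rate_hz = model$frame_rate_hz), class = "hsmm_path")
}

#' Exhaustive reference decoder
#'
#' Enumerates every duration-segmented cyclic state path and scores it with
#' the same boundary-censored product as [viterbi_hsmm()]. Cost grows
#' exponentially; guarded to `T <= 30`.
#'
#' @param model a `radar_hsmm`.
#' @param b emission matrix (frames x 4).
#' @return an `hsmm_path` with the maximum-probability segmentation.
#' @export
brute_force_decode <- function(model, b) {
  T_len <- nrow(b)
  if (T_len > 30L) stop("brute_force_decode is guarded to T <= 30", call. = FALSE)
  dd <- model$durations
  logb <- log(pmax(b, EMISSION_FLOOR))
  C <- rbind(0, apply(logb, 2L, cumsum))
  logpi <- log(model$pi)
  tab <- lapply(1:4, function(j)
    .duration_tables(dd$mean_frames[j], dd$sd_frames[j], dd$d_min[j], dd$d_max[j]))
  emis <- function(j, from, to) C[to + 1L, j] - C[from, j]

  best <- list(score = -Inf, states = NULL)
  recurse <- function(pos, j, states, score) {
    remaining <- T_len - pos
    for (d in seq_len(min(dd$d_max[j], remaining))) {
      run <- c(states, rep(j, d))
      if (d == remaining) {                  # right-censored final run
        s <- score + tab[[j]]$logS[d] + emis(j, pos + 1L, T_len)
        if (s > best$score) best <<- list(score = s, states = run)
      } else if (d >= dd$d_min[j]) {         # complete interior run
        recurse(pos + d, model$successor[j], run,
                score + tab[[j]]$logp[d] + emis(j, pos + 1L, pos + d))
      }
    }
  }
  for (j0 in 1:4) {
    for (d1 in seq_len(min(dd$d_max[j0], T_len))) {
      s <- logpi[j0] + tab[[j0]]$logS[d1] + emis(j0, 1L, d1)
      if (d1 == T_len) {
        if (s > best$score) best <- list(score = s, states = rep(j0, T_len))
      } else {
        recurse(d1, model$successor[j0], rep(j0, d1), s)
      }
    }
  }
  structure(list(states = best$states, log_probability = best$score,
                 frame_rate_hz = model$frame_rate_hz), class = "hsmm_path")
}

#' @export
print.hsmm_path <- function(x, ...) {
  r <- rle(x$states)
  cat(sprintf("<hsmm_path> %d frames, %d runs, log-probability %.3f\n",
              length(x$states), length(r$lengths), x$log_probability))
  invisible(x)
}

#' Convert a decoded state path to beat annotations
#'
#' Each onset of state 1 marks a systole onset and the following onset of
#' state 3 the diastole onset; censored partial beats at the window edges are
#' dropped.
#'
#' @param path an `hsmm_path` (or integer state vector).
#' @param frame_rate_hz frame rate; taken from the path if available.
#' @param times_s optional frame timestamps (overrides `frame_rate_hz`).
#' @return a beat-annotation data.frame (see [ecg_truth_beats()] for columns)
#'   with `source = "hsmm"`.
#' @export
path_to_beats <- function(path, frame_rate_hz = NULL, times_s = NULL) {
  states <- if (inherits(path, "hsmm_path")) path$states else as.integer(path)
  if (is.null(frame_rate_hz) && inherits(path, "hsmm_path"))
    frame_rate_hz <- path$frame_rate_hz
  if (is.null(times_s))
    times_s <- (seq_along(states) - 1L) / frame_rate_hz
  on <- run_onsets(states)
  on_states <- states[on]
  # drop the (censored) first run's onset: it is not a transition
  on <- on[-1L]; on_states <- on_states[-1L]
  s1 <- on[on_states == 1L]
  s3 <- on[on_states == 3L]
  if (length(s1) < 2L) {
    warning("fewer than one complete beat in decoded path")
    return(empty_beats("hsmm"))
  }
  beats <- empty_beats("hsmm")
  for (k in seq_len(length(s1) - 1L)) {
    mid <- s3[s3 > s1[k] & s3 < s1[k + 1L]]
    if (length(mid) != 1L) next
    beats <- rbind(beats, data.frame(
      beat = nrow(beats) + 1L,
      sys_onset_s = times_s[s1[k]],
      dia_onset_s = times_s[mid],
      next_sys_onset_s = times_s[s1[k + 1L]],
      systolic_s = times_s[mid] - times_s[s1[k]],
      diastolic_s = times_s[s1[k + 1L]] - times_s[mid],
      ibi_s = times_s[s1[k + 1L]] - times_s[s1[k]],
      source = "hsmm"))
  }
  beats
}

#' Decode a recording or integrated spectrum with a fitted HSMM
#'
#' @param object a `radar_hsmm`.
#' @param ispec an `integrated_spectrum` (or emission feature matrix).
#' @param ... unused.
#' @return beat annotations (data.frame); the decoded `hsmm_path` is attached
#'   as attribute `"path"`.
#' @export
predict.radar_hsmm <- function(object, ispec, ...) {
  if (inherits(ispec, "integrated_spectrum")) {
    features <- extract_emission_features(ispec)
    times <- ispec$times_s
  } else {
    features <- ispec
    times <- NULL
  }
  bmat <- emission_posteriors(object$emissions, features)
  path <- viterbi_hsmm(object, bmat)
  beats <- path_to_beats(path, frame_rate_hz = object$frame_rate_hz,
                         times_s = times)
  attr(beats, "path") <- path
  beats
}

#' Serialize / restore a fitted HSMM as structured plain text
#' @param model a `radar_hsmm`.
#' @param path file path (YAML).
#' @return `path` invisibly (write); a `radar_hsmm` (read).
#' @export
write_hsmm_model <- function(model, path) {
  yaml::write_yaml(list(
    pi = model$pi,
    frame_rate_hz = model$frame_rate_hz,
    durations = as.list(model$durations),
    emission_coefficients = as.list(as.data.frame(model$emissions$coefficients)),
    feature_names = model$emissions$feature_names
  ), path, precision = 15L)
  invisible(path)
}

#' @rdname write_hsmm_model
#' @export
read_hsmm_model <- function(path) {
  y <- yaml::read_yaml(path)
  coefs <- as.matrix(as.data.frame(y$emission_coefficients))
  colnames(coefs) <- as.character(1:4)
  rownames(coefs) <- c("(Intercept)", y$feature_names)
  structure(list(
    n_states = 4L, pi = as.numeric(y$pi), successor = c(2L, 3L, 4L, 1L),
    durations = as.data.frame(y$durations),
    emissions = list(coefficients = coefs, feature_names = y$feature_names),
    frame_rate_hz = y$frame_rate_hz
  ), class = "radar_hsmm")
}
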