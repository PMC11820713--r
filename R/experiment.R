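# End-to-end experiment orchestration: per-subject preparation, estimator
# training, beat decoding by every source, per-segment features, and the
# cross-validated blood-pressure evaluation.

BEAT_SOURCES <- c("ecg", "unet", "hsmm", "bpf")

#' Prepare a cohort for analysis
#'
#' Computes, per subject: the 125 Hz integrated spectrum, emission features
#' and four-state frame labels, the pulse wave, the ground-truth and BPF
#' baseline beats, and the fixed-length U-net inputs/labels on the
#' overlapping segment grid.
#'
#' @param cohort a `radar_cohort` from [generate_cohort()].
#' @param window_s,overlap_s segmentation grid.
#' @param unet_len network input length.
#' @return an object of class `cohort_prep` (list, one entry per subject).
#' @export
prepare_cohort <- function(cohort, window_s = 10, overlap_s = 5,
                           unet_len = 1024L) {
  structure(lapply(cohort, function(entry) {
    rec <- entry$recording; truth <- entry$truth
    fs <- rec$sampling_rate_hz
    ispec <- integrated_spectrum(rec, cfg = stft_config(step_ms = 8))
    feats <- extract_emission_features(ispec)
    labels <- hsmm_frame_labels(truth, ispec$times_s)
    pw <- pulse_wave(rec)
    duration_s <- n_samples(rec) / fs
    stride <- window_s - overlap_s
    starts <- seq(0, duration_s - window_s, by = stride)
    seg_x <- matrix(NA_real_, length(starts), unet_len)
    seg_y <- matrix(NA_integer_, length(starts), unet_len)
    seg_times <- vector("list", length(starts))
    for (k in seq_along(starts)) {
      w <- which(ispec$times_s >= starts[k] &
                   ispec$times_s < starts[k] + window_s)
      e <- ispec$energy[w]
      rng <- range(e)
      e <- if (rng[2] > rng[1]) (e - rng[1]) / (rng[2] - rng[1]) else e * 0
      seg_x[k, ] <- lin_resample(e, unet_len)
      tg <- seq(ispec$times_s[w[1L]], ispec$times_s[w[length(w)]],
                length.out = unet_len)
      seg_times[[k]] <- tg
      seg_y[k, ] <- make_labels(truth, tg)
    }
    list(subject_id = rec$subject_id, truth = truth, ispec = ispec,
         emission_features = feats, frame_labels = labels,
         pulse_wave = pw, fs = fs, duration_s = duration_s,
         seg_starts = starts, seg_x = seg_x, seg_y = seg_y,
         seg_times = seg_times,
         ecg_beats = ecg_truth_beats(truth),
         bpf_beats = bpf_baseline_beats(pw, fs))
  }), class = "cohort_prep", window_s = window_s, overlap_s = overlap_s)
}

#' Time-scale-augmented training windows for the U-net
#'
#' Draws one training window per canonical segment, with the window span
#' jittered uniformly in `span_range_s` (the fixed 1024-point input grid then
#' sees the subject's rhythm at a +/- ~25% apparent rate), normalised and
#' resampled exactly like the evaluation windows. Augmentation exposes the
#' network to time scales beyond the training subjects' own heart rates.
#'
#' @param subj one entry of a `cohort_prep`.
#' @param span_range_s window-span range in seconds.
#' @param unet_len network input length.
#' @param seed integer seed.
#' @return list with matrices `x` and `y` (windows x `unet_len`).
#' @export
augment_windows <- function(subj, span_range_s = c(8, 12.5),
                            unet_len = 1024L, seed = 1L) {
  n_win <- length(subj$seg_starts)
  ft <- subj$ispec$times_s
  with_seed(seed, {
    spans <- stats::runif(n_win, span_range_s[1], span_range_s[2])
    starts <- stats::runif(n_win, 0, pmax(0.01, subj$duration_s - spans))
    x <- matrix(NA_real_, n_win, unet_len)
    y <- matrix(NA_integer_, n_win, unet_len)
    for (k in seq_len(n_win)) {
      w <- which(ft >= starts[k] & ft < starts[k] + spans[k])
      e <- subj$ispec$energy[w]
      rng <- range(e)
      e <- if (rng[2] > rng[1]) (e - rng[1]) / (rng[2] - rng[1]) else e * 0
      x[k, ] <- lin_resample(e, unet_len)
      tg <- seq(ft[w[1L]], ft[length(w) + w[1L] - 1L], length.out = unet_len)
      y[k, ] <- make_labels(subj$truth, tg)
    }
    list(x = x, y = y)
  })
}

#' Train the HSMM and U-net estimators on a subject subset
#'
#' The U-net trains on time-scale-augmented windows (see
#' [augment_windows()]); the HSMM trains on the full frame sequences.
#'
#' @param prep a `cohort_prep`.
#' @param subjects indices (or subject ids) of the training subjects.
#' @param unet_cfg a [unet_config()]; the scaled-down config by default.
#' @param seed integer seed.
#' @param augment use time-scale augmentation for the U-net windows.
#' @return list with `hsmm` (a `radar_hsmm`) and `unet` (a `radar_unet`).
#' @export
train_estimators <- function(prep, subjects, unet_cfg = unet_config_scaled(),
                             seed = 1L, augment = TRUE) {
  idx <- .subject_idx(prep, subjects)
  hsmm <- hsmm_fit(lapply(prep[idx], `[[`, "emission_features"),
                   lapply(prep[idx], `[[`, "frame_labels"),
                   frame_rate_hz = prep[[idx[1L]]]$ispec$frame_rate_hz,
                   seed = child_seed(seed, 21L))
  if (augment) {
    aug <- lapply(seq_along(idx), function(j)
      augment_windows(prep[[idx[j]]], seed = child_seed(seed, 300L + j)))
    x <- do.call(rbind, lapply(aug, `[[`, "x"))
    y <- do.call(rbind, lapply(aug, `[[`, "y"))
  } else {
    x <- do.call(rbind, lapply(prep[idx], `[[`, "seg_x"))
    y <- do.call(rbind, lapply(prep[idx], `[[`, "seg_y"))
  }
  unet_cfg$seed <- as.integer(child_seed(seed, 22L))
  unet <- unet_fit(x, y, unet_cfg)
  list(hsmm = hsmm, unet = unet)
}

.subject_idx <- function(prep, subjects) {
  if (is.character(subjects))
    match(subjects, vapply(prep, `[[`, character(1), "subject_id"))
  else as.integer(subjects)
}

# Merge beat annotations from overlapping windows: sort by systole onset and
# drop near-duplicates (onsets closer than tol).
.merge_beats <- function(beats_list, tol_s = 0.2) {
  all_beats <- do.call(rbind, beats_list)
  if (is.null(all_beats) || nrow(all_beats) == 0L) return(empty_beats("unet"))
  all_beats <- all_beats[order(all_beats$sys_onset_s), , drop = FALSE]
  keep <- rep(TRUE, nrow(all_beats))
  last <- -Inf
  for (i in seq_len(nrow(all_beats))) {
    if (all_beats$sys_onset_s[i] - last < tol_s) keep[i] <- FALSE
    else last <- all_beats$sys_onset_s[i]
  }
  out <- all_beats[keep, , drop = FALSE]
  out$beat <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Decode one subject's beats with every source
#'
#' The U-net's per-window predictions are stitched into one subject-level
#' soft mask: every window's values are interpolated back onto the
#' integrated-spectrum frame grid and averaged where windows overlap, and
#' beats are extracted once from the stitched mask (no per-window edge
#' censoring or duplicate merging).
#'
#' @param subj one entry of a `cohort_prep`.
#' @param estimators output of [train_estimators()].
#' @return named list of beat-annotation data.frames
#'   (`ecg`, `unet`, `hsmm`, `bpf`).
#' @export
decode_subject <- function(subj, estimators) {
  hsmm_beats <- predict(estimators$hsmm, subj$ispec)
  masks <- predict(estimators$unet, subj$seg_x)
  ft <- subj$ispec$times_s
  acc <- numeric(length(ft))
  cnt <- numeric(length(ft))
  for (k in seq_along(masks)) {
    vals <- stats::approx(subj$seg_times[[k]], masks[[k]]$values, xout = ft,
                          rule = 1)$y
    ok <- !is.na(vals)
    acc[ok] <- acc[ok] + vals[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  soft <- ifelse(cnt > 0, acc / pmax(cnt, 1), 1)
  unet_beats <- withCallingHandlers(
    mask_to_beats(soft, times_s = ft),
    warning = function(w) invokeRestart("muffleWarning"))
  list(ecg = subj$ecg_beats, unet = unet_beats, hsmm = hsmm_beats,
       bpf = subj$bpf_beats)
}

#' Per-segment feature tables for one subject, all sources
#'
#' @param subj one entry of a `cohort_prep`.
#' @param beats_by_source output of [decode_subject()].
#' @param window_s,overlap_s segmentation grid.
#' @return named list of feature data.frames, one per source.
#' @export
subject_feature_tables <- function(subj, beats_by_source,
                                   window_s = 10, overlap_s = 5) {
  lapply(beats_by_source, function(beats)
    segment_feature_table(beats, subj$pulse_wave, subj$fs, subj$subject_id,
                          subj$truth, subj$duration_s, window_s, overlap_s))
}

FEATURE_COLS <- c("mean_ibi_s", "mean_systolic_s", "mean_diastolic_s",
                  "mean_pulse_width25_s")

# Drop rows with missing features or targets.
.complete_features <- function(df) {
  ok <- stats::complete.cases(df[, c(FEATURE_COLS, "sbp_mmHg", "dbp_mmHg")])
  df[ok, , drop = FALSE]
}

#' Duration-recovery experiment on held-out subjects
#'
#' Trains the HSMM and U-net on `train_subjects`, decodes the remaining
#' subjects, and evaluates per-beat IBI/systolic/diastolic errors of every
#' source against the ECG ground truth.
#'
#' @param prep a `cohort_prep`.
#' @param train_subjects indices of training subjects.
#' @param test_subjects indices of held-out subjects.
#' @param unet_cfg a [unet_config()].
#' @param seed integer seed.
#' @return list with `metrics` (data.frame: `source`, `feature`, `mae_s`,
#'   `rmse_s`, `n_matched`) and the fitted `estimators`.
#' @export
duration_experiment <- function(prep, train_subjects, test_subjects,
                                unet_cfg = unet_config_scaled(), seed = 1L) {
  est <- train_estimators(prep, train_subjects, unet_cfg, seed)
  rows <- list()
  for (s in .subject_idx(prep, test_subjects)) {
    decoded <- decode_subject(prep[[s]], est)
    for (src in BEAT_SOURCES) {
      if (nrow(decoded[[src]]) == 0L) next
      ev <- tryCatch(evaluate_durations(decoded[[src]], prep[[s]]$ecg_beats),
                     error = function(e) NULL)
      if (is.null(ev)) next   # e.g. baseline lag beyond the matching window
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject_id = prep[[s]]$subject_id, source = src),
        ev$metrics, n_matched = ev$n_matched)
    }
  }
  per_subject <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(mae_s, rmse_s) ~ source + feature,
                          data = per_subject, FUN = mean)
  nm <- stats::aggregate(n_matched ~ source + feature, data = per_subject,
                         FUN = sum)
  metrics <- merge(agg, nm)
  list(metrics = metrics, per_subject = per_subject, estimators = est)
}

#' Full cross-validated experiment
#'
#' Runs the complete protocol: estimator training, beat decoding, per-segment
#' features, and grid-searched random-forest BP regression for every beat
#' source under subject-grouped k-fold cross-validation.
#'
#' Two estimator-training protocols are supported. `"per_fold"` retrains the
#' HSMM and U-net inside every fold on that fold's training subjects (the
#' full protocol). `"holdout"` trains them once on `n_estimator_subjects`
#' dedicated subjects that are then excluded from the BP evaluation, and
#' cross-validates the regressor over the remaining subjects; this isolates
#' feature-estimation quality and keeps repeated-seed comparisons tractable.
#'
#' @param cohort a `radar_cohort`, or a prepared `cohort_prep`.
#' @param k folds for the subject-grouped CV.
#' @param seed integer seed (CV assignment, estimator and forest training).
#' @param unet_cfg a [unet_config()].
#' @param protocol `"per_fold"` or `"holdout"`.
#' @param n_estimator_subjects subjects reserved for estimator training under
#'   the holdout protocol.
#' @param grid random-forest hyperparameter grid.
#' @param window_s,overlap_s segmentation grid.
#' @return an object of class `eval_report`: `bp` (per source x target MAE,
#'   STD of absolute error, RMSE, averaged over folds), `durations` (per
#'   source x feature MAE/RMSE), `folds`, `protocol`.
#' @export
run_experiment <- function(cohort, k = 5, seed = 1L,
                           unet_cfg = unet_config_scaled(),
                           protocol = c("per_fold", "holdout"),
                           n_estimator_subjects = 4L,
                           grid = default_rf_grid(),
                           window_s = 10, overlap_s = 5) {
  protocol <- match.arg(protocol)
  prep <- if (inherits(cohort, "cohort_prep")) cohort
          else prepare_cohort(cohort, window_s, overlap_s)
  ids <- vapply(prep, `[[`, character(1), "subject_id")

  if (protocol == "holdout") {
    est_idx <- with_seed(child_seed(seed, 31L),
                         sort(sample(seq_along(prep), n_estimator_subjects)))
    eval_idx <- setdiff(seq_along(prep), est_idx)
    est <- train_estimators(prep, est_idx, unet_cfg, seed)
    # estimator subjects contribute (in-sample-decoded) TRAINING features for
    # the regressor; they never appear in a test fold
    features <- rbind(
      .collect_features(prep, eval_idx, est, window_s, overlap_s),
      .collect_features(prep, est_idx, est, window_s, overlap_s))
    plan <- grouped_kfold(ids[eval_idx], k = k, seed = child_seed(seed, 32L))
    duration_tabs <- .fold_durations(prep, eval_idx, est)
    bp_rows <- list()
    for (f in seq_len(k)) {
      test_ids <- names(plan)[plan == f]
      bp_rows[[f]] <- .fit_eval_bp(features, test_ids, grid,
                                   child_seed(seed, 40L + f),
                                   eval_ids = ids[eval_idx])
    }
  } else {
    plan <- grouped_kfold(ids, k = k, seed = child_seed(seed, 32L))
    bp_rows <- list()
    duration_rows <- list()
    for (f in seq_len(k)) {
      test_ids <- names(plan)[plan == f]
      train_idx <- which(!(ids %in% test_ids))
      test_idx <- which(ids %in% test_ids)
      stopifnot(length(intersect(train_idx, test_idx)) == 0L)
      est <- train_estimators(prep, train_idx, unet_cfg,
                              child_seed(seed, 50L + f))
      features <- .collect_features(prep, c(train_idx, test_idx), est,
                                    window_s, overlap_s)
      bp_rows[[f]] <- .fit_eval_bp(features, test_ids, grid,
                                   child_seed(seed, 40L + f))
      duration_rows[[f]] <- .fold_durations(prep, test_idx, est)
    }
    duration_tabs <- do.call(rbind, duration_rows)
  }

  bp_all <- do.call(rbind, bp_rows)
  bp <- stats::aggregate(cbind(mae, std, rmse) ~ source + target,
                         data = bp_all, FUN = mean)
  durations <- stats::aggregate(cbind(mae_s, rmse_s) ~ source + feature,
                                data = duration_tabs, FUN = mean)
  structure(list(bp = bp, durations = durations, bp_by_fold = bp_all,
                 folds = plan, protocol = protocol, k = k, seed = seed),
            class = "eval_report")
}

# Per-segment features for the given subjects, all sources, as one table.
.collect_features <- function(prep, idx, est, window_s, overlap_s) {
  tabs <- list()
  for (s in idx) {
    decoded <- decode_subject(prep[[s]], est)
    ft <- subject_feature_tables(prep[[s]], decoded, window_s, overlap_s)
    for (src in names(ft)) {
      if (is.null(ft[[src]])) next
      tabs[[length(tabs) + 1L]] <- cbind(source = src, ft[[src]])
    }
  }
  .complete_features(do.call(rbind, tabs))
}

# Duration metrics for the given subjects (vs ECG truth), averaged later.
.fold_durations <- function(prep, idx, est) {
  rows <- list()
  for (s in idx) {
    decoded <- decode_subject(prep[[s]], est)
    for (src in BEAT_SOURCES) {
      if (nrow(decoded[[src]]) == 0L) next
      ev <- tryCatch(evaluate_durations(decoded[[src]], prep[[s]]$ecg_beats),
                     error = function(e) NULL)
      if (is.null(ev)) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(source = src), ev$metrics)
    }
  }
  do.call(rbind, rows)
}

# Train RF per source/target on all non-test subjects in `features`,
# evaluate on the test subjects.
.fit_eval_bp <- function(features, test_ids, grid, seed, eval_ids = NULL) {
  rows <- list()
  for (src in unique(features$source)) {
    fsrc <- features[features$source == src, , drop = FALSE]
    tr <- !(fsrc$subject_id %in% test_ids)
    if (!is.null(eval_ids))    # test rows only from evaluation subjects
      fsrc <- fsrc[tr | fsrc$subject_id %in% eval_ids, , drop = FALSE]
    tr <- !(fsrc$subject_id %in% test_ids)
    if (sum(tr) < 20L || sum(!tr) == 0L) next
    for (target in c("sbp", "dbp")) {
      ycol <- paste0(target, "_mmHg")
      fit <- bp_fit(fsrc[tr, FEATURE_COLS], fsrc[[ycol]][tr],
                    fsrc$subject_id[tr], grid = grid, seed = seed)
      pred <- predict(fit, fsrc[!tr, FEATURE_COLS])
      m <- evaluate_bp(pred, fsrc[[ycol]][!tr])
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, target = target, mae = m["mae"], std = m["std"],
        rmse = m["rmse"], n_test = sum(!tr))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold subject-grouped CV (%s protocol)\n",
              x$k, x$protocol))
  cat("\nBlood pressure (mmHg, averaged over folds):\n")
  b <- x$bp
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-5s %s: MAE %5.2f +/- %5.2f, RMSE %5.2f\n",
                toupper(b$target[i]), format(b$source[i], width = 5),
                b$mae[i], b$std[i], b$rmse[i]))
  cat("\nCardiac durations vs ECG (s):\n")
  d <- x$durations
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-9s %s: MAE %.4f, RMSE %.4f\n", d$feature[i],
                format(d$source[i], width = 5), d$mae_s[i], d$rmse_s[i]))
  invisible(x)
}
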