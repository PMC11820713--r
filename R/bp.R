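# Random-forest blood-pressure regression with grid search, subject-grouped
# cross-validation, and error metrics for BP and cardiac durations.

#' Subject-grouped k-fold assignment
#'
#' Partitions subjects (not segments) into `k` folds as evenly as possible so
#' that no subject's segments ever span a train/test boundary.
#'
#' @param subject_ids character vector (one entry per segment, or the unique
#'   subjects themselves).
#' @param k number of folds.
#' @param seed integer seed for the subject shuffle.
#' @return an object of class `cv_plan`: named integer vector mapping each
#'   subject to a fold in `1..k`.
#' @export
grouped_kfold <- function(subject_ids, k = 5, seed = 1L) {
  subjects <- sort(unique(as.character(subject_ids)))
  if (length(subjects) < k)
    stop(sprintf("need at least %d distinct subjects, got %d", k,
                 length(subjects)), call. = FALSE)
  shuffled <- with_seed(seed, sample(subjects))
  fold <- stats::setNames(rep_len(seq_len(k), length(subjects)), shuffled)
  structure(fold[subjects], class = "cv_plan", k = k)
}

#' Default random-forest hyperparameter grid
#' @return data.frame over `num_trees` (100/300/500), `max_depth`
#'   (0 = unlimited, 5, 10) and `min_node` (1, 5).
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(100L, 300L, 500L),
              max_depth = c(0L, 5L, 10L),
              min_node = c(1L, 5L))
}

.fit_ranger <- function(x, y, p, seed) {
  ranger::ranger(x = x, y = y, num.trees = p$num_trees,
                 max.depth = p$max_depth, min.node.size = p$min_node,
                 seed = seed, num.threads = 1L)
}

#' Fit a grid-searched random-forest BP regressor
#'
#' Selects hyperparameters by subject-grouped inner cross-validation MAE on
#' the training segments only, then refits on all training data.
#'
#' @param x numeric feature matrix (segments x features).
#' @param y numeric target (mmHg).
#' @param subject_ids subject of each training segment (guards the inner CV
#'   against leakage).
#' @param grid hyperparameter grid (see [default_rf_grid()]).
#' @param inner_k inner CV folds.
#' @param seed integer seed.
#' @return an object of class `radar_bp` with the fitted forest and the
#'   chosen hyperparameters.
#' @export
bp_fit <- function(x, y, subject_ids, grid = default_rf_grid(),
                   inner_k = 3L, seed = 1L) {
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  x <- as.matrix(x)
  if (nrow(x) < 20L) stop("need at least 20 training segments", call. = FALSE)
  inner <- grouped_kfold(subject_ids, k = min(inner_k, length(unique(subject_ids))),
                         seed = child_seed(seed, 2L))
  fold_of <- inner[as.character(subject_ids)]
  cv_mae <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- numeric(0)
    for (f in seq_len(attr(inner, "k"))) {
      tr <- fold_of != f
      if (!any(tr) || all(tr)) next
      fit <- .fit_ranger(x[tr, , drop = FALSE], y[tr], grid[g, ],
                         seed = child_seed(seed, 10L + f))
      pred <- stats::predict(fit, data = x[!tr, , drop = FALSE])$predictions
      errs <- c(errs, abs(pred - y[!tr]))
    }
    cv_mae[g] <- mean(errs)
  }
  best <- which.min(cv_mae)   # ties resolve to the first (smallest) config
  model <- .fit_ranger(x, y, grid[best, ], seed = child_seed(seed, 1L))
  structure(list(model = model, chosen = grid[best, ],
                 cv_mae = cv_mae, grid = grid,
                 feature_names = colnames(x)), class = "radar_bp")
}

#' @export
print.radar_bp <- function(x, ...) {
  cat("<radar_bp> random-forest BP regressor\n")
  cat(sprintf("  chosen: %d trees, max depth %s, min node %d (inner-CV MAE %.3f mmHg)\n",
              x$chosen$num_trees,
              ifelse(x$chosen$max_depth == 0, "unlimited", x$chosen$max_depth),
              x$chosen$min_node, min(x$cv_mae)))
  invisible(x)
}

#' @export
predict.radar_bp <- function(object, newdata, ...) {
  stats::predict(object$model,
                 data = as.matrix(newdata)[, object$feature_names,
                                           drop = FALSE])$predictions
}

#' Blood-pressure error metrics
#'
#' MAE, the standard deviation of the absolute errors (the "MAE +/- STD"
#' convention), and RMSE.
#'
#' @param predictions,truth aligned numeric vectors (mmHg).
#' @return named numeric vector `c(mae, std, rmse)`.
#' @export
evaluate_bp <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("length mismatch between predictions and truth", call. = FALSE)
  e <- abs(predictions - truth)
  c(mae = mean(e), std = stats::sd(e), rmse = sqrt(mean(e^2)))
}

#' Duration errors of estimated beats against reference beats
#'
#' Beats are matched one-to-one by nearest systole onset within
#' `tol_s`; unmatched estimated beats are reported as insertions and
#' unmatched reference beats as deletions. Errors are computed on matched
#' pairs only.
#'
#' @param est,ref beat-annotation data.frames.
#' @param tol_s matching tolerance on the systole onset (seconds).
#' @return list with a `metrics` data.frame (`feature`, `mae_s`, `rmse_s`),
#'   `n_matched`, `n_insertions`, `n_deletions`.
#' @export
evaluate_durations <- function(est, ref, tol_s = 0.4) {
  if (nrow(est) == 0L || nrow(ref) == 0L)
    stop("no beats to evaluate", call. = FALSE)
  used <- logical(nrow(ref))
  pairs <- matrix(integer(0), ncol = 2L)
  for (i in order(est$sys_onset_s)) {
    d <- abs(ref$sys_onset_s - est$sys_onset_s[i])
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol_s) { used[j] <- TRUE; pairs <- rbind(pairs, c(i, j)) }
  }
  if (nrow(pairs) == 0L) stop("zero matched beats", call. = FALSE)
  feats <- c(ibi = "ibi_s", systolic = "systolic_s", diastolic = "diastolic_s")
  metrics <- do.call(rbind, lapply(names(feats), function(f) {
    err <- est[[feats[f]]][pairs[, 1L]] - ref[[feats[f]]][pairs[, 2L]]
    data.frame(feature = f, mae_s = mean(abs(err)), rmse_s = sqrt(mean(err^2)))
  }))
  list(metrics = metrics, n_matched = nrow(pairs),
       n_insertions = nrow(est) - nrow(pairs),
       n_deletions = nrow(ref) - nrow(pairs))
}
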