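# Beat annotations from the different sources (ECG truth, BPF baseline) and
# per-segment feature aggregation.

empty_beats <- function(source) {
  data.frame(beat = integer(0), sys_onset_s = numeric(0),
             dia_onset_s = numeric(0), next_sys_onset_s = numeric(0),
             systolic_s = numeric(0), diastolic_s = numeric(0),
             ibi_s = numeric(0), source = character(0))
}

#' Beat annotations from ECG ground truth
#'
#' Systole runs from each R peak to the T-wave end, diastole from the T-wave
#' end to the next R peak.
#'
#' @param truth a `ground_truth`.
#' @return data.frame with one row per complete beat: `beat`, `sys_onset_s`,
#'   `dia_onset_s`, `next_sys_onset_s`, `systolic_s`, `diastolic_s`, `ibi_s`,
#'   `source = "ecg"`.
#' @export
ecg_truth_beats <- function(truth) {
  pb <- truth$per_beat
  data.frame(beat = pb$beat,
             sys_onset_s = pb$r_peak_s,
             dia_onset_s = pb$t_end_s,
             next_sys_onset_s = pb$r_peak_s + pb$ibi_s,
             systolic_s = pb$systolic_s,
             diastolic_s = pb$diastolic_s,
             ibi_s = pb$ibi_s,
             source = "ecg")
}

#' Conventional band-pass-filter baseline beats
#'
#' The filter-based convention treats the falling interval of the 0.5-2 Hz
#' pulse wave (local maximum to the next local minimum) as systole and the
#' rising interval as diastole; the IBI is the maximum-to-maximum interval.
#' Peaks are picked with a minimum separation of 0.3 s and a prominence of at
#' least 0.2 x the signal's interquartile range.
#'
#' @param pw pulse-wave sequence (from [pulse_wave()]).
#' @param fs sampling rate of `pw` in Hz.
#' @param start_time_s time of the first sample.
#' @return beat-annotation data.frame with `source = "bpf"`.
#' @export
bpf_baseline_beats <- function(pw, fs, start_time_s = 0) {
  min_dist <- max(1L, round(0.3 * fs))
  prom <- 0.2 * stats::IQR(pw)
  pk <- find_peaks(pw, min_dist = min_dist, min_prom = prom)
  if (length(pk) < 2L) {
    warning("no pulse-wave peaks found")
    return(empty_beats("bpf"))
  }
  beats <- empty_beats("bpf")
  t <- start_time_s + (seq_along(pw) - 1L) / fs
  for (k in seq_len(length(pk) - 1L)) {
    seg <- pk[k]:pk[k + 1L]
    trough <- seg[which.min(pw[seg])]
    if (trough <= pk[k] || trough >= pk[k + 1L]) next
    beats <- rbind(beats, data.frame(
      beat = nrow(beats) + 1L,
      sys_onset_s = t[pk[k]],
      dia_onset_s = t[trough],
      next_sys_onset_s = t[pk[k + 1L]],
      systolic_s = t[trough] - t[pk[k]],
      diastolic_s = t[pk[k + 1L]] - t[trough],
      ibi_s = t[pk[k + 1L]] - t[pk[k]],
      source = "bpf"))
  }
  beats
}

#' Pulse-wave width at 25% of the beat's peak amplitude
#'
#' For each beat window the pulse peak is located, the baseline is the
#' window minimum, and the width is the time between the two crossings of
#' `baseline + 0.25 * (peak - baseline)` bracketing the peak, linearly
#' interpolated between samples.
#'
#' @param pw pulse-wave sequence.
#' @param beats beat-annotation data.frame (windows `sys_onset_s` to
#'   `next_sys_onset_s`).
#' @param fs sampling rate of `pw` in Hz.
#' @param start_time_s time of the first sample of `pw`.
#' @return numeric vector of widths in seconds, one per beat (`NA` where the
#'   level is never crossed).
#' @export
pulse_width_25 <- function(pw, beats, fs, start_time_s = 0) {
  n <- length(pw)
  t <- function(i) start_time_s + (i - 1L) / fs
  vapply(seq_len(nrow(beats)), function(k) {
    i0 <- max(1L, ceiling((beats$sys_onset_s[k] - start_time_s) * fs) + 1L)
    i1 <- min(n, floor((beats$next_sys_onset_s[k] - start_time_s) * fs))
    if (i1 - i0 < 2L) return(NA_real_)
    w <- i0:i1
    seg <- pw[w]
    pk <- which.max(seg)
    base <- min(seg)
    level <- base + 0.25 * (max(seg) - base)
    if (max(seg) <= base) return(NA_real_)
    # walk left from the peak to the crossing
    l <- pk
    while (l > 1L && seg[l - 1L] >= level) l <- l - 1L
    t_left <- if (l == 1L) t(w[1L]) else {
      f <- (level - seg[l - 1L]) / (seg[l] - seg[l - 1L])
      t(w[l - 1L]) + f / fs
    }
    r <- pk
    while (r < length(seg) && seg[r + 1L] >= level) r <- r + 1L
    t_right <- if (r == length(seg)) t(w[length(seg)]) else {
      f <- (seg[r] - level) / (seg[r] - seg[r + 1L])
      t(w[r]) + f / fs
    }
    t_right - t_left
  }, numeric(1))
}

#' Aggregate beats into per-segment features
#'
#' Arithmetic means over the beats fully inside the segment window, plus the
#' blood-pressure targets.
#'
#' @param beats beat-annotation data.frame.
#' @param widths per-beat 25%-widths aligned with `beats` (or `NULL`).
#' @param start_s,end_s segment window in seconds.
#' @param sbp_mmHg,dbp_mmHg segment BP targets (scalars, may be `NA`).
#' @return one-row data.frame of segment features, or `NULL` (with a warning)
#'   if the segment contains no complete beat.
#' @export
aggregate_segment <- function(beats, widths = NULL, start_s, end_s,
                              sbp_mmHg = NA_real_, dbp_mmHg = NA_real_) {
  inside <- beats$sys_onset_s >= start_s & beats$next_sys_onset_s <= end_s
  if (!any(inside)) {
    warning("segment contains no complete beat; skipped")
    return(NULL)
  }
  mw <- if (is.null(widths)) NA_real_ else mean(widths[inside], na.rm = TRUE)
  data.frame(
    n_beats = sum(inside),
    mean_ibi_s = mean(beats$ibi_s[inside]),
    mean_systolic_s = mean(beats$systolic_s[inside]),
    mean_diastolic_s = mean(beats$diastolic_s[inside]),
    mean_pulse_width25_s = mw,
    sbp_mmHg = sbp_mmHg,
    dbp_mmHg = dbp_mmHg
  )
}

#' Per-segment feature table for one recording and one beat source
#'
#' Slides the canonical `window_s`/`overlap_s` grid over the recording and
#' aggregates the supplied beats (and pulse-wave widths) per window; BP
#' targets are taken from the ground truth's per-segment table when provided.
#'
#' @param beats beat-annotation data.frame (absolute times).
#' @param pw pulse-wave sequence for the 25%-width feature.
#' @param fs sampling rate of `pw`.
#' @param subject_id subject identifier.
#' @param truth optional `ground_truth` carrying `per_segment_bp`.
#' @param duration_s recording length in seconds.
#' @param window_s,overlap_s segmentation grid.
#' @return data.frame of segment features (possibly zero rows).
#' @export
segment_feature_table <- function(beats, pw, fs, subject_id, truth = NULL,
                                  duration_s, window_s = 10, overlap_s = 5) {
  widths <- pulse_width_25(pw, beats, fs)
  stride <- window_s - overlap_s
  starts <- seq(0, duration_s - window_s, by = stride)
  bp <- if (!is.null(truth)) truth$per_segment_bp else NULL
  rows <- list()
  for (k in seq_along(starts)) {
    sbp <- if (!is.null(bp)) bp$sbp_mmHg[k] else NA_real_
    dbp <- if (!is.null(bp)) bp$dbp_mmHg[k] else NA_real_
    row <- withCallingHandlers(
      aggregate_segment(beats, widths, starts[k], starts[k] + window_s,
                        sbp, dbp),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(row)) next
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(subject_id = subject_id, segment_index = k,
                 start_s = starts[k]), row)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
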