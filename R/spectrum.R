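# Short-time Fourier transform and band-energy integration: the integrated
# spectrum is the method's core observable.

#' STFT configuration
#'
#' Defaults follow the analysis convention for 1 kHz chest-vibration signals:
#' a 256 ms window (shorter than any plausible interbeat interval, so each
#' frame sees at most one burst) and a 1 ms step for maximal temporal
#' resolution. The FFT is zero-padded to `fft_length` for smoother band sums.
#'
#' @param window_ms analysis window length in milliseconds.
#' @param step_ms hop between consecutive frames in milliseconds.
#' @param window_function `"hann"` (default) or `"rect"`.
#' @param fft_length FFT size; frames are zero-padded up to this length.
#' @return an object of class `stft_config`.
#' @export
stft_config <- function(window_ms = 256, step_ms = 1,
                        window_function = "hann", fft_length = 1024) {
  if (step_ms > window_ms) stop("'step_ms' must not exceed 'window_ms'",
                                call. = FALSE)
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 window_function = match.arg(window_function, c("hann", "rect")),
                 fft_length = fft_length), class = "stft_config")
}

.stft_window <- function(name, n) {
  switch(name,
         hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
         rect = rep(1, n))
}

# Core frame loop. Calls `consume(power_chunk, frame_idx)` with a time x freq
# power block per chunk; power is folded one-sided and scaled so that with a
# rectangular window the row sum equals the frame energy (Parseval).
.stft_apply <- function(x, fs, cfg, consume, chunk_frames = 4096L) {
  wlen <- round(cfg$window_ms / 1000 * fs)
  step <- max(1L, round(cfg$step_ms / 1000 * fs))
  n <- length(x)
  if (n < wlen) stop("signal shorter than one STFT window", call. = FALSE)
  nfft <- max(cfg$fft_length, wlen)
  win <- .stft_window(cfg$window_function, wlen)
  starts <- seq(1L, n - wlen + 1L, by = step)
  nh <- nfft %/% 2L + 1L
  fold_src <- nfft + 2L - (2L:(nfft %/% 2L))
  for (c0 in seq(1L, length(starts), by = chunk_frames)) {
    c1 <- min(length(starts), c0 + chunk_frames - 1L)
    st <- starts[c0:c1]
    idx <- outer(0L:(wlen - 1L), st, `+`)
    fr <- matrix(x[idx], nrow = wlen) * win
    if (nfft > wlen)
      fr <- rbind(fr, matrix(0, nfft - wlen, ncol(fr)))
    X <- stats::mvfft(fr)
    p <- (Mod(X))^2 / nfft
    folded <- p[1L:nh, , drop = FALSE]
    folded[2L:(nh - 1L), ] <- folded[2L:(nh - 1L), , drop = FALSE] +
      p[fold_src, , drop = FALSE]
    consume(t(folded), c0:c1)
  }
  list(times_s = (starts - 1L) / fs + wlen / (2 * fs),
       freqs_hz = (seq_len(nh) - 1L) * fs / nfft,
       n_frames = length(starts),
       frame_rate_hz = fs / step)
}

#' Short-time Fourier transform
#'
#' Frame `t` covers `[t, t + window)`; the reported `times_s` are frame
#' centres. Power is the squared magnitude of the windowed (zero-padded) FFT,
#' folded to a one-sided `0..fs/2` axis so that the per-frame sum over all
#' frequencies equals the frame energy when a rectangular window is used
#' (Parseval). Real and complex inputs are both supported; for complex inputs
#' the folded axis accumulates the positive- and negative-frequency power.
#'
#' @param x real or complex sequence.
#' @param fs sampling rate in Hz.
#' @param cfg an [stft_config()].
#' @return an object of class `spectrogram` with `times_s`, `freqs_hz` and a
#'   `power` matrix (time x frequency).
#' @export
stft <- function(x, fs, cfg = stft_config()) {
  power <- NULL
  meta <- .stft_apply(x, fs, cfg, function(block, idx) {
    if (is.null(power)) power <<- matrix(0, 0L, ncol(block))
    power <<- rbind(power, block)
  })
  structure(list(times_s = meta$times_s, freqs_hz = meta$freqs_hz,
                 power = power, frame_rate_hz = meta$frame_rate_hz),
            class = "spectrogram")
}

#' Integrate spectrogram energy over a frequency band
#'
#' Sums power over all frequency bins inside `band_hz` (inclusive) at each
#' frame, producing the integrated-spectrum waveform whose per-beat peak pair
#' marks the systole and diastole onset vibrations.
#'
#' @param spec a `spectrogram`.
#' @param band_hz numeric `(low, high)` in Hz.
#' @return an object of class `integrated_spectrum` with `times_s`, `energy`,
#'   `band_hz` and `frame_rate_hz`.
#' @export
integrate_spectrum <- function(spec, band_hz = c(5, 30)) {
  sel <- spec$freqs_hz >= band_hz[1] - 1e-9 & spec$freqs_hz <= band_hz[2] + 1e-9
  if (!any(sel)) stop("integration band contains no frequency bins",
                      call. = FALSE)
  structure(list(times_s = spec$times_s,
                 energy = rowSums(spec$power[, sel, drop = FALSE]),
                 band_hz = band_hz,
                 frame_rate_hz = spec$frame_rate_hz),
            class = "integrated_spectrum")
}

#' Integrated spectrum of a recording (memory-bounded pipeline)
#'
#' Band-passes I and Q to `filter_band`, forms the complex signal, and
#' integrates STFT energy over `integrate_band` chunk by chunk without
#' materialising the full spectrogram. With `step_ms = 8` the frame rate is
#' 125 Hz, aligned with the down-sampled label grid (identical to computing
#' frames at a 1 ms step and keeping every 8th).
#'
#' @param rec a `recording` or `segment`.
#' @param filter_band [filter_spec()] for the pre-STFT band-pass.
#' @param integrate_band numeric `(low, high)` integration band in Hz.
#' @param cfg an [stft_config()].
#' @return an `integrated_spectrum`.
#' @export
integrated_spectrum <- function(rec, filter_band = filter_spec(8, 30),
                                integrate_band = c(5, 30),
                                cfg = stft_config(step_ms = 8)) {
  fs <- rec$sampling_rate_hz
  s <- to_complex(bandpass(rec$channels$i, filter_band, fs),
                  bandpass(rec$channels$q, filter_band, fs))
  nfft <- max(cfg$fft_length, round(cfg$window_ms / 1000 * fs))
  freqs <- (seq_len(nfft %/% 2L + 1L) - 1L) * fs / nfft
  sel <- freqs >= integrate_band[1] - 1e-9 & freqs <= integrate_band[2] + 1e-9
  if (!any(sel)) stop("integration band contains no frequency bins",
                      call. = FALSE)
  energy <- numeric(0)
  meta <- .stft_apply(s, fs, cfg, function(block, idx) {
    energy <<- c(energy, rowSums(block[, sel, drop = FALSE]))
  }, chunk_frames = 4096L)
  structure(list(times_s = meta$times_s + (rec$start_time_s %||% 0),
                 energy = energy,
                 band_hz = integrate_band,
                 frame_rate_hz = meta$frame_rate_hz),
            class = "integrated_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Min-max normalise an integrated spectrum to [0, 1]
#'
#' Constant input maps to all zeros. The scaling is invariant to multiplying
#' the energy by any positive constant.
#'
#' @param ispec an `integrated_spectrum`.
#' @return the normalised `integrated_spectrum`.
#' @export
normalize_integrated <- function(ispec) {
  e <- ispec$energy
  rng <- range(e)
  ispec$energy <- if (rng[2] > rng[1]) (e - rng[1]) / (rng[2] - rng[1])
                  else numeric(length(e))
  ispec
}

#' Resample a sequence to a fixed length by linear interpolation
#'
#' Used to map the variable-length per-segment integrated spectrum onto the
#' fixed 1024-point network input grid; endpoints are preserved.
#'
#' @param x numeric vector or `integrated_spectrum`.
#' @param target_len output length.
#' @return numeric vector of length `target_len`.
#' @export
resample_to_length <- function(x, target_len = 1024L) {
  v <- if (inherits(x, "integrated_spectrum")) x$energy else x
  lin_resample(v, target_len)
}

#' @export
print.integrated_spectrum <- function(x, ...) {
  cat(sprintf("<integrated_spectrum> %d frames @ %g Hz, band [%g, %g] Hz\n",
              length(x$energy), x$frame_rate_hz, x$band_hz[1], x$band_hz[2]))
  invisible(x)
}

#' Plot an integrated spectrum
#' @param x an `integrated_spectrum`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.integrated_spectrum <- function(x, ...) {
  graphics::plot(x$times_s, x$energy, type = "l", xlab = "time (s)",
                 ylab = "band energy", ...)
  invisible(x)
}

# Simple local-maxima finder used by alignment checks and the BPF baseline.
# Returns indices of strict local maxima separated by at least min_dist
# samples, keeping the larger peak on conflicts; peaks below min_prom
# prominence are dropped.
find_peaks <- function(x, min_dist = 1L, min_prom = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  if (min_prom > 0) {
    prom <- vapply(cand, function(p) {
      l <- p; lmin <- x[p]
      while (l > 1L && x[l] <= x[p]) { l <- l - 1L; lmin <- min(lmin, x[l]) }
      r <- p; rmin <- x[p]
      while (r < n && x[r] <= x[p]) { r <- r + 1L; rmin <- min(rmin, x[r]) }
      x[p] - max(lmin, rmin)
    }, numeric(1))
    cand <- cand[prom >= min_prom]
  }
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand])]
  keep <- logical(0)
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  sort(kept)
}

#' Per-beat alignment of integrated-spectrum peaks with burst centres
#'
#' For each complete beat, finds the two largest local maxima of the
#' integrated spectrum inside the beat window and measures their distance to
#' the systole- and diastole-onset burst centres (`onset + burst_duration/2`).
#'
#' @param ispec an `integrated_spectrum`.
#' @param truth a `ground_truth`.
#' @param tol_s alignment tolerance in seconds.
#' @return list with `fraction_aligned` (beats whose two peaks both fall
#'   within `tol_s`), `n_beats`, and the per-beat absolute offsets.
#' @export
two_peak_alignment <- function(ispec, truth, tol_s = 0.03) {
  pb <- truth$per_beat
  dur <- truth$physiology$burst_duration_s
  dur_t <- dur * truth$physiology$t_burst_duration_scale
  aligned <- logical(0)
  off1 <- off2 <- numeric(0)
  for (b in seq_len(nrow(pb))) {
    w <- ispec$times_s >= pb$r_peak_s[b] &
      ispec$times_s < pb$r_peak_s[b] + pb$ibi_s[b] - 0.01
    if (sum(w) < 5L) next
    e <- ispec$energy[w]; tt <- ispec$times_s[w]
    pk <- find_peaks(e, min_dist = max(2L, round(0.1 * ispec$frame_rate_hz)))
    if (length(pk) < 2L) { aligned <- c(aligned, FALSE); next }
    top2 <- sort(tt[pk[order(-e[pk])][1:2]])
    c_sys <- pb$r_peak_s[b] + dur / 2
    c_dia <- pb$t_end_s[b] + dur_t / 2
    o1 <- abs(top2[1] - c_sys); o2 <- abs(top2[2] - c_dia)
    off1 <- c(off1, o1); off2 <- c(off2, o2)
    aligned <- c(aligned, o1 <= tol_s && o2 <= tol_s)
  }
  list(fraction_aligned = mean(aligned), n_beats = length(aligned),
       systole_offsets_s = off1, diastole_offsets_s = off2)
}
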