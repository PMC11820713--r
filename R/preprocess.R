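# Band-pass filtering at the three analysis bands, complex-signal formation
# and arctangent phase demodulation.

#' Band-pass filter specification
#'
#' Butterworth band-pass applied forward-backward by default (zero phase, so
#' no timing bias enters the duration estimates). The three canonical bands
#' are `[8, 30]` Hz (cardiac vibration band), `[0.5, 2]` Hz (pulse wave) and
#' `[0.24, 31.25]` Hz (ECG conditioning).
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order (per pass).
#' @param zero_phase apply forward-backward (`filtfilt`) if `TRUE`.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz, high_hz, order = 4, zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz)
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Default analysis bands
#' @return named list of [filter_spec()] objects: `high` = 8-30 Hz,
#'   `pulse` = 0.5-2 Hz, `ecg` = 0.24-31.25 Hz.
#' @export
default_bands <- function() {
  list(high = filter_spec(8, 30),
       pulse = filter_spec(0.5, 2),
       ecg = filter_spec(0.24, 31.25))
}

#' Apply a band-pass filter
#'
#' @param x real input sequence.
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @return filtered sequence, same length as `x`.
#' @export
bandpass <- function(x, spec, fs) {
  if (spec$high_hz >= fs / 2)
    stop("band edge at or above Nyquist", call. = FALSE)
  # realized as a high-pass/low-pass cascade: a direct narrow band-pass at
  # low normalized frequency is numerically unstable in double precision
  hp <- signal::butter(spec$order, spec$low_hz / (fs / 2), type = "high")
  lp <- signal::butter(spec$order, spec$high_hz / (fs / 2), type = "low")
  if (spec$zero_phase)
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  else as.numeric(signal::filter(lp, signal::filter(hp, x)))
}

#' Combine I and Q into the complex baseband signal
#'
#' @param i,q equal-length real sequences.
#' @return complex vector `i + 1i * q`.
#' @export
to_complex <- function(i, q) {
  if (length(i) != length(q))
    stop("I and Q must have equal length", call. = FALSE)
  complex(real = i, imaginary = q)
}

#' Arctangent phase demodulation
#'
#' Unwrapped phase angle of `I + jQ`; multiplied by `lambda / (4*pi)` this
#' recovers chest displacement up to an additive constant.
#'
#' @param i,q equal-length real sequences.
#' @return unwrapped phase in radians.
#' @export
demodulate_phase <- function(i, q) {
  signal::unwrap(Arg(to_complex(i, q)))
}

#' Conventional pulse-wave signal
#'
#' The baseline 1-D reduction used by filter-based methods: the unwrapped
#' phase of the complex signal, band-passed to `[0.5, 2]` Hz. Its falling and
#' rising intervals are the conventional proxies for systole and diastole.
#'
#' @param rec a `recording` (or any list with `channels$i`, `channels$q`,
#'   `sampling_rate_hz`).
#' @param band a [filter_spec()]; defaults to 0.5-2 Hz.
#' @return real sequence (radians, band-passed), same length as the channels.
#' @export
pulse_wave <- function(rec, band = filter_spec(0.5, 2)) {
  ph <- demodulate_phase(rec$channels$i, rec$channels$q)
  bandpass(ph, band, rec$sampling_rate_hz)
}
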