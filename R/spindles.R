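# Automated sleep-spindle detection: 10-15 Hz band filtering, 750-ms RMS
# smoothing, cubing, and dual mean-relative thresholds with a strict
# 0.5-10 s duration gate.

#' Spindle-detection parameters
#'
#' The published procedure applies a 10-15 Hz bandpass and, in cascade, a
#' Butterworth band filter designed to a 3 Hz first stopband, 10 Hz first
#' passband, 15 Hz second passband, 22 Hz second stopband and 24 dB
#' attenuation; the cascade is kept literal even though it is partially
#' redundant.  The smoothed trace is cubed and a spindle is a maximal
#' interval above `lower_mult` times the mean cubed envelope whose peak
#' exceeds `upper_mult` times that mean, lasting strictly more than
#' `min_dur_s` and strictly less than `max_dur_s` seconds.
#'
#' @param band_hz Bandpass edges in Hz (default `c(10, 15)`).
#' @param stop_hz Stopband edges of the Butterworth design (default
#'   `c(3, 22)`).
#' @param atten_db Stopband attenuation for the design (default 24 dB).
#' @param ripple_db Passband ripple allowance used when solving for the
#'   design order (default 3 dB).
#' @param rms_window_ms RMS smoothing window (default 750 ms).
#' @param lower_mult,upper_mult Start/end and peak thresholds as multiples
#'   of the mean cubed envelope (defaults 1.2 and 3.5).
#' @param min_dur_s,max_dur_s Strict duration gate (defaults 0.5 and 10 s).
#' @param baseline `"global"` (default) computes the threshold baseline as
#'   the mean cubed envelope over the whole trace supplied.
#' @export
spindle_params <- function(band_hz = c(10, 15), stop_hz = c(3, 22),
                           atten_db = 24, ripple_db = 3,
                           rms_window_ms = 750,
                           lower_mult = 1.2, upper_mult = 3.5,
                           min_dur_s = 0.5, max_dur_s = 10,
                           baseline = "global") {
  if (lower_mult <= 0 || upper_mult <= lower_mult)
    stop("need 0 < lower_mult < upper_mult", call. = FALSE)
  if (min_dur_s <= 0 || max_dur_s <= min_dur_s)
    stop("need 0 < min_dur_s < max_dur_s", call. = FALSE)
  structure(list(band_hz = band_hz, stop_hz = stop_hz, atten_db = atten_db,
                 ripple_db = ripple_db, rms_window_ms = rms_window_ms,
                 lower_mult = lower_mult, upper_mult = upper_mult,
                 min_dur_s = min_dur_s, max_dur_s = max_dur_s,
                 baseline = baseline),
            class = "spindle_params")
}

#' Spindle band filtering
#'
#' Zero-phase cascade of a 4th-order 10-15 Hz Butterworth bandpass and the
#' stopband-specified Butterworth band design (order solved from the
#' attenuation requirement).  Length-preserving.
#'
#' @param eeg Numeric EEG trace.
#' @param fs Sampling rate in Hz (must exceed twice the upper stopband).
#' @param params A [spindle_params()].
#' @return Filtered trace.
#' @export
spindle_band_filter <- function(eeg, fs, params = spindle_params()) {
  if (fs <= 2 * params$stop_hz[2])
    stop("sampling rate too low for the spindle filter design", call. = FALSE)
  bp <- butter_design(4, params$band_hz, fs, "pass")
  n_spec <- butter_order_bandpass(params$band_hz, params$stop_hz,
                                  params$ripple_db, params$atten_db, fs)
  spec <- butter_design(n_spec, params$band_hz, fs, "pass")
  zero_phase_filter(spec, zero_phase_filter(bp, eeg))
}

#' Cube a non-negative envelope
#'
#' Pointwise third power; order-preserving, and it amplifies the ratio of
#' burst to background (signal-to-noise) for any envelope whose burst mean
#' exceeds its background mean.
#'
#' @param envelope Non-negative numeric vector.
#' @export
cube_signal <- function(envelope) {
  if (any(envelope < 0)) stop("envelope must be non-negative", call. = FALSE)
  envelope^3
}

#' Detect spindles on a cubed envelope
#'
#' Thresholds are `lower_mult` and `upper_mult` times the global mean of
#' the cubed envelope.  A candidate is a maximal interval strictly above
#' the lower threshold; it is retained iff its maximum exceeds the upper
#' threshold and its duration lies strictly between `min_dur_s` and
#' `max_dur_s`.  The peak is the argmax within the interval.
#'
#' @param cubed_envelope From [cube_signal()] of [rms_envelope()].
#' @param fs Sampling rate in Hz.
#' @param params A [spindle_params()].
#' @return Data frame: `start_s`, `end_s`, `peak_s`, `duration_s`.
#' @export
detect_spindles <- function(cubed_envelope, fs, params = spindle_params()) {
  if (length(cubed_envelope) == 0L) stop("empty envelope", call. = FALSE)
  base <- mean(cubed_envelope)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0), duration_s = numeric(0))
  if (base <= 0) return(empty)
  lo <- params$lower_mult * base
  hi <- params$upper_mult * base
  r <- rle(cubed_envelope > lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- empty
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    dur <- (i1 - i0 + 1L) / fs
    if (dur <= params$min_dur_s || dur >= params$max_dur_s) next
    seg <- cubed_envelope[i0:i1]
    if (max(seg) <= hi) next
    pk <- i0 + which.max(seg) - 1L
    out <- rbind(out, data.frame(start_s = (i0 - 1L) / fs, end_s = i1 / fs,
                                 peak_s = (pk - 1L) / fs,
                                 duration_s = dur))
  }
  rownames(out) <- NULL
  out
}

#' Run the full spindle detector on a recording
#'
#' [spindle_band_filter()] then [rms_envelope()] then [cube_signal()] then
#' [detect_spindles()].  Detection runs on the whole trace (no stage
#' restriction), matching the published procedure.
#'
#' @param rec A [recording()] (or a numeric EEG trace with `fs` supplied).
#' @param params A [spindle_params()].
#' @param fs Sampling rate, required when `rec` is a bare trace.
#' @return Data frame as from [detect_spindles()].
#' @export
find_spindles <- function(rec, params = spindle_params(), fs = NULL) {
  if (inherits(rec, "recording")) {
    eeg <- rec$eeg
    fs <- rec$eeg_fs
  } else {
    eeg <- rec
    if (is.null(fs)) stop("`fs` required for a bare trace", call. = FALSE)
  }
  filt <- spindle_band_filter(eeg, fs, params)
  env <- rms_envelope(filt, fs, params$rms_window_ms)
  detect_spindles(cube_signal(env), fs, params)
}

#' Spindle count and rate per sleep hour
#'
#' @param spindles Data frame from [detect_spindles()]/[find_spindles()].
#' @param total_sleep_s Total sleep time in seconds (e.g. from
#'   [sleep_metrics()]); the rate is `NA` (missing) when zero and the
#'   count is positive.
#' @return List with `count` and `count_per_sleep_hour`.
#' @export
spindle_metrics <- function(spindles, total_sleep_s) {
  count <- nrow(spindles)
  rate <- if (total_sleep_s > 0) count / (total_sleep_s / 3600)
          else if (count == 0) 0 else NA_real_
  list(count = count, count_per_sleep_hour = rate)
}
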