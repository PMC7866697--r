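# Digital filtering primitives.
#
# No DSP package ships with this installation, so the Butterworth design
# (analog prototype -> band transform -> bilinear transform, transfer-function
# form) is implemented here and validated in the test suite against
# independently computed reference coefficients.

# Polynomial with the given (complex) roots, leading coefficient 1.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  p
}

#' Butterworth IIR filter design
#'
#' Designs a digital Butterworth filter by the standard route: analog
#' lowpass prototype, frequency transform (lowpass, highpass or bandpass)
#' with pre-warped edges, then bilinear transform.  Returns transfer-function
#' coefficients compatible with [filter_tf()] and [zero_phase_filter()].
#'
#' @param n Filter order (for `"bandpass"` the resulting digital filter has
#'   order `2 * n`).
#' @param cutoff_hz Cutoff frequency in Hz; a length-2 vector for bandpass.
#' @param fs Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`.
#' @return List with numerator `b` and denominator `a` coefficient vectors.
#' @export
#' @examples
#' f <- butter_design(4, 50, fs = 500, type = "low")
#' length(f$b)
butter_design <- function(n, cutoff_hz, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  stopifnot_scalar_pos(n, "n")
  stopifnot_scalar_pos(fs, "fs")
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2))
    stop("cutoff frequencies must lie strictly inside (0, fs/2)", call. = FALSE)
  # analog Butterworth prototype: n poles on the unit left half-circle
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  gain <- 1
  # pre-warp edges (working rate 2, as is conventional for the bilinear step)
  fs2 <- 2
  warped <- 2 * fs2 * tan(pi * cutoff_hz / fs)
  if (type == "low") {
    p <- p * warped
    gain <- gain * warped^n
  } else if (type == "high") {
    gain <- gain * Re(prod(-p))
    p <- warped / p
    z <- rep(0 + 0i, n)
  } else {
    if (length(warped) != 2L)
      stop("bandpass design needs two cutoff frequencies", call. = FALSE)
    bw <- warped[2] - warped[1]
    w0 <- sqrt(warped[1] * warped[2])
    s <- p * bw / 2
    disc <- sqrt(s^2 - w0^2)
    p <- c(s + disc, s - disc)
    z <- rep(0 + 0i, n)
    gain <- gain * bw^n
  }
  # bilinear transform
  f2 <- 2 * fs2
  gain <- gain * Re(prod(f2 - z) / prod(f2 - p))
  zd <- (f2 + z) / (f2 - z)
  pd <- (f2 + p) / (f2 - p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Minimum Butterworth order meeting a bandpass attenuation spec
# (passband edges wp, stopband edges ws in Hz; gains in dB).
butter_order_bandpass <- function(wp_hz, ws_hz, gpass_db, gstop_db, fs) {
  warp <- function(f) tan(pi * f / fs)
  wp <- warp(wp_hz); ws <- warp(ws_hz)
  # selectivity of each stopband edge after the bandpass-to-lowpass mapping
  nat <- abs((ws^2 - wp[1] * wp[2]) / (ws * (wp[2] - wp[1])))
  nat <- min(nat)
  gp <- 10^(gpass_db / 10) - 1
  gs <- 10^(gstop_db / 10) - 1
  ceiling(log10(gs / gp) / (2 * log10(nat)))
}

#' Apply an IIR filter (direct form, zero initial conditions)
#'
#' @param coef List with `b` and `a` as from [butter_design()].
#' @param x Numeric signal.
#' @return Filtered signal, same length.
#' @export
filter_tf <- function(coef, x) {
  .filter_df2t(coef$b / coef$a[1], coef$a / coef$a[1], x)
}

#' Zero-phase (forward-backward) filtering
#'
#' Filters forward and backward with odd-reflection end padding, cancelling
#' the filter's phase response.  Mirrors the common `filtfilt` behaviour.
#'
#' @inheritParams filter_tf
#' @export
zero_phase_filter <- function(coef, x) {
  padlen <- 3L * (max(length(coef$a), length(coef$b)) - 1L)
  if (length(x) <= padlen)
    stop("signal too short for zero-phase filtering", call. = FALSE)
  .filtfilt_df2t(coef$b / coef$a[1], coef$a / coef$a[1], x, padlen)
}

# Complex frequency response H(f) of a transfer function at `freq_hz`.
freq_response <- function(coef, freq_hz, fs) {
  w <- exp(-1i * 2 * pi * freq_hz / fs)
  polyval <- function(cf, x) {
    acc <- rep(0 + 0i, length(x))
    for (c1 in cf) acc <- acc * x + c1
    acc
  }
  polyval(coef$b, w) / polyval(coef$a, w)
}

# Fraction of a filtered-white-noise component's variance falling in
# [lo, hi] Hz, from the filter's squared magnitude response.
band_variance_fraction <- function(coef, lo, hi, fs, df = 0.05) {
  f <- seq(0, fs / 2, by = df)
  h2 <- Mod(freq_response(coef, f, fs))^2
  sum(h2[f >= lo & f <= hi]) / sum(h2)
}

#' Sliding root-mean-square envelope
#'
#' Centered moving RMS with the window shrunk at the edges, so the output
#' has the same length as the input.
#'
#' @param x Numeric signal (any sign; the square is averaged).
#' @param fs Sampling rate in Hz.
#' @param window_ms Window length in milliseconds (default 750).
#' @return Non-negative envelope, `length(x)` values.
#' @export
rms_envelope <- function(x, fs, window_ms = 750) {
  stopifnot_scalar_pos(window_ms, "window_ms")
  w <- round(fs * window_ms / 1000)
  n <- length(x)
  if (w >= n) stop("RMS window must be shorter than the signal", call. = FALSE)
  half <- w %/% 2L
  cs <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}
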