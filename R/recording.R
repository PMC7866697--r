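# The Recording container and the clock/light-cycle and edge-trimming
# conventions shared by every analysis stage.

#' Multichannel telemetry recording
#'
#' Container for one subject's continuous EEG and EMG traces (microvolts)
#' plus an optional activity channel, with sampling metadata and the clock
#' time at which the recording started.  EEG/EMG are typically acquired at
#' 500 Hz and activity at 200 Hz by rodent telemetry systems.
#'
#' @param eeg,emg Numeric traces in microvolts.
#' @param activity Numeric activity counts, or `NULL` if not recorded.
#' @param eeg_fs,emg_fs,activity_fs Sampling rates in Hz.
#' @param start_clock_h Clock hour-of-day in `[0, 24)` at the first sample.
#' @param subject_id,group_label Identifier strings.
#' @return An object of class `"recording"`.
#' @export
recording <- function(eeg, emg, activity = NULL,
                      eeg_fs = 500, emg_fs = 500, activity_fs = 200,
                      start_clock_h = 0, subject_id = "s1",
                      group_label = "none") {
  stopifnot_scalar_pos(eeg_fs, "eeg_fs")
  stopifnot_scalar_pos(emg_fs, "emg_fs")
  stopifnot_scalar_pos(activity_fs, "activity_fs")
  if (length(eeg) < 1L) stop("recording must have positive duration", call. = FALSE)
  if (abs(length(eeg) / eeg_fs - length(emg) / emg_fs) > 1 / min(eeg_fs, emg_fs))
    stop("EEG and EMG must cover the same duration", call. = FALSE)
  if (start_clock_h < 0 || start_clock_h >= 24)
    stop("`start_clock_h` must lie in [0, 24)", call. = FALSE)
  structure(list(eeg = eeg, emg = emg, activity = activity,
                 eeg_fs = eeg_fs, emg_fs = emg_fs, activity_fs = activity_fs,
                 start_clock_h = start_clock_h, subject_id = subject_id,
                 group_label = group_label),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (group %s): %.2f h, EEG/EMG %g/%g Hz%s, starts %05.2f h\n",
              x$subject_id, x$group_label, duration_s(x) / 3600,
              x$eeg_fs, x$emg_fs,
              if (is.null(x$activity)) "" else sprintf(", activity %g Hz", x$activity_fs),
              x$start_clock_h))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [recording()].
#' @export
duration_s <- function(rec) length(rec$eeg) / rec$eeg_fs

#' Light-dark schedule
#'
#' Vivarium illumination schedule as a half-open clock interval.  With the
#' conventional 12:12 schedule, lights are on over `[7, 19)` and the dark
#' cycle is the complement `[19, 24) U [0, 7)`; every hour-of-day belongs to
#' exactly one cycle.
#'
#' @param lights_on_h,lights_off_h Clock hours in `[0, 24)`, distinct.
#' @return Object of class `"light_dark_scheme"`.
#' @export
light_dark_scheme <- function(lights_on_h = 7, lights_off_h = 19) {
  if (lights_on_h == lights_off_h)
    stop("lights-on and lights-off hours must differ", call. = FALSE)
  structure(list(lights_on_h = lights_on_h, lights_off_h = lights_off_h),
            class = "light_dark_scheme")
}

#' Assign clock hours to the light or dark cycle
#'
#' @param hour Numeric hours-of-day (any values; reduced modulo 24).
#' @param scheme A [light_dark_scheme()].
#' @return Character vector, `"light"` or `"dark"`.
#' @export
hour_cycle <- function(hour, scheme = light_dark_scheme()) {
  h <- hour %% 24
  on <- scheme$lights_on_h
  off <- scheme$lights_off_h
  in_light <- if (on < off) h >= on & h < off else h >= on | h < off
  ifelse(in_light, "light", "dark")
}

#' Clock hour-of-day of a sample time
#'
#' @param sample_time_s Seconds from recording start (vectorised).
#' @param start_clock_h Clock hour at recording start.
#' @return Hour-of-day in `[0, 24)`.
#' @export
clock_hour_of <- function(sample_time_s, start_clock_h) {
  if (any(sample_time_s < 0)) stop("sample times must be >= 0", call. = FALSE)
  (start_clock_h + sample_time_s / 3600) %% 24
}

#' Trim the head and tail of a recording
#'
#' Standard edge-trimming before spectral and spike analyses: dropping 3 h
#' from each end of a 24-h recording leaves an 18-h analysis window, and
#' trimming 3 h from the head of a 72-h recording leaves 69 h.  The start
#' clock advances by the trimmed head, modulo 24.
#'
#' @param rec A [recording()].
#' @param head_h,tail_h Hours to remove from the start and end.
#' @return The trimmed [recording()].
#' @export
trim_edges <- function(rec, head_h = 3, tail_h = 3) {
  if (head_h < 0 || tail_h < 0) stop("trim amounts must be >= 0", call. = FALSE)
  dur <- duration_s(rec)
  if ((head_h + tail_h) * 3600 >= dur)
    stop("trim exceeds recording duration", call. = FALSE)
  slice <- function(x, fs) {
    if (is.null(x)) return(NULL)
    i0 <- round(head_h * 3600 * fs)
    i1 <- length(x) - round(tail_h * 3600 * fs)
    x[(i0 + 1L):i1]
  }
  rec$eeg <- slice(rec$eeg, rec$eeg_fs)
  rec$emg <- slice(rec$emg, rec$emg_fs)
  # `[<-` keeps an explicit NULL element ($<- would delete it, and later
  # `$activity` would partial-match `activity_fs`)
  rec["activity"] <- list(slice(rec$activity, rec$activity_fs))
  rec$start_clock_h <- (rec$start_clock_h + head_h) %% 24
  rec
}

#' Low-pass preprocessing of the EEG trace
#'
#' The acquisition chain band-limits to the frequencies of interest below
#' 50 Hz.  Because a 0 Hz high-pass edge is a no-op (and the hardware
#' already applied a 0.1 Hz high-pass), this is implemented as a zero-phase
#' 4th-order Butterworth low-pass at 50 Hz.
#'
#' @param rec A [recording()] with `eeg_fs > 100` Hz.
#' @param cutoff_hz Low-pass edge, default 50 Hz.
#' @return The filtered EEG trace (numeric, same length as `rec$eeg`).
#' @export
preprocess_eeg <- function(rec, cutoff_hz = 50) {
  if (rec$eeg_fs <= 2 * cutoff_hz)
    stop("EEG sampling rate too low for the requested cutoff", call. = FALSE)
  coef <- butter_design(4, cutoff_hz, fs = rec$eeg_fs, type = "low")
  zero_phase_filter(coef, rec$eeg)
}
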