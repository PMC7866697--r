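# Two-pass epileptiform spike counting: windowed amplitude statistics,
# SD-multiple candidate demarcation, strict 3-point peak confirmation and
# activity-based window exclusion.

#' Spike-detection parameters
#'
#' @param window_s Analysis window length in seconds (default 30).
#' @param sd_mult Candidate threshold in SDs from the window mean
#'   (default 2.5, two-sided).
#' @param flank_pts Samples that must rise strictly toward / fall strictly
#'   away from a peak (default 3).
#' @param trim_head_h,trim_tail_h Hours removed from each end before
#'   counting (default 3 each).
#' @param activity_threshold A 30-s window is excluded when any activity
#'   sample exceeds this value (default 0: any detected activity excludes
#'   the window — the strictest reading).
#' @param merge_ms Confirmed candidates closer than this are merged into a
#'   single event, keeping the largest excursion (default 20 ms; refractory
#'   merge to avoid double-counting one transient).
#' @export
spike_params <- function(window_s = 30, sd_mult = 2.5, flank_pts = 3,
                         trim_head_h = 3, trim_tail_h = 3,
                         activity_threshold = 0, merge_ms = 20) {
  stopifnot_scalar_pos(window_s, "window_s")
  stopifnot_scalar_pos(sd_mult, "sd_mult")
  if (flank_pts < 1) stop("`flank_pts` must be >= 1", call. = FALSE)
  structure(list(window_s = window_s, sd_mult = sd_mult,
                 flank_pts = as.integer(flank_pts),
                 trim_head_h = trim_head_h, trim_tail_h = trim_tail_h,
                 activity_threshold = activity_threshold,
                 merge_ms = merge_ms), class = "spike_params")
}

#' Per-window amplitude mean and SD
#'
#' Segments the signal into consecutive complete windows (a trailing
#' partial window is discarded) and returns the mean and standard
#' deviation of the signed sample values per window.
#'
#' @param eeg Numeric trace.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @return Data frame with columns `mean` and `sd`, one row per window.
#' @export
window_amplitude_stats <- function(eeg, fs, window_s = 30) {
  L <- round(window_s * fs)
  nw <- length(eeg) %/% L
  if (nw < 1L) stop("signal shorter than one window", call. = FALSE)
  m <- matrix(eeg[seq_len(nw * L)], nrow = L)
  mu <- colMeans(m)
  sdv <- sqrt(colSums((m - rep(mu, each = L))^2) / (L - 1))
  data.frame(mean = mu, sd = sdv)
}

#' Demarcate candidate spike samples in one window
#'
#' A sample is a candidate when it lies more than `sd_mult` standard
#' deviations above or below the window mean.  A zero-SD window yields no
#' candidates.
#'
#' @param eeg_window Samples of one window.
#' @param mean,sd Window amplitude statistics.
#' @param sd_mult Threshold multiplier.
#' @return Integer indices into `eeg_window`.
#' @export
demarcate_candidates <- function(eeg_window, mean, sd, sd_mult = 2.5) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (sd == 0) return(integer(0))
  which(abs(eeg_window - mean) > sd_mult * sd)
}

#' Confirm candidates as peaks by strict monotone flanks
#'
#' A candidate is confirmed when the `flank_pts` samples before it rise
#' strictly toward it and the `flank_pts` samples after it fall strictly
#' away, in the direction of the candidate's excursion (mirrored for
#' negative excursions).  Ties break toward rejection, and candidates
#' within `flank_pts` of the window edge are dropped.
#'
#' @param eeg_window Samples of one window.
#' @param candidate_indices From [demarcate_candidates()].
#' @param flank_pts Flank length in samples.
#' @param center Window mean used to orient the excursion (default 0).
#' @return Confirmed indices (subset of `candidate_indices`).
#' @export
confirm_peaks <- function(eeg_window, candidate_indices, flank_pts = 3,
                          center = 0) {
  n <- length(eeg_window)
  idx <- candidate_indices[candidate_indices > flank_pts &
                           candidate_indices <= n - flank_pts]
  if (length(idx) == 0L) return(integer(0))
  pos <- eeg_window[idx] >= center
  ok <- rep(TRUE, length(idx))
  for (k in seq_len(flank_pts)) {
    up_before <- eeg_window[idx - k] < eeg_window[idx - k + 1L]
    down_after <- eeg_window[idx + k] < eeg_window[idx + k - 1L]
    down_before <- eeg_window[idx - k] > eeg_window[idx - k + 1L]
    up_after <- eeg_window[idx + k] > eeg_window[idx + k - 1L]
    ok <- ok & ifelse(pos, up_before & down_after, down_before & up_after)
  }
  idx[ok]
}

#' Retain windows free of detected activity
#'
#' A window is retained only when every activity sample in its interval is
#' at or below `threshold`; any detected movement excludes the whole
#' window as possible artifact.
#'
#' @param n_windows Number of analysis windows.
#' @param window_s Window length in seconds.
#' @param activity Activity trace covering the signal, or `NULL` (all
#'   windows retained).
#' @param activity_fs Activity sampling rate in Hz.
#' @param threshold Exclusion threshold (default 0 counts).
#' @return Integer indices of retained windows.
#' @export
exclude_active_windows <- function(n_windows, window_s, activity,
                                   activity_fs, threshold = 0) {
  if (is.null(activity)) return(seq_len(n_windows))
  La <- round(window_s * activity_fs)
  keep <- logical(n_windows)
  for (wi in seq_len(n_windows)) {
    seg <- activity[((wi - 1L) * La + 1L):min(wi * La, length(activity))]
    keep[wi] <- all(seg <= threshold, na.rm = TRUE)
  }
  which(keep)
}

#' Count epileptiform spikes in a recording
#'
#' Full pipeline: trim the recording edges, segment the EEG into
#' windows, demarcate amplitude candidates, confirm peaks by strict
#' monotone flanks, merge confirmations within the refractory radius,
#' exclude windows containing activity, and sum.  Deterministic.
#'
#' Counts from recordings of different durations are not comparable, so a
#' per-hour rate over the retained (artifact-free) windows is always
#' reported alongside the raw count.
#'
#' Detection runs on the unfiltered trace: the strict flank rule relies
#' on the broadband noise floor to reject ordinary signal peaks, and the
#' published spike pipeline states no band-limiting step of its own.
#'
#' @param rec A [recording()].
#' @param params A [spike_params()].
#' @param preprocess Low-pass the EEG at 50 Hz first (default FALSE).
#' @return Object of class `"spike_result"`: `count`, `rate_per_h`,
#'   `hours_analyzed`, `windows_total`, `windows_retained` and an `events`
#'   data frame (`time_s`, `amplitude`, `window_index`; times relative to
#'   the trimmed recording).
#' @export
count_spikes <- function(rec, params = spike_params(), preprocess = FALSE) {
  fs <- rec$eeg_fs
  if (params$trim_head_h > 0 || params$trim_tail_h > 0)
    rec <- trim_edges(rec, params$trim_head_h, params$trim_tail_h)
  eeg <- if (preprocess) preprocess_eeg(rec) else rec$eeg
  L <- round(params$window_s * fs)
  stats_w <- window_amplitude_stats(eeg, fs, params$window_s)
  nw <- nrow(stats_w)
  fp <- params$flank_pts

  # vectorised demarcation + confirmation over all windows at once
  n_used <- nw * L
  x <- eeg[seq_len(n_used)]
  win_of <- rep(seq_len(nw), each = L)
  mu <- stats_w$mean[win_of]
  sdv <- stats_w$sd[win_of]
  cand <- which(sdv > 0 & abs(x - mu) > params$sd_mult * sdv)
  # drop candidates within flank_pts of their window's edges
  pos_in_win <- (cand - 1L) %% L + 1L
  cand <- cand[pos_in_win > fp & pos_in_win <= L - fp]
  ok <- rep(TRUE, length(cand))
  if (length(cand)) {
    pos <- x[cand] >= mu[cand]
    for (k in seq_len(fp)) {
      up_before <- x[cand - k] < x[cand - k + 1L]
      down_after <- x[cand + k] < x[cand + k - 1L]
      down_before <- x[cand - k] > x[cand - k + 1L]
      up_after <- x[cand + k] > x[cand + k - 1L]
      ok <- ok & ifelse(pos, up_before & down_after, down_before & up_after)
    }
  }
  conf <- cand[ok]
  events <- data.frame(time_s = numeric(0), amplitude = numeric(0),
                       window_index = integer(0))
  if (length(conf)) {
    exc <- abs(x[conf] - mu[conf])
    # refractory merge: group confirmations separated by < merge_r samples
    merge_r <- round(params$merge_ms / 1000 * fs)
    grp <- cumsum(c(1L, diff(conf) >= merge_r))
    keep <- vapply(split(seq_along(conf), grp), function(ii)
      ii[which.max(exc[ii])], integer(1))
    keep <- sort(keep)
    events <- data.frame(time_s = (conf[keep] - 1L) / fs,
                         amplitude = x[conf[keep]],
                         window_index = win_of[conf[keep]])
  }

  retained <- exclude_active_windows(nw, params$window_s, rec$activity,
                                     rec$activity_fs,
                                     params$activity_threshold)
  events <- events[events$window_index %in% retained, , drop = FALSE]
  rownames(events) <- NULL
  hours <- length(retained) * params$window_s / 3600
  structure(list(count = nrow(events),
                 rate_per_h = if (hours > 0) nrow(events) / hours else NA_real_,
                 hours_analyzed = hours,
                 windows_total = nw, windows_retained = length(retained),
                 events = events),
            class = "spike_result")
}

#' @export
print.spike_result <- function(x, ...) {
  cat(sprintf("<spike_result> %d spikes over %.2f artifact-free h (%.2f/h; %d/%d windows retained)\n",
              x$count, x$hours_analyzed, x$rate_per_h,
              x$windows_retained, x$windows_total))
  invisible(x)
}
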