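# Rule-based four-state sleep staging: per-second classification from
# EEG/EMG features, 10-s majority epochs, bout/latency metrics and 2-h
# light-dark bin summaries.

STAGE_LEVELS <- c("active_wake", "wake", "sws", "paradoxical", "unscored")

#' Staging rule parameters
#'
#' Quantitative thresholds behind the qualitative staging rules (wake:
#' low-amplitude high-frequency EEG with low EMG tone; active wake: high
#' EMG tone; slow-wave sleep: high-amplitude EEG with elevated delta and
#' low EMG; paradoxical sleep: low-amplitude EEG with elevated theta and
#' low EMG).  The amplitude and EMG thresholds are multiples of the
#' recording-wide median per-second RMS, which makes staging invariant to
#' global amplitude scaling.  Values are this package's calibration,
#' validated against the simulator's ground truth.
#'
#' @param amp_high_mult EEG RMS above `amp_high_mult * median` counts as
#'   high-amplitude (default 1.5).
#' @param emg_high_mult EMG RMS above `emg_high_mult * median` counts as
#'   high tone (default 2).
#' @param delta_frac_min Minimum delta fraction (delta / 0.5-50 Hz power)
#'   for slow-wave sleep (default 0.35).
#' @param theta_over_delta_min Minimum theta/delta power ratio for
#'   paradoxical sleep (default 2).
#' @export
stage_rule_params <- function(amp_high_mult = 1.5, emg_high_mult = 2,
                              delta_frac_min = 0.35,
                              theta_over_delta_min = 2) {
  stopifnot_scalar_pos(amp_high_mult, "amp_high_mult")
  stopifnot_scalar_pos(emg_high_mult, "emg_high_mult")
  if (delta_frac_min <= 0 || delta_frac_min >= 1)
    stop("`delta_frac_min` must lie in (0, 1)", call. = FALSE)
  stopifnot_scalar_pos(theta_over_delta_min, "theta_over_delta_min")
  structure(list(amp_high_mult = amp_high_mult, emg_high_mult = emg_high_mult,
                 delta_frac_min = delta_frac_min,
                 theta_over_delta_min = theta_over_delta_min),
            class = "stage_rule_params")
}

#' Per-second EEG/EMG staging features
#'
#' Segments the EEG into 1-s windows and computes, per second: EEG RMS,
#' delta-band power (0.5-4 Hz), theta-band power (5-9 Hz) and total
#' 0.5-50 Hz power, plus the per-second EMG RMS.  Band powers are the
#' per-second mean square of Butterworth band-filtered copies of the
#' trace, which avoids the coarse 1 Hz binning (and its leakage bias) a
#' 1-s periodogram would impose; the filters run single-pass because only
#' power, not phase, is used.  Total power is the per-second mean square
#' of the trace itself (the acquisition chain already band-limits it to
#' the 0.5-50 Hz range of interest).
#'
#' @param rec A [recording()].
#' @return Data frame, one row per complete second.
#' @export
stage_features <- function(rec) {
  fs <- rec$eeg_fs
  n_s <- length(rec$eeg) %/% fs
  eeg_rms <- per_second_rms(rec$eeg, fs)
  emg_rms <- per_second_rms(rec$emg, rec$emg_fs)[seq_len(n_s)]
  bp <- function(lo, hi)
    per_second_rms(filter_tf(butter_design(4, c(lo, hi), fs, "pass"),
                             rec$eeg), fs)^2
  data.frame(eeg_rms = eeg_rms, emg_rms = emg_rms,
             delta_p = bp(0.5, 4), theta_p = bp(5, 9),
             total_p = eeg_rms^2)
}

#' Classify per-second features into sleep-wake stages
#'
#' Decision tree: high EMG tone -> active wake; else high EEG amplitude
#' with delta fraction at least `delta_frac_min` -> slow-wave sleep; else
#' low amplitude with theta/delta at least `theta_over_delta_min` ->
#' paradoxical sleep; else wake.  Seconds with degenerate (zero-power)
#' features are `unscored`.
#'
#' @param features From [stage_features()].
#' @param params A [stage_rule_params()].
#' @param amp_median,emg_median Baselines; by default the medians of the
#'   supplied features.
#' @return Character vector of per-second stage labels.
#' @export
stage_seconds <- function(features, params = stage_rule_params(),
                          amp_median = stats::median(features$eeg_rms),
                          emg_median = stats::median(features$emg_rms)) {
  amp_thr <- params$amp_high_mult * amp_median
  emg_thr <- params$emg_high_mult * emg_median
  lab <- rep("wake", nrow(features))
  amp_high <- features$eeg_rms > amp_thr
  delta_frac <- ifelse(features$total_p > 0,
                       features$delta_p / features$total_p, 0)
  td_ratio <- ifelse(features$delta_p > 0,
                     features$theta_p / features$delta_p, Inf)
  lab[amp_high & delta_frac >= params$delta_frac_min] <- "sws"
  lab[lab == "wake" & !amp_high &
        td_ratio >= params$theta_over_delta_min] <- "paradoxical"
  lab[features$total_p <= 0] <- "unscored"   # degenerate EEG
  lab[features$emg_rms > emg_thr] <- "active_wake"  # high tone wins
  lab
}

#' @rdname stage_seconds
#' @param eeg_1s_features One row of [stage_features()] (a list or
#'   single-row data frame).
#' @param emg_1s_rms EMG RMS of the same second.
#' @export
stage_second <- function(eeg_1s_features, emg_1s_rms,
                         params = stage_rule_params(),
                         amp_median, emg_median) {
  df <- as.data.frame(eeg_1s_features)
  df$emg_rms <- emg_1s_rms
  stage_seconds(df, params, amp_median = amp_median, emg_median = emg_median)
}

#' Score 10-s epochs by per-second majority
#'
#' Each complete epoch takes the modal per-second label when that label
#' covers at least `majority_frac` of the epoch *and* is the unique mode;
#' otherwise the epoch is `unscored` (a 5 s / 5 s tie has no unique
#' majority).  A trailing partial epoch is dropped.
#'
#' @param per_second_labels Character stage labels, one per second.
#' @param epoch_s Epoch length in seconds (default 10).
#' @param majority_frac Minimum share for the modal label (default 0.5).
#' @param start_clock_h Clock hour of the first second (kept for binning).
#' @return Object of class `"hypnogram"`: `labels`, `epoch_s`,
#'   `start_clock_h`.
#' @export
score_epochs <- function(per_second_labels, epoch_s = 10,
                         majority_frac = 0.5, start_clock_h = 0) {
  n_ep <- length(per_second_labels) %/% epoch_s
  if (n_ep < 1L) stop("need at least one complete epoch", call. = FALSE)
  m <- matrix(match(per_second_labels[seq_len(n_ep * epoch_s)], STAGE_LEVELS),
              nrow = epoch_s)
  counts <- vapply(seq_len(n_ep), function(j) tabulate(m[, j], 5L),
                   integer(5L))
  scoreable <- counts[1:4, , drop = FALSE]  # unscored seconds never win
  top <- apply(scoreable, 2, max)
  n_top <- colSums(scoreable == rep(top, each = 4L))
  winner <- STAGE_LEVELS[apply(scoreable, 2, which.max)]
  lab <- ifelse(top >= majority_frac * epoch_s & n_top == 1L,
                winner, "unscored")
  structure(list(labels = lab, epoch_s = epoch_s,
                 start_clock_h = start_clock_h), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = STAGE_LEVELS))
  cat(sprintf("<hypnogram> %d epochs of %g s (%.2f h), starts %05.2f h\n",
              length(x$labels), x$epoch_s,
              length(x$labels) * x$epoch_s / 3600, x$start_clock_h))
  print(tab)
  invisible(x)
}

#' Stage a recording end to end
#'
#' [stage_features()] then [stage_seconds()] then [score_epochs()].
#'
#' @param rec A [recording()].
#' @param params A [stage_rule_params()].
#' @param epoch_s Scoring epoch in seconds.
#' @return A `"hypnogram"`.
#' @export
stage_recording <- function(rec, params = stage_rule_params(), epoch_s = 10) {
  feats <- stage_features(rec)
  labs <- stage_seconds(feats, params)
  score_epochs(labs, epoch_s = epoch_s, start_clock_h = rec$start_clock_h)
}

#' Extract stage bouts from a hypnogram
#'
#' Maximal runs of identical non-`unscored` labels; an unscored epoch
#' terminates the surrounding bout.
#'
#' @param hyp A `"hypnogram"`.
#' @return Data frame: `state`, `start_s`, `end_s` (half-open, seconds
#'   from recording start).
#' @export
extract_bouts <- function(hyp) {
  r <- rle(hyp$labels)
  end <- cumsum(r$lengths) * hyp$epoch_s
  out <- data.frame(state = r$values, start_s = end - r$lengths * hyp$epoch_s,
                    end_s = end, stringsAsFactors = FALSE)
  out[out$state != "unscored", , drop = FALSE]
}

#' Sleep-architecture metrics
#'
#' Mean bout duration per state (averaging the time spent in each bout of
#' that state); sleep latency (mean, over every wake-state run followed by
#' sleep, of the interval from the run's onset to the next sleep-bout
#' onset, with both wake and active wake eligible as the origin); latency
#' restricted to paradoxical sleep as the target; and total sleep time
#' (summed slow-wave and paradoxical bout durations).  Latencies are `NA`
#' (missing, not zero) when no qualifying transition exists.
#'
#' @param hyp A `"hypnogram"`.
#' @return Object of class `"sleep_metrics"`.
#' @export
sleep_metrics <- function(hyp) {
  if (length(hyp$labels) == 0L) stop("empty hypnogram", call. = FALSE)
  bouts <- extract_bouts(hyp)
  mean_bout <- sapply(STAGE_LEVELS[1:4], function(s) {
    b <- bouts[bouts$state == s, ]
    if (nrow(b) == 0L) NA_real_ else mean(b$end_s - b$start_s)
  })
  sleep_states <- c("sws", "paradoxical")
  total_sleep <- sum((bouts$end_s - bouts$start_s)[bouts$state %in% sleep_states])

  # latency: collapse bouts into wake-class / sleep-state runs
  cls <- ifelse(bouts$state %in% c("wake", "active_wake"), "wakeful",
                bouts$state)
  rr <- rle(cls)
  run_end <- cumsum(rr$lengths)
  run_start_idx <- run_end - rr$lengths + 1L
  lat_any <- lat_ps <- numeric(0)
  for (j in seq_along(rr$values)) {
    if (rr$values[j] != "wakeful") next
    onset <- bouts$start_s[run_start_idx[j]]
    later <- run_end[j] + seq_len(nrow(bouts) - run_end[j])
    nxt_sleep <- later[bouts$state[later] %in% sleep_states][1]
    if (!is.na(nxt_sleep))
      lat_any <- c(lat_any, bouts$start_s[nxt_sleep] - onset)
    nxt_ps <- later[bouts$state[later] == "paradoxical"][1]
    if (!is.na(nxt_ps))
      lat_ps <- c(lat_ps, bouts$start_s[nxt_ps] - onset)
  }
  structure(list(mean_bout_s = mean_bout,
                 latency_s = if (length(lat_any)) mean(lat_any) else NA_real_,
                 latency_paradoxical_s =
                   if (length(lat_ps)) mean(lat_ps) else NA_real_,
                 total_sleep_s = total_sleep),
            class = "sleep_metrics")
}

#' Two-hour clock-aligned bin summaries
#'
#' Assigns each 10-s epoch to the clock-aligned 2-h bin containing its
#' start (bins begin at midnight: 0-2, 2-4, ...), counting awake
#' (wake + active wake), slow-wave, paradoxical and artifact (unscored)
#' scores per bin.  A complete bin holds 720 possible scores; percent time
#' is the count divided by 720 and multiplied by 100.  Partial first/last
#' bins are flagged (`complete = FALSE`) and their `percent_*` columns use
#' the actual epoch count as denominator; `percent_scored_*` columns use
#' only scored (non-artifact) epochs.  Each bin is labeled light or dark
#' by its starting clock hour.
#'
#' @param hyp A `"hypnogram"`.
#' @param scheme A [light_dark_scheme()].
#' @return Data frame, one row per bin.
#' @export
bin_2h <- function(hyp, scheme = light_dark_scheme()) {
  n_ep <- length(hyp$labels)
  t_start <- (seq_len(n_ep) - 1) * hyp$epoch_s
  abs_h <- hyp$start_clock_h + t_start / 3600
  bin_abs <- floor(abs_h / 2) * 2           # absolute 2-h bin since day 0
  labels <- hyp$labels
  out <- NULL
  for (b in unique(bin_abs)) {
    sel <- bin_abs == b
    lab <- factor(labels[sel], levels = STAGE_LEVELS)
    cnt <- tabulate(lab, 5L)
    n_here <- sum(sel)
    possible <- 7200 / hyp$epoch_s          # 720 for 10-s epochs
    denom <- if (n_here == possible) possible else n_here
    scored <- sum(cnt[1:4])
    row <- data.frame(
      day = floor(b / 24) + 1L,
      bin_start_clock_h = b %% 24,
      cycle = hour_cycle(b %% 24, scheme),
      n_epochs = n_here,
      complete = n_here == possible,
      awake_count = cnt[1] + cnt[2],
      sws_count = cnt[3],
      paradoxical_count = cnt[4],
      artifact_count = cnt[5],
      stringsAsFactors = FALSE)
    row$awake_percent <- 100 * row$awake_count / denom
    row$sws_percent <- 100 * row$sws_count / denom
    row$paradoxical_percent <- 100 * row$paradoxical_count / denom
    row$artifact_percent <- 100 * row$artifact_count / denom
    row$awake_percent_scored <- if (scored) 100 * row$awake_count / scored else NA_real_
    row$sws_percent_scored <- if (scored) 100 * row$sws_count / scored else NA_real_
    row$paradoxical_percent_scored <-
      if (scored) 100 * row$paradoxical_count / scored else NA_real_
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Aggregate 2-h bins into light and dark cycles
#'
#' Sums counts per cycle and reports epoch-weighted percent time (total
#' count over total possible epochs in that cycle).
#'
#' @param bins From [bin_2h()].
#' @return Data frame, one row per cycle.
#' @export
aggregate_cycles <- function(bins) {
  out <- NULL
  for (cyc in c("light", "dark")) {
    b <- bins[bins$cycle == cyc, , drop = FALSE]
    if (nrow(b) == 0L) next
    n <- sum(b$n_epochs)
    out <- rbind(out, data.frame(
      cycle = cyc, n_epochs = n,
      awake_count = sum(b$awake_count),
      sws_count = sum(b$sws_count),
      paradoxical_count = sum(b$paradoxical_count),
      artifact_count = sum(b$artifact_count),
      awake_percent = 100 * sum(b$awake_count) / n,
      sws_percent = 100 * sum(b$sws_count) / n,
      paradoxical_percent = 100 * sum(b$paradoxical_count) / n,
      artifact_percent = 100 * sum(b$artifact_count) / n,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
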