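# Waveform synthesis: stage-shaped EEG/EMG/activity with injected spikes
# and spindle bursts, all logged as ground truth.

# Per-stage variance split of the EEG across the three noise components
# (delta-band 0.5-4 Hz, theta-band 5-9 Hz, and a broadband component
# spanning the full 100 Hz acquisition bandwidth, mirroring the hardware
# low-pass).  Slow-wave sleep is delta-dominant; paradoxical sleep
# theta-dominant with weak delta; wake states are broadband.
stage_weights <- function() {
  rbind(active_wake = c(delta = 0.20, theta = 0.10, broad = 0.70),
        wake        = c(delta = 0.20, theta = 0.10, broad = 0.70),
        sws         = c(delta = 0.70, theta = 0.10, broad = 0.20),
        paradoxical = c(delta = 0.08, theta = 0.72, broad = 0.20))
}

# Order-4 band edges keep the narrowband components spectrally clean: an
# order-2 delta component would leak visible energy into the 10-15 Hz
# spindle band, which a genuine 0.5-4 Hz rhythm does not.
component_designs <- function(fs) {
  list(delta = butter_design(4, c(0.5, 4), fs, "pass"),
       theta = butter_design(4, c(5, 9), fs, "pass"),
       broad = butter_design(2, min(100, 0.45 * fs), fs, "low"))
}

# Unit-RMS band-limited noise, with a burn-in discarded so the filter
# start-up transient never reaches the output.
band_noise <- function(n, coef, fs, burn_s = 10) {
  nb <- round(burn_s * fs)
  y <- filter_tf(coef, stats::rnorm(n + nb))[(nb + 1L):(nb + n)]
  y / stats::sd(y)
}

# 40-ms biphasic spike template (one full sine cycle): the peak has three
# strictly rising samples before it and three strictly falling after it at
# 500 Hz, satisfying a 3-point flank confirmation by construction.
spike_template <- function(fs, dur_s = 0.04) {
  n <- round(dur_s * fs)
  tt <- seq_len(n) / n
  sin(2 * pi * tt - pi / n)  # peak near n/4, trough near 3n/4
}

#' Synthesize EEG/EMG/activity traces for a stage schedule
#'
#' Builds the multichannel recording implied by a per-second stage
#' schedule: EEG is a sum of band-limited noise components whose weights
#' and overall amplitude depend on the current stage (slow-wave sleep
#' delta-dominant and high amplitude; paradoxical sleep theta-dominant and
#' low amplitude; wake states broadband and low amplitude), EMG is noise at
#' high tone only during active wake, and the activity channel is nonzero
#' only during active wake.  Epileptiform spikes are injected as biphasic
#' 40-ms transients at Poisson times restricted to non-active-wake seconds,
#' and sleep spindles as Hann-windowed sinusoids at `spindle_freq` inside
#' slow-wave bouts; every injected event is logged in the returned ground
#' truth.  A spindle drawn too close to the end of its slow-wave bout is
#' shortened to fit, never dropped from the log.
#'
#' @param schedule Per-second stage codes from [simulate_stage_schedule()].
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to the config seed).
#' @param subject_id,group_label Identifiers stored in the recording.
#' @return List with elements `recording` ([recording()]) and `truth`
#'   (class `"ground_truth"`: `stage_per_second`, `spike_times_s`,
#'   `spindle_intervals_s` two-column matrix, `group_label`).
#' @export
synthesize_signals <- function(schedule, config, seed = config$seed,
                               subject_id = "s1", group_label = "none") {
  validate_sim_config(config)
  n_s <- length(schedule)
  fs <- config$eeg_fs
  w <- stage_weights()
  with_seed(seed, {
    designs <- component_designs(fs)
    n <- n_s * fs

    # per-second component amplitude coefficients
    amp <- ifelse(schedule == "sws", config$amp_sws, config$amp_wake)
    cd <- amp * sqrt(w[schedule, "delta"]) * config$delta_gain
    ct <- amp * sqrt(w[schedule, "theta"]) *
      ifelse(schedule == "paradoxical", config$theta_gain, 1)
    cb <- amp * sqrt(w[schedule, "broad"])

    eeg <- rep(cd, each = fs) * band_noise(n, designs$delta, fs)
    eeg <- eeg + rep(ct, each = fs) * band_noise(n, designs$theta, fs)
    eeg <- eeg + rep(cb, each = fs) * band_noise(n, designs$broad, fs)
    eeg <- eeg + config$noise_uv * stats::rnorm(n)   # sensor-noise floor

    stage_rms_s <- amp *
      sqrt(w[schedule, "delta"] * config$delta_gain^2 + w[schedule, "theta"] *
             ifelse(schedule == "paradoxical", config$theta_gain, 1)^2 +
             w[schedule, "broad"])

    # --- spikes ----------------------------------------------------------
    spike_times <- numeric(0)
    eligible <- which(schedule != "active_wake")
    if (config$spike_rate_per_h > 0 && length(eligible) > 0) {
      n_spk <- stats::rpois(1, config$spike_rate_per_h * n_s / 3600)
      n_spk <- min(n_spk, length(eligible))
      if (n_spk > 0) {
        tmpl <- spike_template(fs)
        secs <- sort(sample(eligible, n_spk))
        offs <- stats::runif(n_spk, 0.05, 0.9)
        sign_ <- sample(c(-1, 1), n_spk, replace = TRUE)
        peak_at <- which.max(tmpl)
        for (k in seq_len(n_spk)) {
          i0 <- round(((secs[k] - 1) + offs[k]) * fs)
          a <- config$spike_amp_sd * stage_rms_s[secs[k]] * sign_[k]
          idx <- i0 + seq_along(tmpl)
          eeg[idx] <- eeg[idx] + a * tmpl
          spike_times <- c(spike_times, (i0 + peak_at - 1) / fs)
        }
      }
    }

    # --- spindles --------------------------------------------------------
    # target in-band (10-15 Hz) amplitude relative to the slow-wave
    # background, computed from the component filters' frequency responses
    inband_var <- config$amp_sws^2 *
      (w["sws", "delta"] * config$delta_gain^2 *
         band_variance_fraction(designs$delta, 10, 15, fs) +
       w["sws", "theta"] * band_variance_fraction(designs$theta, 10, 15, fs) +
       w["sws", "broad"] * band_variance_fraction(designs$broad, 10, 15, fs))
    spindle_peak_amp <- config$spindle_amp_mult * sqrt(2 * inband_var)

    spindles <- matrix(numeric(0), ncol = 2,
                       dimnames = list(NULL, c("start_s", "end_s")))
    if (config$spindle_rate_per_min_sws > 0) {
      bouts <- schedule_bouts(schedule)
      bouts <- bouts[bouts$stage == "sws", , drop = FALSE]
      for (b in seq_len(nrow(bouts))) {
        dur_min <- (bouts$end_s[b] - bouts$start_s[b]) / 60
        n_spin <- stats::rpois(1, config$spindle_rate_per_min_sws * dur_min)
        if (n_spin == 0) next
        placed <- matrix(numeric(0), ncol = 2)
        for (k in seq_len(n_spin)) {
          d <- stats::runif(1, config$spindle_dur_s[1], config$spindle_dur_s[2])
          for (try in 1:8) {
            st <- stats::runif(1, bouts$start_s[b], bouts$end_s[b] - 0.25)
            en <- min(st + d, bouts$end_s[b])  # shorten-to-fit rule
            clash <- nrow(placed) > 0 &&
              any(st < placed[, 2] + 0.25 & en > placed[, 1] - 0.25)
            if (!clash) break
          }
          if (clash) next
          placed <- rbind(placed, c(st, en))
          i0 <- round(st * fs); i1 <- round(en * fs)
          m <- i1 - i0
          if (m < 4) next
          env <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
          tt <- (seq_len(m) - 1) / fs
          phase <- stats::runif(1, 0, 2 * pi)
          idx <- (i0 + 1L):i1
          eeg[idx] <- eeg[idx] + spindle_peak_amp * env *
            sin(2 * pi * config$spindle_freq * tt + phase)
          spindles <- rbind(spindles, c(st, en))
        }
      }
      spindles <- spindles[order(spindles[, 1]), , drop = FALSE]
    }

    # --- EMG and activity ------------------------------------------------
    tone <- ifelse(schedule == "active_wake",
                   config$emg_tone_high, config$emg_tone_low)
    emg <- rep(tone, each = config$emg_fs) * stats::rnorm(n_s * config$emg_fs)
    act <- integer(n_s * config$activity_fs)
    aw <- which(schedule == "active_wake")
    if (length(aw) > 0) {
      idx <- as.vector(outer(seq_len(config$activity_fs),
                             (aw - 1L) * config$activity_fs, `+`))
      act[idx] <- stats::rpois(length(idx), 2)
    }

    rec <- recording(eeg = eeg, emg = emg, activity = act,
                     eeg_fs = fs, emg_fs = config$emg_fs,
                     activity_fs = config$activity_fs,
                     start_clock_h = config$start_clock_h,
                     subject_id = subject_id, group_label = group_label)
    truth <- structure(list(stage_per_second = schedule,
                            spike_times_s = sort(spike_times),
                            spindle_intervals_s = spindles,
                            group_label = group_label),
                       class = "ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' Simulate one complete recording
#'
#' Convenience wrapper: draws a stage schedule and synthesizes the
#' corresponding signals with the same seed.
#'
#' @inheritParams synthesize_signals
#' @param config A [sim_config()].
#' @export
simulate_recording <- function(config, seed = config$seed,
                               subject_id = "s1", group_label = "none") {
  sched <- simulate_stage_schedule(config, seed = seed)
  synthesize_signals(sched, config, seed = seed + 10000L,
                     subject_id = subject_id, group_label = group_label)
}

#' Simulate a two-group cohort
#'
#' Generates `n_per_group` animals per group with deterministic per-animal
#' seeds (`seed + animal index`), applying each group's [group_effect()]
#' to the base configuration.  The default "affected" effect mirrors the
#' phenotype direction of an elevated-delta, sleep-disrupted model: doubled
#' delta gain, halved paradoxical dwell/entry, halved spindle rate and
#' tripled spike rate.
#'
#' @param config_base A [sim_config()].
#' @param n_per_group Animals per group (>= 1).
#' @param group_effects Named list of [group_effect()] objects, one per
#'   group; names become group labels.
#' @param seed Integer master seed.
#' @return List of `list(recording, truth)` with a `manifest` attribute
#'   (data frame: subject_id, group, seed).
#' @export
generate_cohort <- function(config_base, n_per_group,
                            group_effects = list(
                              control = group_effect(),
                              affected = group_effect(delta_gain = 2,
                                                      paradoxical = 0.5,
                                                      spindle = 0.5,
                                                      spike = 3)),
                            seed = config_base$seed) {
  if (length(n_per_group) == 1L)
    n_per_group <- rep(n_per_group, length(group_effects))
  if (any(n_per_group < 1L) || length(n_per_group) != length(group_effects))
    stop("`n_per_group` must be >= 1 for every group", call. = FALSE)
  out <- list()
  manifest <- NULL
  i <- 0L
  for (g in seq_along(group_effects)) {
    gname <- names(group_effects)[g]
    cfg <- apply_group_effect(config_base, group_effects[[g]])
    for (k in seq_len(n_per_group[g])) {
      i <- i + 1L
      sid <- sprintf("%s_%02d", gname, k)
      out[[i]] <- simulate_recording(cfg, seed = seed + i,
                                     subject_id = sid, group_label = gname)
      manifest <- rbind(manifest,
                        data.frame(subject_id = sid, group = gname,
                                   seed = seed + i))
    }
  }
  attr(out, "manifest") <- manifest
  out
}
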