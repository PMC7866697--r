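# Simulator configuration and cohort group effects.

STAGES <- c("active_wake", "wake", "sws", "paradoxical")

#' Synthetic telemetry configuration
#'
#' All knobs of the synthetic EEG/EMG generator.  Defaults describe a
#' plausible singly housed adult mouse on a 12:12 light-dark schedule
#' (lights on 7 a.m. to 7 p.m.), recorded at the usual telemetry rates of
#' 500 Hz (EEG/EMG) and 200 Hz (activity).  Background amplitudes in
#' microvolts are free parameters of the simulator, not calibrated to any
#' particular acquisition system.
#'
#' @param duration_h Recording length in hours.
#' @param eeg_fs,emg_fs,activity_fs Sampling rates in Hz.
#' @param start_clock_h Clock hour-of-day at the first sample, `[0, 24)`.
#' @param lights_on_h,lights_off_h Illumination schedule clock hours.
#' @param stage_mean_bout_s Named numeric: mean bout duration (s) per stage
#'   (`active_wake`, `wake`, `sws`, `paradoxical`).  Bout dwell times are
#'   truncated-exponential with a 10-s floor so every bout is scorable at
#'   the 10-s epoch scale.
#' @param stage_dwell_bias_dark Multiplier on wake-state dwell during dark
#'   clock hours (mice are nocturnal).
#' @param ps_entry_prob Probability that a slow-wave bout is followed by a
#'   paradoxical-sleep bout (paradoxical sleep is entered only from
#'   slow-wave sleep).
#' @param amp_sws,amp_wake EEG RMS amplitude (microvolts) in slow-wave sleep
#'   and in the low-amplitude stages (wake, active wake, paradoxical).
#' @param delta_gain Multiplier on the 0.5-4 Hz EEG component in every
#'   stage; the "elevated delta" group effect.
#' @param theta_gain Multiplier on the 5-9 Hz component during paradoxical
#'   sleep.
#' @param emg_tone_high,emg_tone_low EMG RMS (microvolts) during active wake
#'   and all other stages.
#' @param noise_uv RMS (microvolts) of the white sensor-noise floor added
#'   to the EEG across the full bandwidth.  Instrument noise does not
#'   scale with the cortical signal; it is what makes the spike
#'   detector's strict monotone-flank confirmation informative, exactly
#'   as measurement noise does on real telemetry traces.
#' @param spike_rate_per_h Mean injected epileptiform-spike rate (events/h),
#'   Poisson over non-active-wake seconds.
#' @param spike_amp_sd Spike amplitude in units of the background SD of the
#'   stage it lands in (default 6).
#' @param spindle_rate_per_min_sws Mean injected spindle rate per minute of
#'   slow-wave sleep.
#' @param spindle_freq Spindle carrier frequency in Hz (the mouse spindle
#'   peak is near 11 Hz, inside the 10-15 Hz detection band).
#' @param spindle_dur_s Length-2 (min, max) spindle duration in seconds.
#' @param spindle_amp_mult Spindle in-band amplitude as a multiple of the
#'   background 10-15 Hz RMS during slow-wave sleep.
#' @param allowed_stages Subset of stages the schedule may visit (degenerate
#'   schedules for testing; default all four).
#' @param seed Default RNG seed carried with the configuration.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(duration_h = 24,
                       eeg_fs = 500, emg_fs = 500, activity_fs = 200,
                       start_clock_h = 0,
                       lights_on_h = 7, lights_off_h = 19,
                       stage_mean_bout_s = c(active_wake = 150, wake = 300,
                                             sws = 180, paradoxical = 60),
                       stage_dwell_bias_dark = 2,
                       ps_entry_prob = 0.5,
                       amp_sws = 120, amp_wake = 50,
                       delta_gain = 1, theta_gain = 1,
                       emg_tone_high = 60, emg_tone_low = 10,
                       noise_uv = 5,
                       spike_rate_per_h = 15, spike_amp_sd = 6,
                       spindle_rate_per_min_sws = 2,
                       spindle_freq = 11, spindle_dur_s = c(0.8, 2),
                       spindle_amp_mult = 4,
                       allowed_stages = STAGES,
                       seed = 1L) {
  cfg <- list(duration_h = duration_h, eeg_fs = eeg_fs, emg_fs = emg_fs,
              activity_fs = activity_fs, start_clock_h = start_clock_h,
              lights_on_h = lights_on_h, lights_off_h = lights_off_h,
              stage_mean_bout_s = stage_mean_bout_s,
              stage_dwell_bias_dark = stage_dwell_bias_dark,
              ps_entry_prob = ps_entry_prob,
              amp_sws = amp_sws, amp_wake = amp_wake,
              delta_gain = delta_gain, theta_gain = theta_gain,
              emg_tone_high = emg_tone_high, emg_tone_low = emg_tone_low,
              noise_uv = noise_uv,
              spike_rate_per_h = spike_rate_per_h, spike_amp_sd = spike_amp_sd,
              spindle_rate_per_min_sws = spindle_rate_per_min_sws,
              spindle_freq = spindle_freq, spindle_dur_s = spindle_dur_s,
              spindle_amp_mult = spindle_amp_mult,
              allowed_stages = allowed_stages, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("duration_h", "eeg_fs", "emg_fs", "activity_fs",
              "stage_dwell_bias_dark", "amp_sws", "amp_wake", "delta_gain",
              "theta_gain", "emg_tone_high", "emg_tone_low", "noise_uv",
              "spike_amp_sd",
              "spindle_freq", "spindle_amp_mult"))
    stopifnot_scalar_pos(cfg[[f]], f)
  if (cfg$spike_rate_per_h < 0 || cfg$spindle_rate_per_min_sws < 0)
    stop("event rates must be >= 0", call. = FALSE)
  if (cfg$lights_on_h == cfg$lights_off_h)
    stop("lights_on_h and lights_off_h must differ", call. = FALSE)
  if (!all(STAGES %in% names(cfg$stage_mean_bout_s)))
    stop("`stage_mean_bout_s` must name all four stages", call. = FALSE)
  if (any(cfg$stage_mean_bout_s < 10))
    stop("mean bout durations must be >= the 10-s bout floor", call. = FALSE)
  if (cfg$spindle_freq < 10 || cfg$spindle_freq > 15)
    stop("spindle_freq must lie within the 10-15 Hz detection band", call. = FALSE)
  if (length(cfg$spindle_dur_s) != 2L || any(cfg$spindle_dur_s <= 0) ||
      diff(cfg$spindle_dur_s) < 0)
    stop("`spindle_dur_s` must be increasing positive (min, max)", call. = FALSE)
  if (cfg$ps_entry_prob < 0 || cfg$ps_entry_prob > 1)
    stop("`ps_entry_prob` must lie in [0, 1]", call. = FALSE)
  if (!all(cfg$allowed_stages %in% STAGES) || length(cfg$allowed_stages) < 1L)
    stop("`allowed_stages` must be a nonempty subset of the four stages",
         call. = FALSE)
  invisible(cfg)
}

#' Group effect multipliers for cohort simulation
#'
#' Describes how an "affected" group deviates from baseline: elevated delta,
#' fewer and shorter paradoxical-sleep bouts, fewer spindles, more spikes.
#' The paradoxical multiplier scales both the mean paradoxical bout duration
#' and the probability of entering paradoxical sleep from slow-wave sleep,
#' so time in paradoxical sleep falls and latency to it rises.
#'
#' @param delta_gain Multiplier on the delta-component gain.
#' @param paradoxical Multiplier on paradoxical dwell and entry probability.
#' @param spindle Multiplier on the spindle rate.
#' @param spike Multiplier on the spike rate.
#' @export
group_effect <- function(delta_gain = 1, paradoxical = 1, spindle = 1,
                         spike = 1) {
  structure(list(delta_gain = delta_gain, paradoxical = paradoxical,
                 spindle = spindle, spike = spike), class = "group_effect")
}

apply_group_effect <- function(cfg, eff) {
  cfg$delta_gain <- cfg$delta_gain * eff$delta_gain
  cfg$stage_mean_bout_s["paradoxical"] <-
    max(10, cfg$stage_mean_bout_s[["paradoxical"]] * eff$paradoxical)
  cfg$ps_entry_prob <- min(1, cfg$ps_entry_prob * eff$paradoxical)
  cfg$spindle_rate_per_min_sws <- cfg$spindle_rate_per_min_sws * eff$spindle
  cfg$spike_rate_per_h <- cfg$spike_rate_per_h * eff$spike
  cfg
}
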