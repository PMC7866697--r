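# The synthetic telemetry generator: schedule mechanics, signal
# signatures, injected events and cohort assembly.

test_that("stage schedule honours configured mean bout durations", {
  cfg <- sim_config(duration_h = 24,
                    stage_mean_bout_s = c(active_wake = 150, wake = 600,
                                          sws = 180, paradoxical = 60),
                    stage_dwell_bias_dark = 1, seed = 5)
  sched <- simulate_stage_schedule(cfg)
  expect_length(sched, 24 * 3600)
  b <- somnoscope:::schedule_bouts(sched)
  wake <- b[b$stage == "wake", ]
  wake <- wake[-nrow(wake), ]   # last bout may be truncated by the horizon
  expect_gte(nrow(wake), 50)
  emp <- mean(wake$end_s - wake$start_s)
  expect_lt(abs(emp - 600) / 600, 0.20)
})

test_that("degenerate and deterministic schedules behave as contracted", {
  cfg1 <- sim_config(duration_h = 10 / 3600, allowed_stages = "sws", seed = 1)
  expect_equal(simulate_stage_schedule(cfg1), rep("sws", 10))
  cfg <- sim_config(duration_h = 0.5, seed = 42)
  expect_identical(simulate_stage_schedule(cfg), simulate_stage_schedule(cfg))
  expect_error(simulate_stage_schedule(sim_config(duration_h = 24), seed = NA),
               "seed")
  expect_error(sim_config(duration_h = -1), "duration_h")
  expect_error(sim_config(lights_on_h = 5, lights_off_h = 5), "differ")
  expect_error(sim_config(spindle_freq = 20), "10-15")
})

test_that("paradoxical sleep is entered only from slow-wave sleep", {
  sched <- simulate_stage_schedule(sim_config(duration_h = 6, seed = 9))
  b <- somnoscope:::schedule_bouts(sched)
  pre <- b$stage[which(b$stage == "paradoxical") - 1L]
  expect_true(all(pre == "sws"))
})

test_that("wake dwell is inflated during the dark phase", {
  cfg <- sim_config(duration_h = 12, start_clock_h = 19,  # all dark
                    stage_dwell_bias_dark = 3, seed = 11)
  sched_d <- simulate_stage_schedule(cfg)
  cfg$start_clock_h <- 7                                   # all light
  sched_l <- simulate_stage_schedule(cfg)
  mean_bout <- function(s, st) {
    b <- somnoscope:::schedule_bouts(s)
    b <- b[b$stage == st, ]
    mean(b$end_s - b$start_s)
  }
  expect_gt(mean_bout(sched_d, "wake"), 1.5 * mean_bout(sched_l, "wake"))
})

test_that("synthesized recordings are deterministic with matching ground truth", {
  sim1 <- quick_sim(seed = 3)
  sim2 <- quick_sim(seed = 3)
  expect_identical(sim1$recording$eeg, sim2$recording$eeg)
  expect_identical(sim1$truth$spike_times_s, sim2$truth$spike_times_s)
  n_s <- length(sim1$truth$stage_per_second)
  expect_equal(length(sim1$recording$eeg), n_s * sim1$recording$eeg_fs)
  expect_equal(length(sim1$recording$activity), n_s * 200)
})

test_that("delta_gain monotonically raises Welch delta power", {
  cfg1 <- sim_config(duration_h = 300 / 3600, allowed_stages = "sws",
                     spike_rate_per_h = 0, spindle_rate_per_min_sws = 0,
                     delta_gain = 1, seed = 8)
  cfg2 <- cfg1; cfg2$delta_gain <- 2
  sched <- simulate_stage_schedule(cfg1)
  r1 <- synthesize_signals(sched, cfg1)$recording
  r2 <- synthesize_signals(sched, cfg2)$recording
  p1 <- band_power(welch_psd(r1$eeg, r1$eeg_fs), "delta")
  p2 <- band_power(welch_psd(r2$eeg, r2$eeg_fs), "delta")
  expect_gt(p2, p1)
})

test_that("stage signatures match the staging assumptions spectrally", {
  base <- list(duration_h = 600 / 3600, spike_rate_per_h = 0,
               spindle_rate_per_min_sws = 0, seed = 12)
  sws <- do.call(sim_config, c(base, list(allowed_stages = "sws")))
  par <- do.call(sim_config, c(base, list(allowed_stages = "paradoxical")))
  r_sws <- simulate_recording(sws)$recording
  r_par <- simulate_recording(par)$recording
  ps_sws <- welch_psd(preprocess_eeg(r_sws), r_sws$eeg_fs)
  ps_par <- welch_psd(preprocess_eeg(r_par), r_par$eeg_fs)
  # slow-wave EEG concentrates over half its 0.5-50 Hz power in delta
  expect_gt(band_power(ps_sws, "delta") /
            band_power(ps_sws, c(0.5, 50), closed_upper = TRUE), 0.5)
  # paradoxical EEG has more theta than delta power
  expect_gt(band_power(ps_par, "theta"), band_power(ps_par, "delta"))
})

test_that("event injection respects rates, stages and logging", {
  cfg <- sim_config(duration_h = 600 / 3600, spike_rate_per_h = 0, seed = 2)
  sim <- simulate_recording(cfg)
  expect_length(sim$truth$spike_times_s, 0)

  # Poisson-consistent spindle counts in pure slow-wave sleep, 2/min
  counts <- vapply(1:4, function(s) {
    cfg <- sim_config(duration_h = 600 / 3600, allowed_stages = "sws",
                      spindle_rate_per_min_sws = 2, seed = 100 + s)
    nrow(simulate_recording(cfg)$truth$spindle_intervals_s)
  }, numeric(1))
  lambda <- 2 * 10          # 10 min of slow-wave sleep at 2 per minute
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 4))

  # every injected spindle lies inside a true slow-wave second
  sim2 <- quick_sim(duration_h = 0.5, seed = 13)
  sp <- sim2$truth$spindle_intervals_s
  if (nrow(sp) > 0) {
    secs <- unlist(apply(sp, 1, function(iv)
      (floor(iv[1]) + 1L):min(ceiling(iv[2]), length(sim2$truth$stage_per_second))))
    expect_true(all(sim2$truth$stage_per_second[secs] == "sws"))
  }
  # spikes stay clear of active wake; activity is nonzero iff active wake
  st <- sim2$truth$stage_per_second[floor(sim2$truth$spike_times_s) + 1L]
  expect_false(any(st == "active_wake"))
  act_sec <- somnoscope:::per_second_rms(as.numeric(sim2$recording$activity), 200)
  expect_true(all((act_sec > 0) ==
                  (sim2$truth$stage_per_second == "active_wake")))
})

test_that("generate_cohort builds labelled deterministic cohorts", {
  cfg <- sim_config(duration_h = 120 / 3600, seed = 1)
  expect_error(generate_cohort(cfg, 0), "n_per_group")
  coh <- generate_cohort(cfg, n_per_group = c(2, 1), seed = 50)
  man <- attr(coh, "manifest")
  expect_equal(nrow(man), 3)
  expect_equal(man$group, c("control", "control", "affected"))
  expect_equal(man$seed, 50 + 1:3)
  coh2 <- generate_cohort(cfg, n_per_group = c(2, 1), seed = 50)
  expect_identical(coh[[3]]$recording$eeg, coh2[[3]]$recording$eeg)
  # the affected configuration carries the documented effect directions
  aff <- somnoscope:::apply_group_effect(cfg, group_effect(
    delta_gain = 2, paradoxical = 0.5, spindle = 0.5, spike = 3))
  expect_equal(aff$delta_gain, 2)
  expect_equal(aff$stage_mean_bout_s[["paradoxical"]],
               cfg$stage_mean_bout_s[["paradoxical"]] / 2)
  expect_equal(aff$ps_entry_prob, cfg$ps_entry_prob / 2)
  expect_equal(aff$spindle_rate_per_min_sws, 1)
  expect_equal(aff$spike_rate_per_h, 45)
})
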