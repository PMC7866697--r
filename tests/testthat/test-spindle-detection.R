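# Spindle detection: band filtering, envelope, cubing and thresholding.

test_that("spindle_band_filter passes 11 Hz and rejects 3 Hz by >= 24 dB", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  p <- spindle_params()
  y11 <- spindle_band_filter(sin(2 * pi * 11 * t), fs, p)
  expect_lt(abs(sd(y11) - sd(sin(2 * pi * 11 * t))) / sd(sin(2 * pi * 11 * t)),
            0.20)
  y3 <- spindle_band_filter(sin(2 * pi * 3 * t), fs, p)
  expect_lt(20 * log10(sd(y3) / sd(sin(2 * pi * 3 * t))), -24)
  expect_equal(spindle_band_filter(numeric(5000), fs, p), numeric(5000))
  expect_error(spindle_band_filter(numeric(1000), 40, p), "too low")
})

test_that("cube_signal amplifies burst-to-background contrast", {
  expect_equal(cube_signal(c(0, 1, 2)), c(0, 1, 8))
  env <- c(rep(1, 50), rep(2.5, 20), rep(1, 50))
  expect_true(all(diff(cube_signal(sort(env))) >= 0))
  snr <- function(e) mean(e[51:70]) / mean(e[c(1:50, 71:120)])
  expect_gt(snr(cube_signal(env)), snr(env))
  expect_error(cube_signal(c(-1, 2)), "non-negative")
})

test_that("detect_spindles applies dual thresholds and strict duration gates", {
  fs <- 100
  base <- rep(1, 60 * fs)
  # brute-force oracle for the threshold rule on an arbitrary envelope
  oracle <- function(env, p) {
    lo <- p$lower_mult * mean(env); hi <- p$upper_mult * mean(env)
    out <- NULL
    i <- 1
    while (i <= length(env)) {
      if (env[i] > lo) {
        j <- i
        while (j < length(env) && env[j + 1] > lo) j <- j + 1
        dur <- (j - i + 1) / fs
        if (dur > p$min_dur_s && dur < p$max_dur_s && max(env[i:j]) > hi)
          out <- rbind(out, c((i - 1) / fs, j / fs))
        i <- j + 1
      } else i <- i + 1
    }
    out
  }
  p <- spindle_params()
  mk <- function(dur_s, amp = 6) {
    env <- base
    m <- dur_s * fs
    env[1000 + seq_len(m)] <- amp * (1 + 0.2 * sin(pi * seq_len(m) / m))
    env
  }
  s1 <- detect_spindles(mk(1), fs, p)
  expect_equal(nrow(s1), 1)
  expect_lt(abs(s1$start_s - 10), 0.05)
  expect_true(s1$start_s < s1$peak_s & s1$peak_s < s1$end_s)
  expect_equal(nrow(detect_spindles(mk(0.3), fs, p)), 0)   # too short
  expect_equal(nrow(detect_spindles(mk(12), fs, p)), 0)    # too long
  expect_equal(nrow(detect_spindles(rep(0, 1000), fs, p)), 0)

  # oracle agreement on a noisy random envelope
  set.seed(5)
  env <- abs(rnorm(6000, 1, 0.5))^2
  got <- detect_spindles(env, fs, p)
  want <- oracle(env, p)
  expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want))
  if (!is.null(want)) {
    expect_equal(got$start_s, want[, 1])
    expect_equal(got$end_s, want[, 2])
  }
})

test_that("detection is invariant to global amplitude scaling", {
  cfg <- sim_config(duration_h = 600 / 3600, allowed_stages = "sws",
                    spike_rate_per_h = 0, seed = 33)
  sim <- simulate_recording(cfg)
  s1 <- find_spindles(sim$recording)
  rec10 <- sim$recording
  rec10$eeg <- rec10$eeg * 10
  s10 <- find_spindles(rec10)
  expect_equal(nrow(s1), nrow(s10))
  expect_equal(s1$start_s, s10$start_s, tolerance = 1e-9)
})

test_that("raising the upper threshold never increases the count", {
  cfg <- sim_config(duration_h = 600 / 3600, allowed_stages = "sws",
                    spike_rate_per_h = 0, seed = 34)
  sim <- simulate_recording(cfg)
  filt <- spindle_band_filter(sim$recording$eeg, 500)
  cubed <- cube_signal(rms_envelope(filt, 500, 750))
  n_prev <- Inf
  for (um in c(2, 3.5, 5, 8)) {
    p <- spindle_params(upper_mult = um)
    n <- nrow(detect_spindles(cubed, 500, p))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("spindle_metrics normalises by sleep time", {
  sp <- data.frame(start_s = 1:12, end_s = 2:13, peak_s = 1:12 + 0.5,
                   duration_s = 1)
  m <- spindle_metrics(sp, 2 * 3600)
  expect_equal(m$count, 12)
  expect_equal(m$count_per_sleep_hour, 6)
  m0 <- spindle_metrics(sp[0, ], 0)
  expect_equal(m0$count, 0)
  expect_equal(m0$count_per_sleep_hour, 0)
  expect_true(is.na(spindle_metrics(sp, 0)$count_per_sleep_hour))
})

test_that("anticorrelated delta and spindle rates yield a negative slope", {
  # animals whose delta gain rises as their spindle rate falls
  gains <- c(1, 1.4, 1.8, 2.2)
  rates <- c(3, 2.2, 1.4, 0.6)
  res <- t(vapply(seq_along(gains), function(i) {
    cfg <- sim_config(duration_h = 600 / 3600, allowed_stages = "sws",
                      delta_gain = gains[i],
                      spindle_rate_per_min_sws = rates[i],
                      spike_rate_per_h = 0, seed = 40 + i)
    sim <- simulate_recording(cfg)
    ps <- welch_psd(preprocess_eeg(sim$recording), 500)
    c(delta = delta_summary(ps)$total_delta,
      spindles = nrow(find_spindles(sim$recording)))
  }, numeric(2)))
  fit <- simple_regression(res[, "delta"], res[, "spindles"])
  expect_lt(fit$slope, 0)
})
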