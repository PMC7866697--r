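# Per-animal summary rows and the cohort comparison report.

#' Summarize one recording into a per-animal metrics row
#'
#' Runs the full analysis battery on a recording: Welch spectral summary
#' (band powers, total/relative delta) on the edge-trimmed, low-passed
#' EEG; spike counting (with its own edge trimming); sleep staging with
#' architecture metrics and per-cycle percent time; and spindle detection
#' with the count-per-sleep-hour rate.
#'
#' @param rec A [recording()].
#' @param trim_head_h,trim_tail_h Edge trimming (hours) for the spectral
#'   and spike analyses; use 0 for short recordings.
#' @param spike_par A [spike_params()] (its trim fields are overridden by
#'   the arguments above).
#' @param stage_par A [stage_rule_params()].
#' @param spindle_par A [spindle_params()].
#' @param scheme A [light_dark_scheme()].
#' @return One-row data frame (an animal-summary row).
#' @export
summarize_recording <- function(rec, trim_head_h = 3, trim_tail_h = 3,
                                spike_par = spike_params(),
                                stage_par = stage_rule_params(),
                                spindle_par = spindle_params(),
                                scheme = light_dark_scheme()) {
  spike_par$trim_head_h <- trim_head_h
  spike_par$trim_tail_h <- trim_tail_h

  trimmed <- if (trim_head_h > 0 || trim_tail_h > 0)
    trim_edges(rec, trim_head_h, trim_tail_h) else rec
  ps <- welch_psd(preprocess_eeg(trimmed), trimmed$eeg_fs)
  ds <- delta_summary(ps)
  bands <- vapply(names(band_scheme()), function(b) band_power(ps, b),
                  numeric(1))

  spk <- count_spikes(rec, spike_par)

  hyp <- stage_recording(rec, stage_par)
  sm <- sleep_metrics(hyp)
  cyc <- aggregate_cycles(bin_2h(hyp, scheme))
  pick <- function(c_, col) {
    v <- cyc[cyc$cycle == c_, col]
    if (length(v)) v else NA_real_
  }

  spin <- find_spindles(rec, spindle_par)
  smet <- spindle_metrics(spin, sm$total_sleep_s)

  out <- data.frame(
    subject_id = rec$subject_id, group_label = rec$group_label,
    hours = duration_s(rec) / 3600,
    total_delta = ds$total_delta, relative_delta = ds$relative_delta,
    total_power = ds$total_power,
    band_delta = bands[["delta"]], band_theta = bands[["theta"]],
    band_alpha = bands[["alpha"]], band_beta = bands[["beta"]],
    band_gamma = bands[["gamma"]],
    spike_count = spk$count, spike_rate_per_h = spk$rate_per_h,
    mean_bout_active_wake_s = sm$mean_bout_s[["active_wake"]],
    mean_bout_wake_s = sm$mean_bout_s[["wake"]],
    mean_bout_sws_s = sm$mean_bout_s[["sws"]],
    mean_bout_paradoxical_s = sm$mean_bout_s[["paradoxical"]],
    latency_s = sm$latency_s,
    latency_paradoxical_s = sm$latency_paradoxical_s,
    total_sleep_s = sm$total_sleep_s,
    spindle_count = smet$count,
    spindles_per_sleep_h = smet$count_per_sleep_hour,
    awake_percent_light = pick("light", "awake_percent"),
    awake_percent_dark = pick("dark", "awake_percent"),
    sws_percent_light = pick("light", "sws_percent"),
    sws_percent_dark = pick("dark", "sws_percent"),
    paradoxical_percent_light = pick("light", "paradoxical_percent"),
    paradoxical_percent_dark = pick("dark", "paradoxical_percent"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize a simulated cohort
#'
#' @param cohort List of `list(recording, truth)` from [generate_cohort()],
#'   or a plain list of recordings.
#' @param ... Passed to [summarize_recording()].
#' @return Animal-summary data frame, one row per animal.
#' @export
summarize_cohort <- function(cohort, ...) {
  rows <- lapply(cohort, function(el) {
    rec <- if (inherits(el, "recording")) el else el$recording
    summarize_recording(rec, ...)
  })
  do.call(rbind, rows)
}

#' Group-comparison report
#'
#' Builds the standard comparison tables from an animal-summary data
#' frame: group descriptives (mean and standard error per metric), pooled
#' Student t tests per metric between the first two groups, per-band power
#' tests with Holm-Sidak adjustment across the five bands, and the
#' delta-spindle regression.  When `out_dir` is given the tables are
#' written as CSV and simple summary figures as PNG.
#'
#' @param summaries Data frame from [summarize_cohort()].
#' @param out_dir Optional output directory.
#' @param alpha Significance level used for flagging (default 0.05).
#' @return List with `descriptives`, `tests`, `band_tests`,
#'   `delta_spindle` (invisible when writing to disk).
#' @export
build_report <- function(summaries, out_dir = NULL, alpha = 0.05) {
  groups <- unique(summaries$group_label)
  metrics <- setdiff(names(summaries)[vapply(summaries, is.numeric, TRUE)],
                     "hours")
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  desc <- do.call(rbind, lapply(groups, function(g) {
    d <- summaries[summaries$group_label == g, metrics, drop = FALSE]
    data.frame(group = g, metric = metrics,
               mean = vapply(d, mean, numeric(1), na.rm = TRUE),
               sem = vapply(d, se, numeric(1)),
               n = nrow(d), row.names = NULL)
  }))

  tests <- NULL
  band_tests <- NULL
  delta_spindle <- NULL
  if (length(groups) >= 2L) {
    ga <- summaries[summaries$group_label == groups[1], ]
    gb <- summaries[summaries$group_label == groups[2], ]
    tests <- do.call(rbind, lapply(metrics, function(m) {
      a <- ga[[m]]; b <- gb[[m]]
      if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2 ||
          (stats::var(a, na.rm = TRUE) == 0 && stats::var(b, na.rm = TRUE) == 0))
        return(NULL)
      tr <- two_sample_t(a, b)
      data.frame(metric = m, t = tr$statistic, df = tr$df, p = tr$p_value,
                 mean_a = tr$mean_a, mean_b = tr$mean_b,
                 significant = tr$p_value < alpha, row.names = NULL)
    }))
    bm <- paste0("band_", names(band_scheme()))
    if (all(bm %in% metrics) && !is.null(tests)) {
      band_tests <- tests[tests$metric %in% bm, , drop = FALSE]
      band_tests$p_adj <- holm_sidak_adjust(band_tests$p)
      band_tests$significant <- band_tests$p_adj < alpha
    }
    if (all(c("total_delta", "spindle_count") %in% names(summaries)) &&
        nrow(summaries) >= 3) {
      r <- try(simple_regression(summaries$total_delta,
                                 summaries$spindle_count), silent = TRUE)
      if (!inherits(r, "try-error")) delta_spindle <- as.data.frame(r)
    }
  }

  res <- list(descriptives = desc, tests = tests, band_tests = band_tests,
              delta_spindle = delta_spindle)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summaries, file.path(out_dir, "animal_summaries.csv"),
                     row.names = FALSE)
    for (nm in names(res)) if (!is.null(res[[nm]]))
      utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    report_figures(summaries, out_dir)
    return(invisible(res))
  }
  res
}

# Simple per-metric group dot plots, one panel per headline metric.
report_figures <- function(summaries, out_dir) {
  key <- c("total_delta", "relative_delta", "spike_count",
           "mean_bout_paradoxical_s", "total_sleep_s", "spindle_count",
           "spindles_per_sleep_h")
  key <- intersect(key, names(summaries))
  grp <- factor(summaries$group_label)
  grDevices::png(file.path(out_dir, "group_summaries.png"),
                 width = 1200, height = 800, res = 120)
  old <- graphics::par(mfrow = c(2, ceiling(length(key) / 2)),
                       mar = c(3, 4, 2, 1))
  # restore par while the png device is still current, then close it
  on.exit({ graphics::par(old); grDevices::dev.off() })
  for (m in key) {
    graphics::stripchart(summaries[[m]] ~ grp, vertical = TRUE,
                         method = "jitter", pch = 19, main = m, ylab = m)
    means <- tapply(summaries[[m]], grp, mean, na.rm = TRUE)
    graphics::points(seq_along(means), means, pch = "-", cex = 3, col = 2)
  }
}
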