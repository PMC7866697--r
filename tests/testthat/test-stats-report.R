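# Group statistics, event matching and report assembly.

test_that("two_sample_t reproduces the pooled Student t", {
  r0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- two_sample_t(a, b)
  o <- t.test(a, b, var.equal = TRUE)         # independent oracle
  expect_equal(r$statistic, unname(o$statistic))
  expect_equal(r$df, unname(o$parameter))
  expect_equal(r$p_value, o$p.value)
  # symmetry under group swap
  r2 <- two_sample_t(b, a)
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
  set.seed(3)
  x <- rnorm(8); y <- rnorm(6) + 1
  ow <- t.test(x, y)
  rw <- two_sample_t(x, y, welch = TRUE)
  expect_equal(rw$statistic, unname(ow$statistic))
  expect_equal(rw$df, unname(ow$parameter))
})

test_that("holm_sidak_adjust matches hand computation and its invariants", {
  expect_equal(holm_sidak_adjust(0.2), 0.2)
  expect_equal(holm_sidak_adjust(c(0, 0, 0)), c(0, 0, 0))
  got <- holm_sidak_adjust(c(0.01, 0.04))
  expect_equal(got, c(1 - (1 - 0.01)^2, max(1 - (1 - 0.01)^2, 0.04)))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("simple_regression matches lm and flags degenerate input", {
  r <- simple_regression(1:5, 2 * (1:5))
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  set.seed(5)
  x <- rnorm(20); y <- 1 + 0.5 * x + rnorm(20)
  r2 <- simple_regression(x, y)
  o <- summary(lm(y ~ x))                    # independent oracle
  expect_equal(r2$slope, unname(o$coefficients["x", "Estimate"]))
  expect_equal(r2$f, unname(o$fstatistic["value"]))
  expect_equal(r2$p_value, unname(o$coefficients["x", "Pr(>|t|)"]))
  expect_equal(r2$df2, 18)
  expect_error(simple_regression(rep(1, 5), rnorm(5)), "constant")
  expect_error(simple_regression(1:2, 1:2), "n >= 3")
})

test_that("flag_outliers flags gross outliers and nothing else", {
  f <- flag_outliers(c(1, 1.1, 0.9, 1.05, 50))
  expect_equal(which(f$flags), 5L)
  expect_equal(f$kept, c(1, 1.1, 0.9, 1.05))
  expect_false(any(flag_outliers(rep(2, 5))$flags))
  expect_false(any(flag_outliers(c(1, 1.001, 0.999))$flags))
  expect_error(flag_outliers(1:2), "n >= 3")
})

test_that("event and interval matching count one-to-one matches", {
  m <- match_events(c(1.00, 2.00, 9.00), c(1.02, 2.04, 3.00), tol_s = 0.05)
  expect_equal(m$n_matched, 2L)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(match_events(numeric(0), 1:3)$recall, 0)
  mi <- match_intervals(rbind(c(0, 1), c(5, 6)), rbind(c(0.4, 1.4), c(8, 9)))
  expect_equal(mi$n_matched, 1L)
  # a detection covering < 50% of the shorter interval does not match
  mi2 <- match_intervals(rbind(c(0, 1)), rbind(c(0.9, 1.9)))
  expect_equal(mi2$n_matched, 0L)
})

test_that("summarize_recording assembles a complete animal row", {
  sim <- quick_sim(duration_h = 0.25, seed = 55)
  row <- summarize_recording(sim$recording, trim_head_h = 0, trim_tail_h = 0)
  expect_equal(nrow(row), 1)
  key <- c("total_delta", "relative_delta", "total_power", "spike_count",
           "spindle_count", "total_sleep_s", "band_delta", "band_gamma")
  expect_true(all(key %in% names(row)))
  expect_true(all(!is.na(row[key])))
  expect_gt(row$relative_delta, 0)
  expect_lte(row$relative_delta, 1)
})

test_that("the full pipeline is deterministic end to end", {
  run <- function() {
    coh <- generate_cohort(sim_config(duration_h = 0.1, start_clock_h = 7),
                           n_per_group = 1, seed = 77)
    build_report(summarize_cohort(coh, trim_head_h = 0, trim_tail_h = 0))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$descriptives, r2$descriptives)
  expect_identical(r1$tests, r2$tests)
})

test_that("build_report produces descriptives, tests and files", {
  set.seed(6)
  mk_rows <- function(g, delta_shift) data.frame(
    subject_id = paste0(g, 1:5), group_label = g, hours = 1,
    total_delta = rnorm(5, 100 + delta_shift, 5),
    relative_delta = rnorm(5, 0.5, 0.02),
    band_delta = rnorm(5, 100 + delta_shift, 5),
    band_theta = rnorm(5, 20, 2), band_alpha = rnorm(5, 10, 1),
    band_beta = rnorm(5, 8, 1), band_gamma = rnorm(5, 5, 1),
    spindle_count = rpois(5, 50), spike_count = rpois(5, 100),
    total_sleep_s = rnorm(5, 1800, 100))
  summ <- rbind(mk_rows("control", 0), mk_rows("affected", 60))
  rep_ <- build_report(summ)
  expect_true(all(c("group", "metric", "mean", "sem") %in%
                  names(rep_$descriptives)))
  td <- rep_$tests[rep_$tests$metric == "total_delta", ]
  expect_true(td$significant)
  expect_equal(nrow(rep_$band_tests), 5)
  expect_true(all(rep_$band_tests$p_adj >= rep_$band_tests$p - 1e-12))
  # single group: descriptives only
  rep1 <- build_report(mk_rows("control", 0))
  expect_null(rep1$tests)
  expect_gt(nrow(rep1$descriptives), 0)
  # on-disk output
  out <- file.path(tempdir(), "report_test")
  build_report(summ, out_dir = out)
  expect_true(file.exists(file.path(out, "animal_summaries.csv")))
  expect_true(file.exists(file.path(out, "tests.csv")))
  expect_true(file.exists(file.path(out, "group_summaries.png")))
  unlink(out, recursive = TRUE)
})
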