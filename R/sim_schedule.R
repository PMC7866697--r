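# Semi-Markov sleep-stage schedule generator.

# Stage-to-stage transition kernel.  Paradoxical sleep is reachable only
# from slow-wave sleep; its entry probability is a config field so cohort
# effects can make paradoxical bouts rarer as well as shorter.
transition_probs <- function(cfg) {
  p_ps <- cfg$ps_entry_prob
  list(
    active_wake = c(wake = 1),
    wake = c(sws = 0.65, active_wake = 0.35),
    sws = c(paradoxical = p_ps,
            wake = (1 - p_ps) * 0.7,
            active_wake = (1 - p_ps) * 0.3),
    paradoxical = c(wake = 0.7, active_wake = 0.1, sws = 0.2)
  )
}

# Truncated-exponential bout dwell: 10-s floor plus an exponential excess
# with the configured mean, rounded to whole seconds.
draw_dwell_s <- function(mean_s) {
  floor_s <- 10
  if (mean_s <= floor_s) return(floor_s)
  max(floor_s, round(floor_s + stats::rexp(1, rate = 1 / (mean_s - floor_s))))
}

#' Simulate a per-second sleep-stage schedule
#'
#' Semi-Markov alternation of the four stages (active wake, wake, slow-wave
#' sleep, paradoxical sleep) with truncated-exponential bout dwell times of
#' the configured means.  Paradoxical sleep is entered only from slow-wave
#' sleep.  Wake-state dwell (wake and active wake) is inflated by
#' `stage_dwell_bias_dark` when the bout starts during a dark clock hour.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to the seed stored in `config`).
#' @return Character vector of stage codes, one per second
#'   (`duration_h * 3600` entries).
#' @export
simulate_stage_schedule <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n_s <- round(config$duration_h * 3600)
  if (n_s < 1L) stop("duration must be positive", call. = FALSE)
  allowed <- config$allowed_stages
  if (length(allowed) == 1L) return(rep(allowed, n_s))
  scheme <- light_dark_scheme(config$lights_on_h, config$lights_off_h)
  with_seed(seed, {
    out <- character(n_s)
    t <- 0L
    state <- if ("wake" %in% allowed) "wake" else allowed[1]
    probs <- transition_probs(config)
    while (t < n_s) {
      mean_s <- config$stage_mean_bout_s[[state]]
      if (state %in% c("wake", "active_wake")) {
        h <- clock_hour_of(t, config$start_clock_h)
        if (hour_cycle(h, scheme) == "dark")
          mean_s <- mean_s * config$stage_dwell_bias_dark
      }
      dwell <- min(draw_dwell_s(mean_s), n_s - t)
      out[(t + 1L):(t + dwell)] <- state
      t <- t + dwell
      p <- probs[[state]][names(probs[[state]]) %in% allowed]
      if (length(p) == 0L) p <- stats::setNames(1, setdiff(allowed, state)[1])
      state <- sample(names(p), 1L, prob = p)
    }
    out
  })
}

# (start_s, end_s, stage) table of the maximal bouts of a per-second schedule.
schedule_bouts <- function(schedule) {
  r <- rle(schedule)
  end <- cumsum(r$lengths)
  data.frame(stage = r$values, start_s = end - r$lengths, end_s = end,
             stringsAsFactors = FALSE)
}
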