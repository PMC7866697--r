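# Shared fixture builders.  All fixtures are generated in code; the only
# state they carry is the seed.

# A short mixed-stage simulation used by several suites.
quick_sim <- function(duration_h = 0.25, seed = 7, start_clock_h = 7, ...) {
  simulate_recording(sim_config(duration_h = duration_h, seed = seed,
                                start_clock_h = start_clock_h, ...))
}

# Epoch-level agreement between a hypnogram and the true per-second
# schedule, excluding epochs that contain a true stage transition.
epoch_agreement <- function(hyp, truth_schedule) {
  n <- length(hyp$labels)
  truth_ep <- vapply(seq_len(n), function(i) {
    s <- truth_schedule[((i - 1) * hyp$epoch_s + 1):(i * hyp$epoch_s)]
    if (length(unique(s)) == 1L) s[1] else NA_character_
  }, character(1))
  keep <- !is.na(truth_ep)
  mean(hyp$labels[keep] == truth_ep[keep])
}

# Hand-rolled hypnogram for metric tests.
make_hyp <- function(labels, epoch_s = 10, start_clock_h = 0) {
  structure(list(labels = labels, epoch_s = epoch_s,
                 start_clock_h = start_clock_h), class = "hypnogram")
}
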