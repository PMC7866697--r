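# Detector-evaluation helpers: match detected events against ground truth.

#' Match detected point events to true event times
#'
#' Greedy one-to-one matching by increasing time difference: a detected
#' time matches an unused true time when they differ by at most
#' `tol_s` seconds.
#'
#' @param detected_s,truth_s Numeric event times in seconds.
#' @param tol_s Matching tolerance (default 0.05 s).
#' @return List with `n_matched`, `recall`, `precision`.
#' @export
match_events <- function(detected_s, truth_s, tol_s = 0.05) {
  nd <- length(detected_s); nt <- length(truth_s)
  if (nd == 0L || nt == 0L)
    return(list(n_matched = 0L,
                recall = if (nt == 0L) NA_real_ else 0,
                precision = if (nd == 0L) NA_real_ else 0))
  dd <- abs(outer(detected_s, truth_s, `-`))
  used_d <- logical(nd); used_t <- logical(nt)
  n <- 0L
  ord <- order(dd)
  for (k in ord) {
    if (dd[k] > tol_s) break
    i <- (k - 1L) %% nd + 1L
    j <- (k - 1L) %/% nd + 1L
    if (used_d[i] || used_t[j]) next
    used_d[i] <- used_t[j] <- TRUE
    n <- n + 1L
  }
  list(n_matched = n, recall = n / nt, precision = n / nd)
}

#' Match detected intervals to true intervals by temporal overlap
#'
#' An interval pair matches when their overlap covers at least
#' `min_overlap` of the shorter interval; matching is greedy one-to-one by
#' decreasing overlap fraction.
#'
#' @param detected,truth Two-column matrices or data frames of
#'   `(start_s, end_s)`.
#' @param min_overlap Required overlap fraction of the shorter interval
#'   (default 0.5).
#' @return List with `n_matched`, `recall`, `precision`.
#' @export
match_intervals <- function(detected, truth, min_overlap = 0.5) {
  d <- as.matrix(detected)[, 1:2, drop = FALSE]
  t_ <- as.matrix(truth)[, 1:2, drop = FALSE]
  nd <- nrow(d); nt <- nrow(t_)
  if (nd == 0L || nt == 0L)
    return(list(n_matched = 0L,
                recall = if (nt == 0L) NA_real_ else 0,
                precision = if (nd == 0L) NA_real_ else 0))
  ov <- matrix(0, nd, nt)
  for (j in seq_len(nt)) {
    inter <- pmin(d[, 2], t_[j, 2]) - pmax(d[, 1], t_[j, 1])
    shorter <- pmin(d[, 2] - d[, 1], t_[j, 2] - t_[j, 1])
    ov[, j] <- ifelse(shorter > 0, pmax(inter, 0) / shorter, 0)
  }
  used_d <- logical(nd); used_t <- logical(nt)
  n <- 0L
  for (k in order(ov, decreasing = TRUE)) {
    if (ov[k] < min_overlap) break
    i <- (k - 1L) %% nd + 1L
    j <- (k - 1L) %/% nd + 1L
    if (used_d[i] || used_t[j]) next
    used_d[i] <- used_t[j] <- TRUE
    n <- n + 1L
  }
  list(n_matched = n, recall = n / nt, precision = n / nd)
}
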