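# Minimal EDF (European Data Format) reader/writer for EEG/EMG/ACT
# interchange.  EDF stores 16-bit samples with per-channel physical
# calibration; a write/read round trip is exact to one quantization step.
# Implemented here because no EDF package ships with this installation.

edf_pad <- function(x, width) {
  x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = "-")
}

edf_num <- function(x, width = 8L) {
  s <- sprintf("%.7g", x)
  if (nchar(s) > width) s <- sprintf("%.*g", width - 4L, x)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Channels are written as `EEG`, `EMG` and (when present) `ACT`, one data
#' record per second.  The recording duration is truncated to whole
#' seconds; physical ranges are symmetric around zero and sized to the
#' observed amplitude, so the quantization step is
#' `(physmax - physmin) / (digmax - digmin)`.  The subject id is stored in
#' the patient field and the group label in the recording field.
#'
#' @param rec A [recording()] with integer sampling rates.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  n_s <- floor(duration_s(rec))
  if (n_s < 1) stop("recording shorter than one EDF record", call. = FALSE)
  sigs <- list(list(label = "EEG", x = rec$eeg, fs = rec$eeg_fs,
                    dim = "uV"),
               list(label = "EMG", x = rec$emg, fs = rec$emg_fs,
                    dim = "uV"))
  if (!is.null(rec$activity))
    sigs <- c(sigs, list(list(label = "ACT", x = rec$activity,
                              fs = rec$activity_fs, dim = "count")))
  for (s in sigs)
    if (s$fs != round(s$fs)) stop("EDF needs integer sampling rates", call. = FALSE)
  ns <- length(sigs)

  start_sec <- round(rec$start_clock_h * 3600)
  hh <- start_sec %/% 3600; mm <- (start_sec %% 3600) %/% 60; ss <- start_sec %% 60

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr(paste0("group=", rec$group_label), 80)
  wr("01.01.00", 8)
  wr(sprintf("%02d.%02d.%02d", hh %% 24, mm, ss), 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr("", 44)
  wr(as.character(n_s), 8)
  wr("1", 8)
  wr(as.character(ns), 4)

  pmaxs <- vapply(sigs, function(s) {
    m <- max(abs(s$x), na.rm = TRUE)
    if (!is.finite(m) || m == 0) 1 else signif(m * 1.05, 6)
  }, numeric(1))
  for (s in sigs) wr(s$label, 16)
  for (s in sigs) wr("", 80)
  for (s in sigs) wr(s$dim, 8)
  for (k in seq_len(ns)) wr(edf_num(-pmaxs[k]), 8)
  for (k in seq_len(ns)) wr(edf_num(pmaxs[k]), 8)
  for (s in sigs) wr("-32768", 8)
  for (s in sigs) wr("32767", 8)
  for (s in sigs) wr("", 80)
  for (s in sigs) wr(as.character(s$fs), 8)
  for (s in sigs) wr("", 32)

  # re-read the header's printed physical ranges so writer and reader use
  # the identical calibration
  pr <- as.numeric(vapply(pmaxs, function(p) edf_num(p), character(1)))
  dig <- vector("list", ns)
  for (k in seq_len(ns)) {
    scale <- (2 * pr[k]) / 65535
    d <- round(sigs[[k]]$x[seq_len(n_s * sigs[[k]]$fs)] / scale)
    dig[[k]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  for (r in seq_len(n_s)) {
    for (k in seq_len(ns)) {
      fs <- sigs[[k]]$fs
      writeBin(dig[[k]][((r - 1L) * fs + 1L):(r * fs)], con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Requires `EEG` and `EMG` channels; `ACT` is optional.  The start clock
#' hour is reconstructed from the header start time and the subject/group
#' from the patient and recording fields when present.
#'
#' @param path EDF file path.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (header truncated)", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  patient <- rd(80)
  rec_field <- rd(80)
  rd(8)
  starttime <- rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1)
    stop("not an EDF file (bad header)", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  if (!all(c("EEG", "EMG") %in% labels))
    stop("EDF file must declare EEG and EMG channels", call. = FALSE)
  if (any(is.na(spr)) || any(spr <= 0) || is.na(rec_dur) || rec_dur <= 0)
    stop("inconsistent sampling declaration in EDF header", call. = FALSE)

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * sum(spr))
    stop("EDF data shorter than declared", call. = FALSE)
  sig <- vector("list", ns)
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  for (k in seq_len(ns)) {
    idx <- as.vector(outer(offs[k] + seq_len(spr[k]),
                           (seq_len(n_rec) - 1L) * per_rec, `+`))
    scale <- (pmax[k] - pmin[k]) / (dmax[k] - dmin[k])
    sig[[k]] <- (raw[idx] - dmin[k]) * scale + pmin[k]
  }
  names(sig) <- labels
  fs <- stats::setNames(spr / rec_dur, labels)

  tt <- suppressWarnings(as.numeric(strsplit(starttime, ".", fixed = TRUE)[[1]]))
  start_h <- if (length(tt) == 3 && !anyNA(tt))
    (tt[1] + tt[2] / 60 + tt[3] / 3600) %% 24 else 0
  group <- sub("^group=", "", rec_field)

  recording(eeg = sig$EEG, emg = sig$EMG, activity = sig$ACT,
            eeg_fs = fs[["EEG"]], emg_fs = fs[["EMG"]],
            activity_fs = if ("ACT" %in% labels) fs[["ACT"]] else 200,
            start_clock_h = start_h,
            subject_id = if (nzchar(patient)) patient else "s1",
            group_label = if (nzchar(group)) group else "none")
}
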