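# Minimal EDF (European Data Format) support: 16-bit integer encoding,
# ASCII headers, one continuous recording per file. Covers what single-trial
# EEG import needs; EDF+ annotations and discontinuous records are out of
# scope.

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write a multichannel recording as an EDF file
#'
#' Signals are scaled per channel to the 16-bit digital range, so writing is
#' lossy at roughly `max(abs(signal)) / 32767` absolute precision. The record
#' duration is 1 s; the recording length must therefore be a whole number of
#' seconds. Channels may have different sampling rates (samples are laid out
#' record by record, as the format prescribes).
#'
#' @param signals List of numeric vectors, one per channel (or a channels x
#'   samples matrix for a uniform rate).
#' @param fs Sampling rate(s) in Hz: scalar or one per channel.
#' @param path Output path.
#' @param channel_names Optional channel labels (<= 16 ASCII chars each).
#' @return `path`, invisibly.
#' @seealso [read_edf_trial()]
#' @export
write_edf <- function(signals, fs, path, channel_names = NULL) {
  if (is.matrix(signals)) {
    signals <- lapply(seq_len(nrow(signals)), function(i) signals[i, ])
  }
  ns <- length(signals)
  fs <- rep_len(as.numeric(fs), ns)
  if (is.null(channel_names)) channel_names <- default_channel_names(ns)
  secs <- vapply(seq_len(ns), function(i) length(signals[[i]]) / fs[i], numeric(1))
  if (max(abs(secs - round(secs[1L]))) > 1e-9) {
    abort_validation("all channels must span the same whole number of seconds")
  }
  n_rec <- as.integer(round(secs[1L]))
  spr <- as.integer(round(fs))

  pmax_ <- vapply(signals, function(x) max(abs(x), 1e-6), numeric(1))
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic subject", 80),
    edf_pad("synthetic recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (ns + 1L), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1L, 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) writeChar(paste0(edf_pad(vals, width), collapse = ""), con, eos = NULL)
  fld(channel_names, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(sprintf("%.6g", -pmax_), 8)
  fld(sprintf("%.6g", pmax_), 8)
  fld(rep(dig_min, ns), 8)
  fld(rep(dig_max, ns), 8)
  fld(rep("", ns), 80)
  fld(spr, 8)
  fld(rep("", ns), 32)

  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      x <- signals[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])]
      dig <- round((x + pmax_[i]) / (2 * pmax_[i]) * (dig_max - dig_min) + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  list(
    version = rd(8), patient = rd(80), recording = rd(80),
    startdate = rd(8), starttime = rd(8),
    header_bytes = as.integer(rd(8)), reserved = rd(44),
    n_records = as.integer(rd(8)), record_seconds = as.numeric(rd(8)),
    ns = as.integer(rd(4))
  )
}

#' Read a single-trial EDF recording
#'
#' Reads a continuous EDF record in which the resting-state baseline was
#' captured first: the first `baseline_seconds` become the baseline signal
#' and the remainder the trial signal. All channels must share one sampling
#' rate; EDF files mixing rates are rejected as unsupported.
#'
#' @param path Path to the EDF file.
#' @param subject_id,trial_id Identity assigned to the resulting trial.
#' @param baseline_seconds Leading seconds to treat as baseline; must be
#'   shorter than the recording.
#' @param ratings Named list/vector with `valence` and `arousal` in `[1, 9]`.
#' @return An [eeg_trial()].
#' @export
read_edf_trial <- function(path, subject_id, trial_id, baseline_seconds,
                           ratings) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: '%s'", path), class = "invbase_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  h <- read_edf_header(con)
  rd <- function(width, n) {
    vapply(seq_len(n), function(i) trimws(readChar(con, width, useBytes = TRUE)), character(1))
  }
  labels <- rd(16, h$ns); rd(80, h$ns); rd(8, h$ns)
  phys_min <- as.numeric(rd(8, h$ns)); phys_max <- as.numeric(rd(8, h$ns))
  dig_min <- as.numeric(rd(8, h$ns)); dig_max <- as.numeric(rd(8, h$ns))
  rd(80, h$ns)
  spr <- as.integer(rd(8, h$ns)); rd(32, h$ns)

  if (length(unique(spr)) != 1L) {
    abort_format(sprintf(
      "unsupported EDF: channels have mixed sampling rates (%s samples/record)",
      paste(unique(spr), collapse = ", ")
    ))
  }
  fs <- spr[1L] / h$record_seconds
  total_seconds <- h$n_records * h$record_seconds
  if (baseline_seconds >= total_seconds) {
    abort_validation(sprintf(
      "baseline_seconds (%g) must be shorter than the recording (%g s)",
      baseline_seconds, total_seconds
    ))
  }

  sig <- matrix(0, h$ns, h$n_records * spr[1L])
  for (r in seq_len(h$n_records)) {
    for (i in seq_len(h$ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      sig[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (dig - dig_min[i]) * gain + phys_min[i]
    }
  }

  nb <- as.integer(round(baseline_seconds * fs))
  eeg_trial(subject_id, trial_id, fs,
            trial_signal = sig[, (nb + 1L):ncol(sig), drop = FALSE],
            baseline_signal = sig[, seq_len(nb), drop = FALSE],
            ratings = ratings, channel_names = labels)
}
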