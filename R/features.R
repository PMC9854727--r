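#' Frequency band definitions
#'
#' The four classical EEG bands used for feature extraction, with integer Hz
#' edges: theta 3--7, alpha 8--13, beta 14--29, gamma 30--47. Bands must be
#' non-overlapping and ascending. A bin at frequency `f` belongs to band
#' `(f_lo, f_hi)` iff `f_lo <= f < f_hi + 1`: the half-open upper rule makes
#' the integer-edge bands tile `[3, 48)` so fractional-frequency bins (e.g.
#' 7.5 Hz on a 6 s grid) are never dropped between bands.
#'
#' @param bands A data frame with columns `name`, `f_lo`, `f_hi` (integer Hz).
#' @return A tibble of class `band_set`.
#' @export
band_set <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- tibble::tibble(
      name = c("theta", "alpha", "beta", "gamma"),
      f_lo = c(3L, 8L, 14L, 30L),
      f_hi = c(7L, 13L, 29L, 47L)
    )
  }
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("name", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo > bands$f_hi)) {
    abort_validation("each band needs f_lo <= f_hi")
  }
  if (is.unsorted(bands$f_lo, strictly = TRUE) ||
      any(utils::head(bands$f_hi, -1) + 1L > utils::tail(bands$f_lo, -1))) {
    abort_validation("bands must be ascending and non-overlapping")
  }
  class(bands) <- c("band_set", class(bands))
  bands
}

#' Map a frequency grid into band bin indices
#'
#' Returns, for each band, the indices of the grid bins it owns under the
#' `f_lo <= f < f_hi + 1` rule. A band falling entirely outside the grid gets
#' an empty slice (flagged by its zero length).
#'
#' @param freqs Ascending numeric frequency grid in Hz.
#' @param bands A [band_set()].
#' @return Named list of integer index vectors, one per band.
#' @export
band_slices <- function(freqs, bands = band_set()) {
  if (is.unsorted(freqs)) abort_validation("frequency grid must be ascending")
  out <- lapply(seq_len(nrow(bands)), function(i) {
    which(freqs >= bands$f_lo[i] & freqs < bands$f_hi[i] + 1)
  })
  names(out) <- bands$name
  out
}

#' Average consecutive slot spectra into fixed windows
#'
#' Groups `k = window_seconds / slot_seconds` consecutive slot spectra and
#' averages them bin-wise per channel, generalising the spectrum over the
#' window; trailing slots that do not fill a window are discarded. One window
#' later becomes one classifier data point.
#'
#' @param slot_spectra List of `eeg_spectrum` objects on a shared grid.
#' @param slot_seconds Slot length in seconds.
#' @param window_seconds Window length; must be a positive integer multiple
#'   of `slot_seconds`.
#' @return List of window `eeg_spectrum` objects (origin `"window"`, with
#'   `slot_index` reused as the 0-based window index).
#' @export
window_average <- function(slot_spectra, slot_seconds, window_seconds) {
  if (window_seconds < slot_seconds) {
    abort_validation("window_seconds must be >= slot_seconds")
  }
  k <- window_seconds / slot_seconds
  if (abs(k - round(k)) > 1e-9) {
    abort_validation("window_seconds must be an integer multiple of slot_seconds")
  }
  k <- as.integer(round(k))
  n_win <- length(slot_spectra) %/% k
  lapply(seq_len(n_win), function(w) {
    group <- slot_spectra[((w - 1L) * k + 1L):(w * k)]
    acc <- Reduce(`+`, lapply(group, `[[`, "magnitudes")) / k
    new_spectrum(acc, group[[1L]]$freqs, "window", w - 1L)
  })
}

#' Band-wise mean and variance features of a window spectrum
#'
#' For each channel and band, the mean and population variance (divisor =
#' bin count) of the magnitudes in the band's slice: 2 values per band, so 8
#' per channel with the default four bands.
#'
#' @param window An `eeg_spectrum` (typically a window average).
#' @param bands A [band_set()].
#' @return Numeric matrix, channels x (2 * n_bands); columns ordered
#'   band-major (`theta_mean`, `theta_variance`, `alpha_mean`, ...).
#' @export
band_features <- function(window, bands = band_set()) {
  slices <- band_slices(window$freqs, bands)
  empty <- names(slices)[lengths(slices) == 0L]
  if (length(empty) > 0L) {
    abort_validation(sprintf(
      "band(s) %s have no bins on this grid", paste(empty, collapse = ", ")
    ))
  }
  n_ch <- nrow(window$magnitudes)
  out <- matrix(0, n_ch, 2L * length(slices))
  cn <- character(2L * length(slices))
  for (i in seq_along(slices)) {
    m <- window$magnitudes[, slices[[i]], drop = FALSE]
    mu <- rowMeans(m)
    out[, 2L * i - 1L] <- mu
    out[, 2L * i] <- rowMeans(m^2) - mu^2
    cn[2L * i - 1L] <- paste0(names(slices)[i], "_mean")
    cn[2L * i] <- paste0(names(slices)[i], "_variance")
  }
  out[, seq(2L, ncol(out), by = 2L)] <-
    pmax(out[, seq(2L, ncol(out), by = 2L), drop = FALSE], 0)
  colnames(out) <- cn
  out
}

#' Binarize a 1--9 affective rating at 5.5
#'
#' Ratings below 5.5 map to the low class; 5.5 and above map to high (the
#' boundary rating is assigned to high so that low is exactly `[1, 5.5)`).
#'
#' @param r Numeric rating(s) in `[1, 9]`.
#' @return Character vector of `"low"` / `"high"`.
#' @export
binarize_rating <- function(r) {
  if (any(!is.finite(r) | r < 1 | r > 9)) {
    abort_validation("ratings must lie in [1, 9]")
  }
  ifelse(r < 5.5, "low", "high")
}

#' Extract the windowed band-power feature table from a dataset
#'
#' Runs the full pipeline per trial: slotting, FFT, the configured baseline
#' removal (the baseline spectrum is computed and aligned once per trial),
#' window averaging and band statistics. Each window becomes one row with
#' the flattened feature vector in canonical order: channel-major, band order
#' theta/alpha/beta/gamma, stat order mean/variance — 256 features for 32
#' channels. Labels come from binarizing the trial's ratings at 5.5, coded
#' `LV`/`HV` and `LA`/`HA`.
#'
#' @param dataset An [eeg_dataset()].
#' @param cfg A [removal_config()].
#' @param slot_seconds Slot length in seconds (default 6).
#' @param window_seconds Window length in seconds (default 12); integer
#'   multiple of `slot_seconds`.
#' @param bands A [band_set()].
#' @return A tibble with columns `subject_id`, `trial_id`, `window_index`,
#'   `valence_label`, `arousal_label`, then one column per feature named
#'   `<channel>_<band>_<stat>`.
#' @export
assemble_features <- function(dataset, cfg = removal_config(),
                              slot_seconds = 6, window_seconds = 12,
                              bands = band_set()) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  rows <- purrr::map(dataset$trials, function(tr) {
    slots <- segment_slots(tr, slot_seconds)
    spectra <- purrr::imap(slots, function(s, i) {
      compute_spectrum(s, tr$fs, slot_index = i - 1L)
    })
    base <- align_grids(baseline_spectrum(tr), spectra[[1L]]$freqs)
    removed <- purrr::map(spectra, remove_baseline, base = base, cfg = cfg)
    windows <- window_average(removed, slot_seconds, window_seconds)
    v <- binarize_rating(tr$ratings$valence)
    a <- binarize_rating(tr$ratings$arousal)
    purrr::map(windows, function(w) {
      feats <- band_features(w, bands)
      vec <- as.vector(t(feats))   # channel-major flattening
      names(vec) <- feature_names(dataset$channel_names, bands)
      c(
        list(subject_id = tr$subject_id, trial_id = tr$trial_id,
             window_index = w$slot_index,
             valence_label = if (v == "high") "HV" else "LV",
             arousal_label = if (a == "high") "HA" else "LA"),
        as.list(vec)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Canonical feature column names
#'
#' `<channel>_<band>_<stat>` in channel-major order with band order as given
#' and stats mean then variance.
#'
#' @param channel_names Ordered channel labels.
#' @param bands A [band_set()].
#' @return Character vector of length `channels * n_bands * 2`.
#' @export
feature_names <- function(channel_names, bands = band_set()) {
  unlist(lapply(channel_names, function(ch) {
    unlist(lapply(bands$name, function(b) paste(ch, b, c("mean", "variance"), sep = "_")))
  }))
}

#' Names of the feature columns present in a feature tibble
#'
#' Everything that is not one of the five metadata columns.
#'
#' @param records A feature tibble from [assemble_features()].
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(records) {
  setdiff(names(records),
          c("subject_id", "trial_id", "window_index",
            "valence_label", "arousal_label"))
}
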