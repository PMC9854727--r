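#' Baseline-removal configuration
#'
#' Chooses between the three baseline-removal strategies and fixes the
#' numerical parameters they share:
#'
#' * `invbase` — inverse filtering: the trial slot's magnitude spectrum is
#'   divided point-wise by the subject's resting-state baseline spectrum.
#'   Subject-specific multiplicative spectral gain cancels exactly, which is
#'   the mechanism behind subject-independent features.
#' * `subtractive` — the conventional correction: the baseline spectrum is
#'   subtracted from the slot spectrum (clipped at zero).
#' * `nbc` — no baseline correction; slot spectra pass through unchanged.
#'
#' @param method One of `"invbase"`, `"subtractive"`, `"nbc"`.
#' @param epsilon_rel Division floor for `invbase`, relative to each channel's
#'   maximum baseline magnitude; prevents blow-up at near-zero baseline bins
#'   without touching in-band values. Must lie in (0, 1).
#' @param analysis_band Length-2 numeric `(f_lo, f_hi)` in Hz; after removal
#'   the spectrum is restricted to bins with `f_lo <= f <= f_hi`. The default
#'   `c(3, 47)` spans the outer edges of the theta--gamma bands.
#' @param spectrum `"magnitude"` (default) operates on magnitude spectra;
#'   `"power"` squares magnitudes before removal. Division and the
#'   log-equivalence property are form-invariant under squaring.
#' @return A list of class `removal_config`.
#' @seealso [remove_baseline()], [assemble_features()]
#' @export
removal_config <- function(method = c("invbase", "subtractive", "nbc"),
                           epsilon_rel = 1e-8,
                           analysis_band = c(3, 47),
                           spectrum = c("magnitude", "power")) {
  method <- match.arg(method)
  spectrum <- match.arg(spectrum)
  if (!is.numeric(epsilon_rel) || length(epsilon_rel) != 1L ||
      epsilon_rel <= 0 || epsilon_rel >= 1) {
    abort_config("epsilon_rel must lie in (0, 1)")
  }
  if (length(analysis_band) != 2L || analysis_band[1] <= 0 ||
      analysis_band[1] >= analysis_band[2]) {
    abort_config("analysis_band must be (f_lo, f_hi) with 0 < f_lo < f_hi")
  }
  structure(
    list(method = method, epsilon_rel = epsilon_rel,
         analysis_band = as.numeric(analysis_band), spectrum = spectrum),
    class = "removal_config"
  )
}

new_spectrum <- function(magnitudes, freqs, origin, slot_index = NA_integer_) {
  structure(
    list(magnitudes = magnitudes, freqs = as.numeric(freqs),
         origin = origin, slot_index = slot_index),
    class = "eeg_spectrum"
  )
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf(
    "<eeg_spectrum:%s> %d ch x %d bins, %.3g-%.3g Hz\n",
    x$origin, nrow(x$magnitudes), length(x$freqs),
    min(x$freqs), max(x$freqs)
  ))
  invisible(x)
}

#' Split a trial into equal non-overlapping time slots
#'
#' The trial signal is cut into consecutive slots of `slot_seconds`; trailing
#' samples that do not fill a whole slot are discarded (floor semantics), so
#' the slot count is `floor(samples / slot_samples)`.
#'
#' @param trial An [eeg_trial()].
#' @param slot_seconds Positive slot length in seconds.
#' @return A list of channels x slot_samples matrices, in temporal order.
#' @export
segment_slots <- function(trial, slot_seconds) {
  stopifnot(inherits(trial, "eeg_trial"))
  slot_samples <- as.integer(round(slot_seconds * trial$fs))
  n <- ncol(trial$trial_signal)
  if (slot_samples < 1L) {
    abort_validation("slot_seconds is too small: it rounds to zero samples")
  }
  if (slot_samples > n) {
    abort_validation(sprintf(
      "slot of %d samples exceeds trial length of %d samples", slot_samples, n
    ))
  }
  n_slots <- n %/% slot_samples
  lapply(seq_len(n_slots), function(i) {
    trial$trial_signal[, ((i - 1L) * slot_samples + 1L):(i * slot_samples),
                       drop = FALSE]
  })
}

#' Magnitude spectrum of a time-domain segment
#'
#' Computes the one-sided discrete Fourier transform of each channel
#' (unnormalised forward convention) and discards phase. Bin `k` (0-based)
#' sits at frequency `k * fs / n` for `k = 0 ... floor(n/2)`.
#'
#' @param segment Numeric matrix, channels x n samples, n >= 2.
#' @param fs Sampling rate in Hz.
#' @param origin Origin tag stored on the result (default `"slot"`).
#' @param slot_index Optional slot index carried along.
#' @return An `eeg_spectrum` with non-negative magnitudes on the grid above.
#' @export
compute_spectrum <- function(segment, fs, origin = "slot",
                             slot_index = NA_integer_) {
  if (!is.matrix(segment)) segment <- matrix(segment, nrow = 1L)
  n <- ncol(segment)
  if (n < 2L) {
    abort_validation("segment must contain at least 2 samples")
  }
  n_keep <- n %/% 2L + 1L
  ft <- stats::mvfft(t(segment))          # n x channels, complex
  mags <- t(Mod(ft[seq_len(n_keep), , drop = FALSE]))
  freqs <- (seq_len(n_keep) - 1L) * fs / n
  new_spectrum(mags, freqs, origin, slot_index)
}

#' Baseline magnitude spectrum of a trial
#'
#' Applies [compute_spectrum()] to the full resting-state baseline segment
#' (3 s in the DEAP-style layout). This spectrum is the divisor of the
#' inverse-filter correction.
#'
#' @param trial An [eeg_trial()].
#' @return An `eeg_spectrum` with `origin = "baseline"`.
#' @export
baseline_spectrum <- function(trial) {
  stopifnot(inherits(trial, "eeg_trial"))
  compute_spectrum(trial$baseline_signal, trial$fs, origin = "baseline")
}

#' Interpolate a baseline spectrum onto a target frequency grid
#'
#' The slot and baseline segments generally have different lengths (e.g. a
#' 6 s slot against a 3 s baseline), so their DFT grids differ. Before
#' point-wise removal the baseline magnitudes are linearly interpolated onto
#' the slot grid; frequencies outside the baseline grid take the nearest-edge
#' value.
#'
#' @param base An `eeg_spectrum` (typically `origin = "baseline"`).
#' @param target_freqs Ascending numeric frequency grid in Hz.
#' @return An `eeg_spectrum` on `target_freqs` with the origin preserved.
#' @export
align_grids <- function(base, target_freqs) {
  stopifnot(inherits(base, "eeg_spectrum"))
  if (identical(as.numeric(target_freqs), base$freqs)) {
    return(base)
  }
  out <- t(apply(base$magnitudes, 1L, function(m) {
    stats::approx(base$freqs, m, xout = target_freqs, rule = 2)$y
  }))
  if (length(target_freqs) == 1L) out <- matrix(out, ncol = 1L)
  new_spectrum(out, target_freqs, base$origin, base$slot_index)
}

#' Inverse-filter baseline removal (spectral division)
#'
#' Divides the slot spectrum point-wise by the baseline spectrum, per channel
#' and bin. The divisor is floored at `epsilon_rel` times the channel's
#' maximum baseline magnitude; a channel whose baseline is identically zero
#' passes through unchanged with a warning.
#'
#' @param slot Slot `eeg_spectrum`.
#' @param base Baseline `eeg_spectrum` on the same grid (use [align_grids()]).
#' @param cfg A [removal_config()] with `method = "invbase"`.
#' @return The baseline-free `eeg_spectrum` on the slot grid.
#' @export
invbase_remove <- function(slot, base, cfg = removal_config("invbase")) {
  check_grids(slot, base)
  ch_max <- apply(base$magnitudes, 1L, max)
  denom <- base$magnitudes
  out <- slot$magnitudes
  live <- ch_max > 0
  if (any(!live)) {
    warning("baseline all-zero on ", sum(!live),
            " channel(s); passing those channels through undivided",
            call. = FALSE)
  }
  if (any(live)) {
    floor_m <- cfg$epsilon_rel * ch_max[live]
    d <- pmax(denom[live, , drop = FALSE],
              matrix(floor_m, sum(live), ncol(denom)))
    out[live, ] <- slot$magnitudes[live, , drop = FALSE] / d
  }
  new_spectrum(out, slot$freqs, "slot", slot$slot_index)
}

#' Subtractive baseline removal (spectral subtraction)
#'
#' The conventional correction: baseline magnitudes are subtracted from the
#' slot magnitudes element-wise and the result is clipped at zero so
#' magnitudes stay non-negative.
#'
#' @inheritParams invbase_remove
#' @param cfg A [removal_config()] with `method = "subtractive"`.
#' @return The corrected `eeg_spectrum`.
#' @export
subtractive_remove <- function(slot, base, cfg = removal_config("subtractive")) {
  check_grids(slot, base)
  out <- pmax(slot$magnitudes - base$magnitudes, 0)
  new_spectrum(out, slot$freqs, "slot", slot$slot_index)
}

#' Apply the configured baseline-removal method to one slot spectrum
#'
#' Dispatches on `cfg$method` (`nbc` passes the slot through), aligning the
#' baseline onto the slot grid first when needed, then restricts the result
#' to the analysis band (`f_lo <= f <= f_hi`). With `cfg$spectrum = "power"`
#' both spectra are squared before removal.
#'
#' @inheritParams invbase_remove
#' @param cfg A [removal_config()].
#' @return An `eeg_spectrum` restricted to the analysis band.
#' @export
remove_baseline <- function(slot, base, cfg) {
  stopifnot(inherits(cfg, "removal_config"))
  if (cfg$spectrum == "power") {
    slot <- new_spectrum(slot$magnitudes^2, slot$freqs, slot$origin, slot$slot_index)
    base <- new_spectrum(base$magnitudes^2, base$freqs, base$origin, base$slot_index)
  }
  out <- switch(
    cfg$method,
    nbc = slot,
    invbase = invbase_remove(slot, align_grids(base, slot$freqs), cfg),
    subtractive = subtractive_remove(slot, align_grids(base, slot$freqs), cfg),
    abort_config(sprintf("unknown removal method '%s'", cfg$method))
  )
  restrict_band(out, cfg$analysis_band)
}

restrict_band <- function(spec, band) {
  keep <- spec$freqs >= band[1] & spec$freqs <= band[2]
  new_spectrum(spec$magnitudes[, keep, drop = FALSE], spec$freqs[keep],
               spec$origin, spec$slot_index)
}

check_grids <- function(slot, base) {
  if (length(slot$freqs) != length(base$freqs) ||
      max(abs(slot$freqs - base$freqs)) > 1e-9) {
    rlang::abort("slot and baseline grids differ; align_grids() must run first",
                 class = "invbase_internal_error")
  }
  invisible(TRUE)
}
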