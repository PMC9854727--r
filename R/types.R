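#' Construct a single EEG trial
#'
#' An `eeg_trial` bundles one stimulus presentation: the trial signal recorded
#' while the stimulus played, the resting-state baseline segment recorded just
#' before it, the subject's valence/arousal self-ratings, and identity
#' metadata. Signals are channels-by-samples matrices of amplitudes in
#' microvolts; both signals must share the channel count and order.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param trial_id Non-negative integer trial index within the subject.
#' @param fs Sampling rate in Hz (> 0), shared by trial and baseline.
#' @param trial_signal Numeric matrix, channels x samples.
#' @param baseline_signal Numeric matrix, channels x baseline samples.
#' @param ratings Named numeric vector or list with elements `valence` and
#'   `arousal`, each in `[1, 9]`.
#' @param channel_names Character vector of channel labels, one per row of
#'   `trial_signal`. Defaults to `Ch01`, `Ch02`, ...
#' @return An object of class `eeg_trial`.
#' @seealso [eeg_dataset()], [generate_trial()]
#' @export
eeg_trial <- function(subject_id, trial_id, fs, trial_signal, baseline_signal,
                      ratings, channel_names = NULL) {
  if (!is.matrix(trial_signal) || !is.matrix(baseline_signal)) {
    abort_validation("trial_signal and baseline_signal must be channels x samples matrices")
  }
  if (nrow(trial_signal) != nrow(baseline_signal)) {
    abort_validation(sprintf(
      "channel mismatch: trial has %d channels, baseline has %d",
      nrow(trial_signal), nrow(baseline_signal)
    ))
  }
  if (ncol(trial_signal) < 1L || ncol(baseline_signal) < 1L) {
    abort_validation("trial and baseline signals must contain at least one sample")
  }
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort_validation("fs must be a single positive number (Hz)")
  }
  ratings <- as.list(ratings)
  for (axis in c("valence", "arousal")) {
    r <- ratings[[axis]]
    if (is.null(r) || !is.finite(r) || r < 1 || r > 9) {
      abort_validation(sprintf(
        "rating '%s' must lie in [1, 9]; got %s (subject %s, trial %s)",
        axis, if (is.null(r)) "nothing" else format(r), subject_id, trial_id
      ))
    }
  }
  if (is.null(channel_names)) {
    channel_names <- default_channel_names(nrow(trial_signal))
  }
  if (length(channel_names) != nrow(trial_signal)) {
    abort_validation("channel_names length must equal the channel count")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      trial_id = as.integer(trial_id),
      fs = fs,
      trial_signal = trial_signal,
      baseline_signal = baseline_signal,
      ratings = list(valence = as.numeric(ratings$valence),
                     arousal = as.numeric(ratings$arousal)),
      channel_names = as.character(channel_names)
    ),
    class = "eeg_trial"
  )
}

default_channel_names <- function(n) sprintf("Ch%02d", seq_len(n))

#' Construct an EEG dataset
#'
#' A homogeneous collection of [eeg_trial()] objects: all trials must share
#' the sampling rate, channel count and order, trial duration and baseline
#' duration, and the (subject, trial) identity pairs must be unique. This is
#' the container the whole pipeline operates on.
#'
#' @param trials List of `eeg_trial` objects.
#' @return An object of class `eeg_dataset` with elements `trials`, `fs`,
#'   `n_channels` and `channel_names`.
#' @export
eeg_dataset <- function(trials) {
  if (length(trials) == 0L) {
    abort_validation("an eeg_dataset needs at least one trial")
  }
  if (!all(vapply(trials, inherits, logical(1), "eeg_trial"))) {
    abort_validation("all elements of `trials` must be eeg_trial objects")
  }
  ref <- trials[[1L]]
  for (tr in trials) {
    if (tr$fs != ref$fs) {
      abort_validation("all trials must share one sampling rate")
    }
    if (nrow(tr$trial_signal) != nrow(ref$trial_signal) ||
        !identical(tr$channel_names, ref$channel_names)) {
      abort_validation("all trials must share channel count and channel order")
    }
    if (ncol(tr$trial_signal) != ncol(ref$trial_signal) ||
        ncol(tr$baseline_signal) != ncol(ref$baseline_signal)) {
      abort_validation("all trials must share trial and baseline durations")
    }
  }
  keys <- vapply(trials, function(tr) paste(tr$subject_id, tr$trial_id), character(1))
  if (anyDuplicated(keys)) {
    abort_validation("(subject_id, trial_id) pairs must be unique")
  }
  structure(
    list(
      trials = trials,
      fs = ref$fs,
      n_channels = nrow(ref$trial_signal),
      channel_names = ref$channel_names
    ),
    class = "eeg_dataset"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf(
    "<eeg_trial> subject %s, trial %d: %d ch x %d samples @ %g Hz (baseline %d), valence %.1f arousal %.1f\n",
    x$subject_id, x$trial_id, nrow(x$trial_signal), ncol(x$trial_signal),
    x$fs, ncol(x$baseline_signal), x$ratings$valence, x$ratings$arousal
  ))
  invisible(x)
}

#' @export
print.eeg_dataset <- function(x, ...) {
  subs <- unique(vapply(x$trials, `[[`, character(1), "subject_id"))
  cat(sprintf(
    "<eeg_dataset> %d trials, %d subjects, %d channels @ %g Hz\n",
    length(x$trials), length(subs), x$n_channels, x$fs
  ))
  invisible(x)
}

#' Summarise a dataset as a tibble of trial metadata
#'
#' One row per trial: subject, trial id, ratings and durations. Handy for
#' piping into dplyr.
#'
#' @param x An `eeg_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per trial.
#' @export
tidy.eeg_dataset <- function(x, ...) {
  purrr::map_dfr(x$trials, function(tr) {
    tibble::tibble(
      subject_id = tr$subject_id,
      trial_id = tr$trial_id,
      valence = tr$ratings$valence,
      arousal = tr$ratings$arousal,
      trial_seconds = ncol(tr$trial_signal) / tr$fs,
      baseline_seconds = ncol(tr$baseline_signal) / tr$fs
    )
  })
}

# -- error helpers ------------------------------------------------------------

abort_validation <- function(msg) {
  rlang::abort(msg, class = "invbase_validation_error")
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "invbase_format_error")
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "invbase_config_error")
}
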