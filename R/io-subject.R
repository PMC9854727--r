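#' Write a single-subject dataset to an HDF5 container
#'
#' One file per subject, mirroring the trials x channels x samples layout of
#' DEAP-style distributions: datasets `trial_data` (T x C x S), `baseline_data`
#' (T x C x B), `ratings` (T x 2, valence then arousal), scalar `fs`,
#' `channel_names`, plus `subject_id` and `trial_ids` so a read round-trips
#' exactly.
#'
#' @param dataset An [eeg_dataset()] whose trials all belong to one subject.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [read_subject_file()]
#' @export
write_subject_file <- function(dataset, path) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  subs <- unique(vapply(dataset$trials, `[[`, character(1), "subject_id"))
  if (length(subs) != 1L) {
    abort_validation("write_subject_file expects a single-subject dataset (one file per subject)")
  }
  n_t <- length(dataset$trials)
  n_c <- dataset$n_channels
  n_s <- ncol(dataset$trials[[1L]]$trial_signal)
  n_b <- ncol(dataset$trials[[1L]]$baseline_signal)
  trial_data <- array(0, c(n_t, n_c, n_s))
  baseline_data <- array(0, c(n_t, n_c, n_b))
  ratings <- matrix(0, n_t, 2L)
  for (i in seq_len(n_t)) {
    tr <- dataset$trials[[i]]
    trial_data[i, , ] <- tr$trial_signal
    baseline_data[i, , ] <- tr$baseline_signal
    ratings[i, ] <- c(tr$ratings$valence, tr$ratings$arousal)
  }
  if (file.exists(path)) file.remove(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (isFALSE(ok)) {
    rlang::abort(sprintf("cannot create file '%s'", path), class = "invbase_io_error")
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(trial_data, path, "trial_data")
  rhdf5::h5write(baseline_data, path, "baseline_data")
  rhdf5::h5write(ratings, path, "ratings")
  rhdf5::h5write(dataset$fs, path, "fs")
  rhdf5::h5write(dataset$channel_names, path, "channel_names")
  rhdf5::h5write(subs, path, "subject_id")
  rhdf5::h5write(vapply(dataset$trials, `[[`, integer(1), "trial_id"),
                 path, "trial_ids")
  invisible(path)
}

#' Read a subject file written by [write_subject_file()]
#'
#' Validates the container against the trial invariants instead of silently
#' coercing: a missing dataset is a format error naming the missing field, a
#' channel-axis mismatch between trial and baseline arrays or a rating
#' outside `[1, 9]` is a validation error (the latter lists the offending
#' trials). Trial order is preserved.
#'
#' @param path Path to the HDF5 subject file.
#' @return An [eeg_dataset()].
#' @export
read_subject_file <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: '%s'", path), class = "invbase_io_error")
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- rhdf5::h5ls(path)$name
  for (field in c("trial_data", "baseline_data", "ratings", "fs", "channel_names")) {
    if (!field %in% present) {
      abort_format(sprintf("subject file is missing dataset '%s'", field))
    }
  }
  trial_data <- rhdf5::h5read(path, "trial_data")
  baseline_data <- rhdf5::h5read(path, "baseline_data")
  ratings <- rhdf5::h5read(path, "ratings")
  fs <- as.numeric(rhdf5::h5read(path, "fs"))
  channel_names <- as.character(rhdf5::h5read(path, "channel_names"))
  subject_id <- if ("subject_id" %in% present) {
    as.character(rhdf5::h5read(path, "subject_id"))[1L]
  } else {
    sub("\\.[^.]*$", "", basename(path))
  }
  trial_ids <- if ("trial_ids" %in% present) {
    as.integer(rhdf5::h5read(path, "trial_ids"))
  } else {
    seq_len(dim(trial_data)[1L]) - 1L
  }

  if (length(dim(trial_data)) != 3L || length(dim(baseline_data)) != 3L) {
    abort_validation("trial_data and baseline_data must be 3-D (trials x channels x samples)")
  }
  if (dim(trial_data)[1L] != dim(baseline_data)[1L] ||
      dim(trial_data)[2L] != dim(baseline_data)[2L]) {
    abort_validation(sprintf(
      "trial_data (%s) and baseline_data (%s) disagree on trial/channel axes",
      paste(dim(trial_data), collapse = "x"),
      paste(dim(baseline_data), collapse = "x")
    ))
  }
  ratings <- matrix(as.numeric(ratings), nrow = dim(trial_data)[1L])
  bad <- which(apply(ratings, 1L, function(r) any(!is.finite(r) | r < 1 | r > 9)))
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "ratings outside [1, 9] for trial index(es): %s",
      paste(bad - 1L, collapse = ", ")
    ))
  }

  trials <- lapply(seq_len(dim(trial_data)[1L]), function(i) {
    eeg_trial(
      subject_id, trial_ids[i], fs,
      matrix(trial_data[i, , ], dim(trial_data)[2L], dim(trial_data)[3L]),
      matrix(baseline_data[i, , ], dim(baseline_data)[2L], dim(baseline_data)[3L]),
      ratings = list(valence = ratings[i, 1L], arousal = ratings[i, 2L]),
      channel_names = channel_names
    )
  })
  eeg_dataset(trials)
}
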