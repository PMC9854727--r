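test_that("trial and dataset constructors enforce the invariants", {
  expect_s3_class(tiny_trial(), "eeg_trial")
  expect_error(tiny_trial(valence = 0.5), "valence",
               class = "invbase_validation_error")
  expect_error(
    eeg_trial("S01", 0, 128, matrix(0, 2, 10), matrix(0, 3, 5),
              list(valence = 5, arousal = 5)),
    "channel", class = "invbase_validation_error"
  )
  expect_error(eeg_dataset(list()), class = "invbase_validation_error")

  t1 <- tiny_trial(trial_id = 0)
  t2 <- tiny_trial(trial_id = 1); t2$fs <- 256
  expect_error(eeg_dataset(list(t1, t2)), "sampling rate",
               class = "invbase_validation_error")
  expect_error(eeg_dataset(list(t1, t1)), "unique",
               class = "invbase_validation_error")
})

test_that("subject files round-trip bit-exactly through HDF5", {
  ds <- tiny_dataset(n_trials = 3)
  path <- withr::local_tempfile(fileext = ".h5")
  write_subject_file(ds, path)
  back <- read_subject_file(path)
  expect_identical(length(back$trials), 3L)
  for (i in 1:3) {
    expect_identical(back$trials[[i]]$trial_signal, ds$trials[[i]]$trial_signal)
    expect_identical(back$trials[[i]]$baseline_signal,
                     ds$trials[[i]]$baseline_signal)
    expect_identical(back$trials[[i]]$ratings, ds$trials[[i]]$ratings)
    expect_identical(back$trials[[i]]$subject_id, ds$trials[[i]]$subject_id)
    expect_identical(back$trials[[i]]$trial_id, ds$trials[[i]]$trial_id)
  }
  expect_identical(back$channel_names, ds$channel_names)
  expect_identical(back$fs, ds$fs)
})

test_that("reading a DEAP-shaped container passes shapes through", {
  path <- withr::local_tempfile(fileext = ".h5")
  withr::with_seed(1, {
    rhdf5::h5createFile(path)
    rhdf5::h5write(array(rnorm(2 * 32 * 7680), c(2, 32, 7680)), path, "trial_data")
    rhdf5::h5write(array(rnorm(2 * 32 * 384), c(2, 32, 384)), path, "baseline_data")
    rhdf5::h5write(matrix(c(2, 7, 8, 3), 2), path, "ratings")
    rhdf5::h5write(128, path, "fs")
    rhdf5::h5write(sprintf("EEG%02d", 1:32), path, "channel_names")
    rhdf5::h5closeAll()
  })
  ds <- read_subject_file(path)
  expect_identical(length(ds$trials), 2L)
  expect_identical(ds$n_channels, 32L)
  expect_identical(ncol(ds$trials[[1]]$trial_signal), 7680L)
  expect_identical(ncol(ds$trials[[1]]$baseline_signal), 384L)
  expect_identical(ds$channel_names[1], "EEG01")
})

test_that("malformed subject files are rejected with named problems", {
  # missing ratings dataset
  p1 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(p1)
  rhdf5::h5write(array(0, c(1, 2, 8)), p1, "trial_data")
  rhdf5::h5write(array(0, c(1, 2, 4)), p1, "baseline_data")
  rhdf5::h5write(8, p1, "fs")
  rhdf5::h5write(c("a", "b"), p1, "channel_names")
  rhdf5::h5closeAll()
  expect_error(read_subject_file(p1), "ratings",
               class = "invbase_format_error")

  # channel-axis mismatch between trial and baseline arrays
  p2 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(p2)
  rhdf5::h5write(array(0, c(1, 2, 8)), p2, "trial_data")
  rhdf5::h5write(array(0, c(1, 3, 4)), p2, "baseline_data")
  rhdf5::h5write(matrix(c(5, 5), 1), p2, "ratings")
  rhdf5::h5write(8, p2, "fs")
  rhdf5::h5write(c("a", "b"), p2, "channel_names")
  rhdf5::h5closeAll()
  expect_error(read_subject_file(p2), class = "invbase_validation_error")

  # rating out of [1, 9] cites the trial index
  p3 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(p3)
  rhdf5::h5write(array(0, c(2, 2, 8)), p3, "trial_data")
  rhdf5::h5write(array(0, c(2, 2, 4)), p3, "baseline_data")
  rhdf5::h5write(matrix(c(5, 0.5, 5, 5), 2), p3, "ratings")
  rhdf5::h5write(8, p3, "fs")
  rhdf5::h5write(c("a", "b"), p3, "channel_names")
  rhdf5::h5closeAll()
  expect_error(read_subject_file(p3), "trial index",
               class = "invbase_validation_error")
})

test_that("write_subject_file refuses multi-subject datasets", {
  ds <- eeg_dataset(list(tiny_trial(subject_id = "A"),
                         tiny_trial(subject_id = "B")))
  expect_error(write_subject_file(ds, tempfile()), "single-subject",
               class = "invbase_validation_error")
})

test_that("EDF trials split baseline and trial by duration arithmetic", {
  path <- withr::local_tempfile(fileext = ".edf")
  withr::with_seed(8, {
    sig <- matrix(rnorm(2 * 63 * 128, sd = 20), 2)
    write_edf(sig, fs = 128, path = path, channel_names = c("Fp1", "Fp2"))
  })
  tr <- read_edf_trial(path, "S05", 3L, baseline_seconds = 3,
                       ratings = list(valence = 6, arousal = 2))
  expect_identical(ncol(tr$baseline_signal), 384L)
  expect_identical(ncol(tr$trial_signal), 7680L)
  expect_identical(tr$fs, 128)
  expect_identical(tr$channel_names, c("Fp1", "Fp2"))

  # 16-bit quantisation bounds the round-trip error
  sig2 <- withr::with_seed(8, matrix(rnorm(2 * 63 * 128, sd = 20), 2))
  recon <- cbind(tr$baseline_signal, tr$trial_signal)
  expect_lt(max(abs(recon - sig2)), 2 * max(abs(sig2)) / 65535 + 1e-9)

  expect_error(
    read_edf_trial(path, "S05", 3L, baseline_seconds = 63,
                   ratings = list(valence = 6, arousal = 2)),
    class = "invbase_validation_error"
  )
})

test_that("EDF files with mixed sampling rates are unsupported", {
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(list(sin(seq_len(2 * 128) / 5), sin(seq_len(2 * 256) / 9)),
            fs = c(128, 256), path = path)
  expect_error(
    read_edf_trial(path, "S01", 0L, 1, list(valence = 5, arousal = 5)),
    "mixed sampling", class = "invbase_format_error"
  )
})

test_that("feature tables round-trip through CSV", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 5,
                      n_channels = 32, trial_seconds = 12, seed = 4)
  rec <- assemble_features(generate_dataset(cfg), removal_config(), 6, 12)
  expect_identical(nrow(rec), 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(rec, path)

  lines <- readLines(path)
  expect_length(lines, 6L)                                   # header + 5
  expect_identical(length(strsplit(lines[1], ",")[[1]]), 261L)  # 5 meta + 256

  back <- read_feature_table(path)
  expect_identical(names(back), names(rec))
  m0 <- as.matrix(rec[feature_cols(rec)])
  m1 <- as.matrix(back[feature_cols(back)])
  expect_lt(max(abs(m1 - m0) / pmax(abs(m0), 1e-300)), 1e-9)

  # empty table: header-only CSV
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(rec[0, ], p2)
  expect_length(readLines(p2), 1L)

  expect_error(write_feature_table(dplyr::select(rec, -valence_label), path),
               "valence_label", class = "invbase_validation_error")
})
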