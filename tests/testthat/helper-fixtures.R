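# Shared fixtures, all generated in code.

# A small valid trial: white noise, optionally deterministic.
tiny_trial <- function(subject_id = "S01", trial_id = 0L, n_channels = 2L,
                       fs = 32, trial_seconds = 4, baseline_seconds = 1,
                       valence = 3, arousal = 8, seed = 42) {
  withr::with_seed(seed, {
    eeg_trial(
      subject_id, trial_id, fs,
      trial_signal = matrix(rnorm(n_channels * fs * trial_seconds),
                            n_channels),
      baseline_signal = matrix(rnorm(n_channels * fs * baseline_seconds),
                               n_channels),
      ratings = list(valence = valence, arousal = arousal)
    )
  })
}

tiny_dataset <- function(n_trials = 4L, ...) {
  eeg_dataset(lapply(seq_len(n_trials) - 1L, function(i) {
    tiny_trial(trial_id = i, valence = if (i %% 2) 8 else 3,
               arousal = if (i %% 2) 8 else 3, seed = 100 + i, ...)
  }))
}

# A spectrum object straight from values, for operation-level tests.
spectrum_of <- function(mags, freqs, origin = "slot") {
  invbase:::new_spectrum(as.matrix(mags), freqs, origin)
}

# Build a real signal whose n-point DFT has the prescribed one-sided
# magnitudes (zero phase), n even; mags has length n/2 + 1 (DC..Nyquist).
signal_from_magnitudes <- function(mags, n) {
  full <- complex(real = numeric(n))
  full[1] <- mags[1]
  nh <- n %/% 2
  full[2:(nh + 1)] <- mags[2:(nh + 1)]
  full[n:(nh + 2)] <- mags[2:nh]
  Re(fft(full, inverse = TRUE)) / n
}

# Feature records with two planted Gaussian classes, for classifier tests.
gaussian_records <- function(n_per_class = 30L, n_subjects = 2L, shift = 6,
                             sd = 1, seed = 7, n_features = 4L) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    cls <- rep(c("low", "high"), each = n_per_class)
    x <- matrix(rnorm(n * n_features, sd = sd), n)
    x[cls == "high", ] <- x[cls == "high", ] + shift
    d <- tibble::tibble(
      subject_id = rep_len(sprintf("S%02d", seq_len(n_subjects)), n),
      trial_id = seq_len(n) - 1L,
      window_index = 0L,
      valence_label = ifelse(cls == "high", "HV", "LV"),
      arousal_label = ifelse(cls == "high", "HA", "LA")
    )
    feat <- tibble::as_tibble(as.data.frame(x))
    names(feat) <- sprintf("Ch01_f%d_mean", seq_len(n_features))
    dplyr::bind_cols(d, feat)
  })
}
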