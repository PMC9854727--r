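#' Synthetic EEG study configuration
#'
#' Describes a DEAP-shaped synthetic study in which every trial obeys the
#' multiplicative degradation model underlying inverse-filter baseline
#' removal: an emotion signal (band-limited noise whose per-band power
#' depends on the class) is shaped in the frequency domain by a
#' subject-specific, spectrally smooth gain kernel, and the resting-state
#' baseline is an independent realisation of the same kernel. Subject
#' kernels vary log-normally across subjects, which is exactly the
#' subject-specific distortion the inverse filter is meant to cancel.
#'
#' @param n_subjects,n_trials_per_subject Study size.
#' @param n_channels Channels per recording (default 32, DEAP layout).
#' @param fs Sampling rate in Hz (default 128).
#' @param trial_seconds Trial length (default 60 s).
#' @param baseline_seconds Resting-state baseline length (default 3 s).
#' @param class_effects Named list `low`/`high` of per-band power
#'   multipliers. Defaults boost theta/alpha for the low class and
#'   beta/gamma for the high class.
#' @param subject_gain_sd Standard deviation of the per-subject per-channel
#'   log spectral gain (default 1.0, i.e. typical gain factors of ~e).
#' @param channel_gain_cor Correlation of the log gain across channels within
#'   a subject (default 0.8): most of a subject's spectral gain is a global
#'   amplitude property (skull thickness, electrode impedance) shared by all
#'   channels, with smaller channel-specific deviations on top.
#' @param kernel_smoothness Correlation scale of the gain profile across
#'   frequency, in Hz (default 5).
#' @param noise_sd Additive white sensor noise, in units of the ~unit-scale
#'   synthetic signal (default 0.05).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param bands [band_set()] the class effects refer to.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 32L, n_trials_per_subject = 40L,
                         n_channels = 32L, fs = 128, trial_seconds = 60,
                         baseline_seconds = 3,
                         class_effects = list(
                           low = c(theta = 1.5, alpha = 1.5, beta = 1, gamma = 1),
                           high = c(theta = 1, alpha = 1, beta = 1.5, gamma = 1.5)
                         ),
                         subject_gain_sd = 1.0, channel_gain_cor = 0.8,
                         kernel_smoothness = 5,
                         noise_sd = 0.05, seed = 0L, bands = band_set()) {
  check_pos <- function(x, nm, strict = TRUE) {
    if (length(x) != 1L || !is.finite(x) || (strict && x <= 0) || (!strict && x < 0)) {
      abort_config(sprintf("field '%s' must be %s", nm,
                           if (strict) "a positive number" else "non-negative"))
    }
  }
  check_pos(n_subjects, "n_subjects"); check_pos(n_trials_per_subject, "n_trials_per_subject")
  check_pos(n_channels, "n_channels"); check_pos(fs, "fs")
  check_pos(trial_seconds, "trial_seconds"); check_pos(baseline_seconds, "baseline_seconds")
  check_pos(kernel_smoothness, "kernel_smoothness")
  check_pos(subject_gain_sd, "subject_gain_sd", strict = FALSE)
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (length(channel_gain_cor) != 1L || channel_gain_cor < 0 || channel_gain_cor > 1) {
    abort_config("field 'channel_gain_cor' must lie in [0, 1]")
  }
  for (cls in names(class_effects)) {
    if (any(class_effects[[cls]] <= 0)) {
      abort_config(sprintf("field 'class_effects$%s' must be all-positive", cls))
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_trials_per_subject = as.integer(n_trials_per_subject),
         n_channels = as.integer(n_channels), fs = fs,
         trial_seconds = trial_seconds, baseline_seconds = baseline_seconds,
         class_effects = class_effects, subject_gain_sd = subject_gain_sd,
         channel_gain_cor = channel_gain_cor,
         kernel_smoothness = kernel_smoothness, noise_sd = noise_sd,
         seed = as.integer(seed), bands = bands),
    class = "synth_config"
  )
}

#' Draw a subject's spectral gain kernel
#'
#' The kernel is a strictly positive, spectrally smooth per-channel gain
#' profile. At knots spaced `kernel_smoothness` Hz apart the log gain is the
#' sum of a subject-level deviate shared by all channels (weight
#' `sqrt(channel_gain_cor)`) and an independent per-channel deviate (weight
#' `sqrt(1 - channel_gain_cor)`), spline-interpolated across frequency,
#' scaled by `subject_gain_sd` and exponentiated. Across subjects the log
#' profile at a knot has standard deviation `subject_gain_sd`, and within a
#' subject the log gains of two channels correlate at `channel_gain_cor`.
#' The draw is deterministic given the configuration seed and the subject
#' index.
#'
#' @param cfg A [synth_config()].
#' @param subject_index 1-based subject index.
#' @return An object of class `subject_kernel`; evaluate it on a frequency
#'   grid with [eval_kernel()].
#' @export
make_subject_kernel <- function(cfg, subject_index) {
  knots <- seq(0, cfg$fs / 2, by = cfg$kernel_smoothness)
  if (knots[length(knots)] < cfg$fs / 2) knots <- c(knots, cfg$fs / 2)
  kseed <- (abs(cfg$seed) %% 1000003L) * 1009L + 7919L * as.integer(subject_index)
  z <- withr::with_seed(kseed, {
    z_subj <- stats::rnorm(length(knots))
    z_ch <- matrix(stats::rnorm(cfg$n_channels * length(knots)),
                   cfg$n_channels, length(knots))
    sqrt(cfg$channel_gain_cor) * matrix(z_subj, cfg$n_channels,
                                        length(knots), byrow = TRUE) +
      sqrt(1 - cfg$channel_gain_cor) * z_ch
  })
  structure(
    list(knots = knots, log_gain = cfg$subject_gain_sd * z,
         subject_index = as.integer(subject_index),
         cache = new.env(parent = emptyenv())),
    class = "subject_kernel"
  )
}

#' Evaluate a subject kernel on a frequency grid
#'
#' Natural-spline interpolation of the per-channel log gain followed by
#' exponentiation, so the result is strictly positive everywhere. Grids are
#' cached on the kernel, as the generator evaluates the same two grids (trial
#' and baseline) for every trial of a subject.
#'
#' @param kernel A `subject_kernel`.
#' @param freqs Numeric frequency grid in Hz.
#' @return Channels x length(freqs) matrix of positive gains.
#' @export
eval_kernel <- function(kernel, freqs) {
  key <- paste0("n", length(freqs), "_", format(freqs[min(2, length(freqs))], digits = 12))
  hit <- kernel$cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- t(apply(kernel$log_gain, 1L, function(v) {
    stats::spline(kernel$knots, v, xout = freqs, method = "natural")$y
  }))
  if (length(freqs) == 1L) out <- matrix(out, ncol = 1L)
  out <- exp(out)
  kernel$cache[[key]] <- out
  out
}

band_amplitude_profile <- function(freqs, effects, bands) {
  m <- numeric(length(freqs))
  slices <- band_slices(freqs, bands)
  for (b in names(slices)) {
    mult <- effects[[b]]
    if (is.null(mult)) mult <- 1
    m[slices[[b]]] <- sqrt(mult)   # power multiplier -> amplitude
  }
  m
}

# Hermitian-symmetric inverse transform: half-spectrum (C x nh, bins 1..nh of
# an n-point DFT, DC excluded) -> real time-domain signal (C x n).
half_spectrum_to_time <- function(half, n) {
  n_ch <- nrow(half)
  nh <- ncol(half)
  full <- matrix(0 + 0i, n, n_ch)
  full[2:(nh + 1L), ] <- t(half)
  conj_rows <- n - (1:nh) + 1L
  keep <- conj_rows > (nh + 1L)   # avoid overwriting Nyquist when n even
  full[conj_rows[keep], ] <- Conj(t(half))[keep, , drop = FALSE]
  if (n %% 2L == 0L) full[nh + 1L, ] <- Re(t(half)[nh, ])   # real Nyquist
  t(Re(stats::mvfft(full, inverse = TRUE))) / n
}

#' Generate one synthetic trial
#'
#' Builds the emotion signal in the frequency domain as complex white noise
#' shaped by the class's per-band amplitude profile, multiplies it by the
#' subject kernel, and inverse-transforms to time. The baseline segment is
#' the inverse transform of the kernel under a flat unit-magnitude excitation
#' with independent random phase, so its magnitude spectrum equals the kernel
#' exactly when `noise_sd = 0`. White sensor noise of sd `noise_sd` is added
#' to both signals. Ratings are 7.5 (high) or 2.5 (low) on both axes, so
#' labels travel through the ordinary rating binarization. Consumes the
#' current RNG stream; seed upstream for reproducibility.
#'
#' @param cfg A [synth_config()].
#' @param kernel The subject's [make_subject_kernel()] result.
#' @param class_label `"low"` or `"high"`.
#' @param subject_id,trial_id Identity metadata for the resulting trial.
#' @return An [eeg_trial()].
#' @export
generate_trial <- function(cfg, kernel, class_label, subject_id, trial_id) {
  class_label <- match.arg(class_label, c("low", "high"))
  n <- as.integer(round(cfg$trial_seconds * cfg$fs))
  nb <- as.integer(round(cfg$baseline_seconds * cfg$fs))
  n_ch <- cfg$n_channels

  # trial: band-shaped complex white noise times the subject kernel
  nh <- n %/% 2L
  freqs <- (1:nh) * cfg$fs / n
  m <- band_amplitude_profile(freqs, cfg$class_effects[[class_label]], cfg$bands)
  noise_c <- matrix(complex(real = stats::rnorm(n_ch * nh),
                            imaginary = stats::rnorm(n_ch * nh)) / sqrt(2),
                    n_ch, nh)
  emo <- sqrt(n) * sweep(noise_c, 2L, m, `*`)
  half <- emo * eval_kernel(kernel, freqs)
  trial_sig <- half_spectrum_to_time(half, n)

  # baseline: flat unit excitation with random phase through the same kernel
  nbh <- nb %/% 2L
  bfreqs <- (1:nbh) * cfg$fs / nb
  phase <- matrix(stats::runif(n_ch * nbh, 0, 2 * pi), n_ch, nbh)
  bhalf <- sqrt(nb) * eval_kernel(kernel, bfreqs) * exp(1i * phase)
  base_sig <- half_spectrum_to_time(bhalf, nb)

  if (cfg$noise_sd > 0) {
    trial_sig <- trial_sig + matrix(stats::rnorm(n_ch * n, sd = cfg$noise_sd), n_ch, n)
    base_sig <- base_sig + matrix(stats::rnorm(n_ch * nb, sd = cfg$noise_sd), n_ch, nb)
  }

  r <- if (class_label == "high") 7.5 else 2.5
  eeg_trial(subject_id, trial_id, cfg$fs, trial_sig, base_sig,
            ratings = list(valence = r, arousal = r),
            channel_names = default_channel_names(n_ch))
}

#' Generate a full synthetic dataset
#'
#' One subject kernel per subject, `n_trials_per_subject` trials each with
#' classes balanced by alternation (trial 0 low, trial 1 high, ...). Fully
#' reproducible from `cfg$seed`: two calls with equal configurations return
#' bit-identical datasets.
#'
#' @param cfg A [synth_config()].
#' @return An [eeg_dataset()] with `n_subjects * n_trials_per_subject` trials.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  trials <- withr::with_seed(cfg$seed, {
    purrr::flatten(purrr::map(seq_len(cfg$n_subjects), function(s) {
      kernel <- make_subject_kernel(cfg, s)
      sid <- sprintf("S%02d", s)
      purrr::map(seq_len(cfg$n_trials_per_subject), function(t) {
        lab <- if ((t - 1L) %% 2L == 0L) "low" else "high"
        generate_trial(cfg, kernel, lab, sid, t - 1L)
      })
    }))
  })
  eeg_dataset(trials)
}
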