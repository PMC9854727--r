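test_that("segment_slots partitions the trial with floor semantics", {
  tr <- tiny_trial(fs = 128, trial_seconds = 60, n_channels = 3)

  slots <- segment_slots(tr, 6)
  expect_length(slots, 10L)
  expect_true(all(vapply(slots, ncol, integer(1)) == 768L))
  expect_identical(slots[[1]], tr$trial_signal[, 1:768])

  expect_length(segment_slots(tr, 60), 1L)

  # 7 s slots: floor(7680 / 896) = 8 slots, 7680 - 8 * 896 = 512 discarded
  slots7 <- segment_slots(tr, 7)
  expect_length(slots7, 8L)
  used <- do.call(cbind, slots7)
  expect_identical(ncol(tr$trial_signal) - ncol(used), 512L)
  expect_identical(used, tr$trial_signal[, seq_len(8 * 896)])

  expect_error(segment_slots(tr, 61), class = "invbase_validation_error")
  expect_error(segment_slots(tr, 1e-9), class = "invbase_validation_error")
})

test_that("compute_spectrum matches the closed-form DFT of a cosine", {
  fs <- 128; n <- 768
  t <- (seq_len(n) - 1) / fs
  seg <- rbind(cos(2 * pi * 10 * t))
  sp <- compute_spectrum(seg, fs)

  expect_length(sp$freqs, n %/% 2 + 1)
  expect_equal(sp$freqs[2] - sp$freqs[1], fs / n)
  peak_bin <- which(sp$freqs == 10)
  # unnormalised DFT of an integer-period unit cosine: magnitude n/2 at f0
  expect_equal(sp$magnitudes[1, peak_bin], n / 2, tolerance = 1e-12)
  far <- abs(sp$freqs - 10) >= 2
  expect_lt(max(sp$magnitudes[1, far]), 1e-9 * sp$magnitudes[1, peak_bin])
})

test_that("compute_spectrum is linear and homogeneous", {
  sp0 <- compute_spectrum(matrix(0, 2, 64), fs = 32)
  expect_true(all(sp0$magnitudes == 0))

  seg <- matrix(rnorm(2 * 64), 2)
  a <- compute_spectrum(seg, 32)
  b <- compute_spectrum(3.7 * seg, 32)
  expect_equal(b$magnitudes, 3.7 * a$magnitudes, tolerance = 1e-12)

  expect_error(compute_spectrum(matrix(1, 1, 1), 32),
               class = "invbase_validation_error")
})

test_that("baseline_spectrum uses the full baseline segment", {
  tr <- tiny_trial(fs = 128, baseline_seconds = 3)
  bs <- baseline_spectrum(tr)
  expect_identical(bs$origin, "baseline")
  expect_length(bs$freqs, 193L)  # floor(384/2) + 1
  expect_equal(bs$freqs[2], 1 / 3)

  t <- (seq_len(384) - 1) / 128
  tr$baseline_signal <- rbind(cos(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  bs10 <- baseline_spectrum(tr)
  expect_equal(bs10$freqs[which.max(bs10$magnitudes[1, ])], 10)

  tr$baseline_signal[] <- 0
  expect_true(all(baseline_spectrum(tr)$magnitudes == 0))
})

test_that("align_grids interpolates linearly and clamps at the edges", {
  base <- spectrum_of(rbind(c(2, 4, 6)), c(0, 1, 2), origin = "baseline")

  same <- align_grids(base, c(0, 1, 2))
  expect_identical(same$magnitudes, base$magnitudes)

  mid <- align_grids(base, c(0.5, 1.5))
  expect_equal(mid$magnitudes[1, ], c(3, 5))

  const <- spectrum_of(rbind(rep(7, 5)), 0:4, origin = "baseline")
  out <- align_grids(const, c(-1, 0.3, 2.2, 9))
  expect_equal(out$magnitudes[1, ], rep(7, 4))
})

test_that("invbase_remove divides element-wise with a relative floor", {
  cfg <- removal_config("invbase")
  f <- c(1, 2, 3)
  slot <- spectrum_of(rbind(c(4, 9, 16)), f)
  base <- spectrum_of(rbind(c(2, 3, 4)), f, origin = "baseline")
  expect_equal(invbase_remove(slot, base, cfg)$magnitudes[1, ], c(2, 3, 4))

  expect_equal(invbase_remove(slot, slot, cfg)$magnitudes[1, ], c(1, 1, 1))

  flat <- spectrum_of(rbind(c(1, 1, 1)), f, origin = "baseline")
  expect_equal(invbase_remove(slot, flat, cfg)$magnitudes, slot$magnitudes)

  # all-zero baseline channel passes through with a warning
  slot2 <- spectrum_of(rbind(c(4, 9, 16), c(4, 9, 16)), f)
  base2 <- spectrum_of(rbind(c(2, 3, 4), c(0, 0, 0)), f, origin = "baseline")
  expect_warning(out <- invbase_remove(slot2, base2, cfg), "all-zero")
  expect_equal(out$magnitudes[2, ], c(4, 9, 16))
  expect_equal(out$magnitudes[1, ], c(2, 3, 4))

  # near-zero baseline bin is floored, not divided through
  base3 <- spectrum_of(rbind(c(1e-20, 1, 1)), f, origin = "baseline")
  out3 <- invbase_remove(slot, base3, cfg)
  expect_equal(out3$magnitudes[1, 1], 4 / (cfg$epsilon_rel * 1))
})

test_that("subtractive_remove subtracts and clips at zero", {
  f <- c(1, 2, 3)
  slot <- spectrum_of(rbind(c(4, 9, 16)), f)
  base <- spectrum_of(rbind(c(2, 3, 4)), f, origin = "baseline")
  expect_equal(subtractive_remove(slot, base)$magnitudes[1, ], c(2, 6, 12))
  expect_true(all(subtractive_remove(base, slot)$magnitudes[1, ] == 0))
  expect_true(all(subtractive_remove(slot, slot)$magnitudes == 0))
})

test_that("remove_baseline dispatches and restricts to the analysis band", {
  tr <- tiny_trial(fs = 128, trial_seconds = 12, n_channels = 2)
  slot <- compute_spectrum(segment_slots(tr, 6)[[1]], tr$fs)
  base <- align_grids(baseline_spectrum(tr), slot$freqs)

  cfg <- removal_config("nbc")
  out <- remove_baseline(slot, base, cfg)
  keep <- slot$freqs >= 3 & slot$freqs <= 47
  # bins k with 3 <= k/6 <= 47 on the 6 s grid: k = 18..282, 265 bins
  expect_identical(sum(keep), 265L)
  expect_length(out$freqs, 265L)
  expect_equal(out$magnitudes, slot$magnitudes[, keep])

  cfgi <- removal_config("invbase")
  expect_equal(
    remove_baseline(slot, base, cfgi)$magnitudes,
    invbase_remove(slot, base, cfgi)$magnitudes[, keep]
  )

  mismatched <- spectrum_of(slot$magnitudes[, -1], slot$freqs[-1])
  expect_error(invbase_remove(slot, mismatched),
               class = "invbase_internal_error")
})

test_that("inverse filtering equals subtraction in log-magnitude space", {
  withr::with_seed(3, {
    f <- seq(0, 16, by = 0.5)
    slot <- spectrum_of(matrix(runif(4 * length(f), 0.5, 4), 4), f)
    base <- spectrum_of(matrix(runif(4 * length(f), 0.5, 4), 4), f,
                        origin = "baseline")
  })
  out <- invbase_remove(slot, base)
  expect_lt(
    max(abs(log(out$magnitudes) -
              (log(slot$magnitudes) - log(base$magnitudes)))),
    1e-10
  )
})

test_that("per-channel gain cancels under inverse filtering only", {
  tr <- tiny_trial(n_channels = 3, fs = 64, trial_seconds = 8,
                   baseline_seconds = 2)
  g <- c(0.3, 2.5, 10)
  tr_g <- tr
  tr_g$trial_signal <- tr$trial_signal * g
  tr_g$baseline_signal <- tr$baseline_signal * g

  cfg_inv <- removal_config("invbase")
  cfg_nbc <- removal_config("nbc")
  cfg_sub <- removal_config("subtractive")
  spec_for <- function(trial, cfg) {
    slot <- compute_spectrum(segment_slots(trial, 2)[[1]], trial$fs)
    base <- align_grids(baseline_spectrum(trial), slot$freqs)
    remove_baseline(slot, base, cfg)
  }

  inv0 <- spec_for(tr, cfg_inv); inv1 <- spec_for(tr_g, cfg_inv)
  expect_equal(inv1$magnitudes, inv0$magnitudes, tolerance = 1e-9)

  nbc0 <- spec_for(tr, cfg_nbc); nbc1 <- spec_for(tr_g, cfg_nbc)
  expect_equal(nbc1$magnitudes, nbc0$magnitudes * g, tolerance = 1e-9)

  sub0 <- spec_for(tr, cfg_sub); sub1 <- spec_for(tr_g, cfg_sub)
  expect_equal(sub1$magnitudes, sub0$magnitudes * g, tolerance = 1e-9)
})

test_that("inverse filtering deconvolves a known kernel exactly", {
  n <- 256; fs <- 64
  withr::with_seed(11, {
    f_sig <- rnorm(n)
    h_mags <- runif(n %/% 2 + 1, 0.5, 1.5)   # strictly positive spectrum
  })
  h_sig <- signal_from_magnitudes(h_mags, n)
  # circular convolution in time = product of spectra
  g_sig <- Re(fft(fft(f_sig) * fft(h_sig), inverse = TRUE)) / n

  slot <- compute_spectrum(rbind(g_sig), fs)
  base <- compute_spectrum(rbind(h_sig), fs)
  out <- invbase_remove(slot, base)

  expected <- Mod(fft(f_sig))[seq_len(n %/% 2 + 1)]
  rel <- abs(out$magnitudes[1, ] - expected) /
    pmax(expected, max(expected) * 1e-6)
  expect_lt(max(rel), 1e-6)
})

test_that("no removal method ever yields negative magnitudes", {
  tr <- tiny_trial(n_channels = 2, fs = 64, trial_seconds = 6,
                   baseline_seconds = 2)
  for (m in c("invbase", "subtractive", "nbc")) {
    cfg <- removal_config(m)
    slot <- compute_spectrum(segment_slots(tr, 2)[[1]], tr$fs)
    base <- align_grids(baseline_spectrum(tr), slot$freqs)
    expect_true(all(remove_baseline(slot, base, cfg)$magnitudes >= 0))
  }
})

test_that("power-spectrum mode squares before removal", {
  f <- c(1, 2, 3)
  slot <- spectrum_of(rbind(c(4, 9, 16)), f)
  base <- spectrum_of(rbind(c(2, 3, 4)), f, origin = "baseline")
  cfg <- removal_config("invbase", analysis_band = c(0.5, 3), spectrum = "power")
  expect_equal(remove_baseline(slot, base, cfg)$magnitudes[1, ],
               (c(4, 9, 16) / c(2, 3, 4))^2)
})
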