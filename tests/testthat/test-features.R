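test_that("band peaks are found, ranked and restricted to their band", {
  sp <- make_peaky_spectrum(c(10, 18, 24), c(5, 2, 3))
  a <- find_band_peaks(sp, alpha_band(), k = 1)
  expect_equal(a$freq, 10)
  expect_equal(a$value, 5)
  b <- find_band_peaks(sp, beta_band(), k = 2)
  expect_equal(b$freq, c(24, 18))
  expect_equal(b$value, c(3, 2))
  expect_true(all(b$is_peak))
})

test_that("a peak-free band falls back to the largest band bins", {
  # strictly decreasing psd: no interior local maximum anywhere
  psd <- rev(seq(0.1, 10, length.out = 61))
  sp <- make_spectrum(psd)
  res <- find_band_peaks(sp, alpha_band(), k = 1)
  expect_equal(res$freq, 8)          # lo-edge bin carries the band maximum
  expect_false(res$is_peak)
  expect_equal(res$value, psd[9])
})

test_that("equal-valued peaks break ties toward the lower frequency", {
  sp <- make_peaky_spectrum(c(15, 20), c(4, 4))
  res <- find_band_peaks(sp, beta_band(), k = 1)
  expect_equal(res$freq, 15)
})

test_that("the 13 Hz edge belongs to beta, not alpha", {
  sp <- make_peaky_spectrum(c(13, 9), c(6, 2))
  a <- find_band_peaks(sp, alpha_band(), k = 1)
  expect_equal(a$freq, 9)
  b <- find_band_peaks(sp, beta_band(), k = 1)
  expect_equal(b$freq, 13)
})

test_that("too coarse a resolution for a band is an error", {
  sp <- make_spectrum(runif(10), resolution = 10)   # bins every 10 Hz
  expect_error(find_band_peaks(sp, alpha_band(), 1), "at least 3")
})

test_that("band-peak features compose the peak search: (f1, f2, f3)", {
  sp <- make_peaky_spectrum(c(10, 18, 24), c(5, 2, 3))
  fv <- extract_bandpeak_features(sp)
  expect_identical(fv$feature_names, c("f1", "f2", "f3"))
  expect_equal(unname(fv$values), c(5, 3, 2))
  expect_equal(fv$meta$peak_freqs, c(10, 24, 18))
})

test_that("an all-zero spectrum yields [0, 0, 0] via the padding fallback", {
  sp <- make_spectrum(rep(0, 61))
  expect_equal(unname(extract_bandpeak_features(sp)$values), c(0, 0, 0))
})

test_that("band-peak extraction equals the exhaustive-scan oracle on random spectra", {
  set.seed(123)
  n_mismatch <- 0
  for (i in 1:1000) {
    res <- 0.5 + runif(1)
    n_bins <- sample(40:80, 1)
    # quantized values provoke plateaus and ties
    psd <- round(runif(n_bins, 0, 8) * 4) / 4
    sp <- make_spectrum(psd, resolution = res)
    for (band in list(alpha_band(), beta_band())) {
      k <- if (band$name == "alpha") 1 else 2
      mine <- find_band_peaks(sp, band, k)
      ref <- oracle_band_peaks(sp$freqs, sp$psd, band$lo, band$hi,
                               band$right_closed, k)
      if (!isTRUE(all.equal(mine$freq, ref$freq)) ||
          !isTRUE(all.equal(mine$value, ref$value))) {
        n_mismatch <- n_mismatch + 1
      }
    }
  }
  expect_equal(n_mismatch, 0)
})

test_that("band-peak features scale quadratically with epoch amplitude", {
  trials <- make_tiny_trials(n_per_task = 1, tasks = "RS", fs = 256,
                             duration_s = 4, channels = "F3")
  ep <- segment_trial(trials[[1]], prep_duration = 0, n_parts = 1)[[1]]
  f1 <- extract_bandpeak_features(welch_psd(ep, welch_params(nperseg = 256)))
  ep$samples <- 3 * ep$samples
  f2 <- extract_bandpeak_features(welch_psd(ep, welch_params(nperseg = 256)))
  expect_equal(unname(f2$values), 9 * unname(f1$values), tolerance = 1e-12)
})

test_that("f2 >= f3 on random spectra and real synthetic epochs", {
  set.seed(9)
  for (i in 1:50) {
    sp <- make_spectrum(runif(61, 0, 5))
    v <- extract_bandpeak_features(sp)$values
    expect_gte(v[["f2"]], v[["f3"]])
  }
})

test_that("raising alpha amplitude raises the class-mean f1", {
  prof <- function(amp) {
    task_profile("RS", alpha_amp = amp, alpha_freq = 10, beta1_amp = 0.5,
                 beta1_freq = 18, beta2_amp = 0.4, beta2_freq = 24,
                 noise_scale = 1, channel_gains = 1)
  }
  mean_f1 <- function(amp, seed) {
    trials <- generate_trials(list(prof(amp)), 50, fs = 256, duration_s = 10,
                              seed = seed, channels = "F3")
    ft <- feature_table(segment_trials(trials), "bandpeak",
                        welch_params(nperseg = 256))
    mean(ft$f1)
  }
  expect_gt(mean_f1(3.0, seed = 14), mean_f1(1.0, seed = 14))
  expect_gt(mean_f1(1.0, seed = 14), mean_f1(0.3, seed = 14))
})

test_that("time-domain summary features match direct computation", {
  fv <- extract_minmaxmeanstd(c(1, 2, 3, 4))
  expect_identical(fv$feature_names, c("min", "max", "mean", "std"))
  expect_equal(unname(fv$values), c(1, 4, 2.5, 1.2909944487358056))
  expect_equal(unname(extract_minmaxmeanstd(rep(7, 10))$values),
               c(7, 7, 7, 0))
  expect_equal(unname(extract_minmaxmeanstd(rep(c(-1, 1), 8))$values[1:3]),
               c(-1, 1, 0))
  expect_error(extract_minmaxmeanstd(numeric(0)), "empty")
})

test_that("band power integrates the PSD over each band", {
  flat <- make_spectrum(rep(1, 257))
  fv <- extract_bandpower(flat)
  expect_equal(unname(fv$values[1]), 4, tolerance = 1e-12)   # [8,13) -> bins 8..12
  expect_equal(unname(fv$values[2]), 17, tolerance = 1e-12)  # [13,30]
  zero <- make_spectrum(rep(0, 257))
  expect_equal(unname(extract_bandpower(zero)$values), c(0, 0))
  narrow <- make_spectrum(rep(1, 5))   # spectrum only spans 0-4 Hz
  expect_error(extract_bandpower(narrow), "outside")
})

test_that("a 10 Hz sinusoid has far more alpha than beta power", {
  t <- (0:2047) / 512
  sp <- welch_psd(sin(2 * pi * 10 * t), welch_params(nperseg = 400), fs = 512)
  fv <- extract_bandpower(sp)
  expect_gt(fv$values[["alpha_power"]], 100 * fv$values[["beta_power"]])
})

test_that("feature tables carry provenance and fixed dimensionality", {
  epochs <- segment_trials(make_tiny_trials(n_per_task = 2, fs = 128))
  ft <- feature_table(epochs, "bandpeak", welch_params(nperseg = 128))
  expect_identical(names(ft), c("trial_id", "part", "channel", "task",
                                "extractor", "f1", "f2", "f3"))
  expect_equal(nrow(ft), length(epochs))
  expect_equal(ncol(feature_matrix(ft)), 3)
  ft2 <- feature_table(epochs, "minmaxmeanstd")
  expect_equal(ncol(feature_matrix(ft2)), 4)
  ft3 <- feature_table(epochs, "bandpower", welch_params(nperseg = 128))
  expect_equal(ncol(feature_matrix(ft3)), 2)
})
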