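# Independent reference implementations ("oracles") and small fixture
# builders shared across the test files.  Oracles are deliberately written
# from first principles -- plain loops and explicit DFTs -- so that they
# share no code path with the package implementation they check.

# Brute-force Welch estimate: explicit segment loop and an O(n^2) DFT via
# the DFT matrix, mean-of-modified-periodograms with one-sided density
# scaling.
oracle_welch <- function(x, fs, nperseg, overlap_fraction = 0.5) {
  hop <- round(nperseg * (1 - overlap_fraction))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))
  dft <- exp(-2i * pi * outer(0:(nperseg - 1), 0:(nperseg - 1)) / nperseg)
  n_keep <- nperseg %/% 2 + 1
  acc <- numeric(n_keep)
  n_seg <- 0
  start <- 1
  while (start + nperseg - 1 <= length(x)) {
    seg <- x[start:(start + nperseg - 1)]
    seg <- (seg - sum(seg) / nperseg) * w
    X <- as.vector(dft %*% seg)
    acc <- acc + Mod(X[1:n_keep])^2
    n_seg <- n_seg + 1
    start <- start + hop
  }
  pxx <- acc / n_seg / (fs * sum(w^2))
  for (i in seq_len(n_keep)) {
    if (i > 1 && !(nperseg %% 2 == 0 && i == n_keep)) pxx[i] <- 2 * pxx[i]
  }
  list(freqs = (0:(n_keep - 1)) * fs / nperseg, psd = pxx, n_segments = n_seg)
}

# Exhaustive neighbor-scan band peak reference: loops over every bin,
# collects strict interior local maxima inside the band, sorts by value
# (desc) then frequency (asc), pads with the best remaining band bins.
oracle_band_peaks <- function(freqs, psd, lo, hi, right_closed, k) {
  in_band <- logical(length(freqs))
  for (i in seq_along(freqs)) {
    in_band[i] <- freqs[i] >= lo &&
      (if (right_closed) freqs[i] <= hi else freqs[i] < hi)
  }
  peak_idx <- integer(0)
  for (i in seq_along(freqs)) {
    if (i == 1 || i == length(freqs) || !in_band[i]) next
    if (psd[i] > psd[i - 1] && psd[i] > psd[i + 1]) {
      peak_idx <- c(peak_idx, i)
    }
  }
  sort_band <- function(idx) {
    if (length(idx) == 0) return(idx)
    idx[order(-psd[idx], freqs[idx])]
  }
  peak_idx <- sort_band(peak_idx)
  sel <- peak_idx[seq_len(min(k, length(peak_idx)))]
  if (length(sel) < k) {
    rest <- sort_band(setdiff(which(in_band), sel))
    sel <- c(sel, rest[seq_len(k - length(sel))])
  }
  data.frame(freq = freqs[sel], value = psd[sel])
}

# AUC as the fraction of concordant (positive, negative) score pairs, ties
# counting one half.
oracle_auc_paircount <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive max-win tally.
oracle_maxwin <- function(winners, tasks) {
  counts <- setNames(integer(length(tasks)), tasks)
  for (w in winners) counts[w] <- counts[w] + 1
  best <- tasks[1]
  for (tk in tasks) if (counts[tk] > counts[best]) best <- tk
  best
}

# A power_spectrum on a regular grid with the given psd values.
make_spectrum <- function(psd, resolution = 1, fs = NULL) {
  freqs <- (seq_along(psd) - 1) * resolution
  power_spectrum(freqs, psd, resolution = resolution)
}

# A spectrum that is `base` everywhere except injected triangular bumps
# (strict local maxima) at the requested frequencies.
make_peaky_spectrum <- function(peaks_at, values, resolution = 1,
                                max_freq = 256, base = 0.01) {
  freqs <- seq(0, max_freq, by = resolution)
  psd <- rep(base, length(freqs))
  for (i in seq_along(peaks_at)) {
    j <- which.min(abs(freqs - peaks_at[i]))
    psd[j] <- values[i]
  }
  power_spectrum(freqs, psd, resolution = resolution)
}

# Tiny single-oscillation trial set for bookkeeping tests.
make_tiny_trials <- function(n_per_task = 2, tasks = c("RS", "MA"), fs = 128,
                             duration_s = 10, channels = c("F3", "C3"),
                             noise_scale = 0.5, seed = 11) {
  alpha_amps <- c(RS = 4, MA = 2, RH = 1.5, LH = 1.5, LA = 3)
  profiles <- lapply(tasks, function(tk) {
    task_profile(tk, alpha_amp = alpha_amps[[tk]], alpha_freq = 10,
                 beta1_amp = 1, beta1_freq = 18, beta2_amp = 0.7,
                 beta2_freq = 24, noise_scale = noise_scale,
                 channel_gains = rep(1, length(channels)))
  })
  generate_trials(profiles, n_per_task, fs = fs, duration_s = duration_s,
                  seed = seed, channels = channels)
}

# Generate a multi-channel band-peak feature table for voting tests.
multiclass_features <- function(profiles, n_trials, seed, fs = 256,
                                channels = c("F3", "F4", "C3", "C4")) {
  trials <- generate_trials(profiles, n_trials, fs = fs, duration_s = 10,
                            seed = seed, channels = channels)
  feature_table(segment_trials(trials), "bandpeak",
                welch_params(nperseg = 256))
}

# Five cleanly separated low-noise profiles for recovery tests.
make_separated_profiles <- function(noise_scale = 0.05, channels = c("F3", "F4", "C3", "C4")) {
  g <- setNames(rep(1, length(channels)), channels)
  list(
    task_profile("RS", 5.0, 10.0, 1.5, 18, 1.0, 24, noise_scale, g),
    task_profile("MA", 2.5, 11.0, 1.4, 20, 1.1, 26, noise_scale, g),
    task_profile("RH", 1.2, 9.0, 0.5, 17, 0.3, 22, noise_scale, g),
    task_profile("LH", 1.2, 12.0, 2.5, 25, 2.0, 15, noise_scale, g),
    task_profile("LA", 3.8, 8.5, 0.9, 28, 0.6, 19, noise_scale, g))
}
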