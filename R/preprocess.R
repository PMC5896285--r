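# Preprocessing: causal low-pass Butterworth filtering of whole trials and
# segmentation into fixed-length single-channel epochs.

#' Design a digital low-pass Butterworth filter as second-order sections
#'
#' Poles of the analog Butterworth prototype are placed on the left-half
#' circle of radius equal to the pre-warped cutoff, paired into complex
#' conjugates, and each pair is mapped through the bilinear transform into
#' one biquad with unit DC gain.  A cascade of second-order sections keeps
#' high-order designs numerically well conditioned, which a direct-form
#' order-10 filter is not.
#'
#' @param order Filter order (even orders yield `order/2` biquads; odd
#'   orders add one first-order section).
#' @param cutoff -3 dB cutoff frequency in Hz.
#' @param fs Sampling rate in Hz; `cutoff` must be below `fs / 2`.
#' @return Object of class `butter_sos`: a list of `(b, a)` coefficient
#'   pairs plus the design parameters.
#' @export
butter_lowpass_sos <- function(order, cutoff, fs) {
  if (cutoff >= fs / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  }
  if (order < 1) stop("order must be >= 1")
  K <- 2 * fs
  wc <- K * tan(pi * cutoff / fs)          # pre-warped analog cutoff
  k <- seq_len(order)
  poles <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  sections <- list()
  # complex poles come in conjugate pairs ordered symmetrically around -wc
  cplx <- poles[Im(poles) > 1e-9 * wc]
  for (p in cplx) {
    re2 <- 2 * Re(p)
    m2 <- Mod(p)^2
    a0 <- K^2 - re2 * K + m2
    a <- c(a0, -2 * K^2 + 2 * m2, K^2 + re2 * K + m2) / a0
    b <- m2 * c(1, 2, 1) / a0
    sections[[length(sections) + 1]] <- list(b = b, a = a)
  }
  if (order %% 2 == 1) {                    # single real pole at -wc
    a0 <- K + wc
    sections[[length(sections) + 1]] <-
      list(b = wc * c(1, 1) / a0, a = c(1, (wc - K) / a0))
  }
  structure(list(sections = sections, order = order, cutoff = cutoff, fs = fs),
            class = "butter_sos")
}

#' Frequency response of a second-order-section filter
#'
#' @param filt A `butter_sos` object.
#' @param freqs Frequencies in Hz at which to evaluate the response.
#' @return Complex response, one value per frequency.
#' @export
sos_freq_response <- function(filt, freqs) {
  z <- exp(-1i * 2 * pi * freqs / filt$fs)
  resp <- rep(1 + 0i, length(freqs))
  for (sec in filt$sections) {
    num <- outer(z, seq_along(sec$b) - 1, `^`) %*% sec$b
    den <- outer(z, seq_along(sec$a) - 1, `^`) %*% sec$a
    resp <- resp * as.vector(num / den)
  }
  resp
}

apply_sos <- function(filt, x) {
  for (sec in filt$sections) {
    x <- as.numeric(signal::filter(sec$b, sec$a, x))
  }
  x
}

#' Low-pass filter a trial
#'
#' Filters each channel of the trial independently with a causal digital
#' Butterworth low-pass filter (10th order, 50 Hz cutoff by default),
#' applied as a single forward pass of a second-order-section cascade.
#'
#' @param trial A `trial_recording`.
#' @param cutoff Cutoff frequency in Hz (default 50).
#' @param order Filter order (default 10).
#' @return A `trial_recording` with the same shape and metadata, filtered.
#' @export
lowpass_filter <- function(trial, cutoff = 50, order = 10) {
  stopifnot(inherits(trial, "trial_recording"))
  filt <- butter_lowpass_sos(order, cutoff, trial$fs)
  out <- trial
  out$samples <- t(apply(trial$samples, 1, function(x) apply_sos(filt, x)))
  rownames(out$samples) <- trial$channel_names
  out
}

#' Construct a single-channel epoch
#'
#' @param samples Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param channel_name,task_label,trial_id,part_index Provenance metadata.
#' @return Object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(samples, fs, channel_name = NA_character_,
                      task_label = NA_character_, trial_id = NA_character_,
                      part_index = 1L) {
  structure(
    list(samples = as.numeric(samples), fs = fs, channel_name = channel_name,
         task_label = task_label, trial_id = trial_id,
         part_index = as.integer(part_index)),
    class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch %s/%s part %d: %d samples @ %g Hz>\n",
              x$trial_id, x$channel_name, x$part_index,
              length(x$samples), x$fs))
  invisible(x)
}

#' Segment a trial into single-channel epochs
#'
#' Drops the initial task-preparation period and splits the remainder of
#' each channel into `n_parts` equal consecutive parts, each becoming one
#' epoch -- the classification unit.  With the defaults (2 s preparation,
#' 2 parts) a 10 s trial yields two 4 s epochs per channel, so 100 trials
#' per task give 200 epochs per class and channel.
#'
#' @param trial A `trial_recording`.
#' @param prep_duration Seconds removed from the start of the trial
#'   (default 2).
#' @param n_parts Number of equal parts (default 2).
#' @return List of `eeg_epoch` objects, channel-major then part.
#' @export
segment_trial <- function(trial, prep_duration = 2, n_parts = 2) {
  stopifnot(inherits(trial, "trial_recording"), n_parts >= 1)
  if (trial$duration_s <= prep_duration) {
    stop("cannot segment trial ", trial$trial_id, ": duration ",
         trial$duration_s, " s does not exceed the ", prep_duration,
         " s preparation period")
  }
  fs <- trial$fs
  n_prep <- round(fs * prep_duration)
  avail <- ncol(trial$samples) - n_prep
  part_len <- avail %/% n_parts
  if (avail %% n_parts != 0) {
    warning("trial ", trial$trial_id, ": ", avail %% n_parts,
            " trailing samples do not fill a part and were truncated")
  }
  epochs <- list()
  for (ch in seq_along(trial$channel_names)) {
    for (p in seq_len(n_parts)) {
      idx <- n_prep + (p - 1) * part_len + seq_len(part_len)
      epochs[[length(epochs) + 1]] <- eeg_epoch(
        trial$samples[ch, idx], fs,
        channel_name = trial$channel_names[ch],
        task_label = trial$task_label,
        trial_id = trial$trial_id,
        part_index = p)
    }
  }
  epochs
}

#' Segment a list of trials
#'
#' @param trials List of `trial_recording` objects.
#' @inheritParams segment_trial
#' @return Flat list of `eeg_epoch` objects.
#' @export
segment_trials <- function(trials, prep_duration = 2, n_parts = 2) {
  do.call(c, lapply(trials, segment_trial,
                    prep_duration = prep_duration, n_parts = n_parts))
}
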