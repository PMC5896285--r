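# Synthetic EEG trial generation: class-dependent alpha/beta oscillations
# over 1/f background noise, the spectral structure the band-peak features
# exploit.

#' Task labels used throughout the package
#'
#' The five mental/motor imagery tasks, in their fixed enumeration order:
#' resting state (RS), mental arithmetic (MA), right-hand imagery (RH),
#' left-hand imagery (LH) and letter-"A" imagery (LA).  The order matters:
#' voting ties are broken toward the earlier task.
#'
#' @format Character vector of length 5.
#' @export
TASKS <- c("RS", "MA", "RH", "LH", "LA")

#' Default EEG channel montage
#'
#' Nine scalp channels spanning frontal, central, parietal and occipital
#' regions.
#'
#' @format Character vector of length 9.
#' @export
CHANNELS <- c("F3", "F4", "C3", "C4", "P3", "P4", "Pz", "O1", "O2")

#' Spectral profile of one task class
#'
#' Describes the rhythmic content of one task's synthetic EEG: a dominant
#' alpha-band (8-13 Hz) oscillation and two weaker beta-band (13-30 Hz)
#' oscillations, superimposed on 1/f background noise.  Amplitudes are in
#' arbitrary microvolt-like units; classification only ever sees relative
#' power, so the absolute scale is immaterial.
#'
#' @param task_label One of `TASKS`.
#' @param alpha_amp Amplitude of the alpha oscillation (>= 0).
#' @param alpha_freq Alpha frequency in Hz, strictly inside \[8, 13\].
#' @param beta1_amp,beta2_amp Amplitudes of the two beta oscillations (>= 0).
#' @param beta1_freq,beta2_freq Distinct beta frequencies in Hz, inside
#'   (13, 30\].
#' @param noise_scale Standard deviation of the 1/f background noise.
#' @param channel_gains Named or unnamed numeric vector of per-channel
#'   multiplicative gains applied to the oscillatory part of the signal.
#' @return An object of class `task_profile`.
#' @export
task_profile <- function(task_label, alpha_amp, alpha_freq,
                         beta1_amp, beta1_freq, beta2_amp, beta2_freq,
                         noise_scale = 1, channel_gains = rep(1, length(CHANNELS))) {
  task_label <- match.arg(task_label, TASKS)
  if (!(alpha_freq >= 8 && alpha_freq <= 13)) {
    stop("invalid profile for task ", task_label,
         ": alpha_freq must lie in [8, 13] Hz, got ", alpha_freq)
  }
  for (bf in c(beta1_freq, beta2_freq)) {
    if (!(bf > 13 && bf <= 30)) {
      stop("invalid profile for task ", task_label,
           ": beta frequencies must lie in (13, 30] Hz, got ", bf)
    }
  }
  if (beta1_freq == beta2_freq) {
    stop("invalid profile for task ", task_label,
         ": beta1_freq and beta2_freq must differ")
  }
  amps <- c(alpha_amp, beta1_amp, beta2_amp)
  if (any(!is.finite(amps)) || any(amps < 0) || noise_scale < 0) {
    stop("invalid profile for task ", task_label,
         ": amplitudes and noise_scale must be finite and >= 0")
  }
  structure(
    list(task_label = task_label,
         alpha_amp = alpha_amp, alpha_freq = alpha_freq,
         beta1_amp = beta1_amp, beta1_freq = beta1_freq,
         beta2_amp = beta2_amp, beta2_freq = beta2_freq,
         noise_scale = noise_scale,
         channel_gains = channel_gains),
    class = "task_profile")
}

#' Default five-task spectral profiles
#'
#' Profiles emulating the qualitative spectral signatures of the five tasks:
#' resting state carries the largest alpha peak; letter imagery a slightly
#' smaller one; mental arithmetic an attenuated alpha; and the two motor
#' imagery tasks show both reduced alpha and beta desynchronization, with a
#' contralateral gain reduction over the central channels (C3 for right-hand,
#' C4 for left-hand imagery) so that the two are distinguishable.
#'
#' @param noise_scale Background 1/f noise scale shared by all tasks
#'   (default 1, giving a clear but non-trivial signal-to-noise ratio).
#' @param channels Channel names the gain vectors refer to.
#' @return Named list of `task_profile` objects, one per task.
#' @export
default_profiles <- function(noise_scale = 1, channels = CHANNELS) {
  gain <- function(...) {
    g <- rep(1, length(channels))
    names(g) <- channels
    override <- c(...)
    g[names(override)] <- override
    g
  }
  list(
    RS = task_profile("RS", alpha_amp = 4.0, alpha_freq = 10.0,
                      beta1_amp = 1.2, beta1_freq = 18, beta2_amp = 0.9,
                      beta2_freq = 24, noise_scale = noise_scale,
                      channel_gains = gain(O1 = 1.2, O2 = 1.2)),
    MA = task_profile("MA", alpha_amp = 2.0, alpha_freq = 10.5,
                      beta1_amp = 1.1, beta1_freq = 19, beta2_amp = 0.85,
                      beta2_freq = 23, noise_scale = noise_scale,
                      channel_gains = gain(F3 = 1.2, F4 = 1.2)),
    RH = task_profile("RH", alpha_amp = 1.4, alpha_freq = 10.0,
                      beta1_amp = 0.55, beta1_freq = 18, beta2_amp = 0.4,
                      beta2_freq = 24, noise_scale = noise_scale,
                      channel_gains = gain(C3 = 0.7)),
    LH = task_profile("LH", alpha_amp = 1.4, alpha_freq = 9.5,
                      beta1_amp = 0.6, beta1_freq = 20, beta2_amp = 0.45,
                      beta2_freq = 26, noise_scale = noise_scale,
                      channel_gains = gain(C4 = 0.7)),
    LA = task_profile("LA", alpha_amp = 3.2, alpha_freq = 10.0,
                      beta1_amp = 1.0, beta1_freq = 17, beta2_amp = 0.75,
                      beta2_freq = 25, noise_scale = noise_scale,
                      channel_gains = gain(P3 = 1.2, P4 = 1.2)))
}

#' Construct a trial recording
#'
#' @param samples Channels x time numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param duration_s Trial duration in seconds; `ncol(samples)` must equal
#'   `round(fs * duration_s)`.
#' @param task_label One of `TASKS`.
#' @param trial_id Integer or character trial identifier.
#' @param channel_names Unique channel names, one per row of `samples`.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(samples, fs, duration_s, task_label, trial_id,
                            channel_names) {
  samples <- as.matrix(samples)
  if (ncol(samples) != round(fs * duration_s)) {
    stop("trial ", trial_id, ": expected ", round(fs * duration_s),
         " samples per channel, got ", ncol(samples))
  }
  if (nrow(samples) != length(channel_names) || anyDuplicated(channel_names)) {
    stop("trial ", trial_id, ": channel_names must be unique and match ",
         "the sample matrix rows")
  }
  task_label <- match.arg(task_label, TASKS)
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, fs = fs, duration_s = duration_s,
         task_label = task_label, trial_id = trial_id,
         channel_names = channel_names),
    class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording %s task=%s: %d channels x %d samples @ %g Hz>\n",
              x$trial_id, x$task_label, nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}

# 1/f ("pink") noise: white Gaussian noise shaped in the frequency domain
# with amplitude proportional to 1/sqrt(f) for f >= 1 Hz and flat below,
# then rescaled to unit standard deviation.  Seedable through the caller's
# RNG state.
pink_noise <- function(n, fs) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freqs <- c(0, seq_len(n - 1)) * fs / n
  # mirror frequencies above Nyquist onto their aliases
  freqs <- pmin(freqs, fs - freqs)
  shape <- 1 / sqrt(pmax(freqs, 1))
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate labeled synthetic EEG trials
#'
#' Each trial's per-channel signal is
#' `channel_gain * (alpha + beta1 + beta2 sinusoids) + noise_scale * pink`,
#' where each oscillation receives a per-trial random amplitude jitter
#' (uniform multiplicative factor in \[0.8, 1.2\]) and a uniform random phase,
#' shared across channels within a trial (the oscillatory sources are common;
#' only their gains differ by channel), while the 1/f noise is drawn
#' independently per channel.  With `jitter = FALSE` amplitudes are taken
#' verbatim and all phases are zero, which makes the noiseless output an
#' exact sum of sinusoids.
#'
#' @param profiles List of `task_profile` objects (one per class).
#' @param n_trials_per_task Number of trials generated for every profile.
#' @param fs Sampling rate in Hz (must exceed 60 Hz, twice the top of the
#'   beta band).
#' @param duration_s Trial duration in seconds.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param channels Channel names; each profile's `channel_gains` must cover
#'   them (by name, or by position if unnamed).
#' @param jitter Apply per-trial amplitude/phase jitter (default TRUE).
#' @return List of `trial_recording` objects, ordered task-major.
#' @export
generate_trials <- function(profiles, n_trials_per_task, fs = 512,
                            duration_s = 10, seed = 1L,
                            channels = CHANNELS, jitter = TRUE) {
  stopifnot(n_trials_per_task >= 1, duration_s > 0)
  if (fs <= 2 * 30) stop("fs must exceed 60 Hz (twice the beta band top)")
  for (p in profiles) {
    if (!inherits(p, "task_profile")) stop("profiles must be task_profile objects")
  }
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1) / fs
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  trials <- list()
  trial_counter <- 0L
  for (p in profiles) {
    gains <- p$channel_gains
    if (!is.null(names(gains))) {
      missing_ch <- setdiff(channels, names(gains))
      if (length(missing_ch) > 0) {
        stop("profile ", p$task_label, " lacks gains for channels: ",
             paste(missing_ch, collapse = ", "))
      }
      gains <- gains[channels]
    } else if (length(gains) != length(channels)) {
      stop("profile ", p$task_label, ": channel_gains length ", length(gains),
           " does not match ", length(channels), " channels")
    }
    osc <- cbind(c(p$alpha_amp, p$alpha_freq),
                 c(p$beta1_amp, p$beta1_freq),
                 c(p$beta2_amp, p$beta2_freq))
    for (i in seq_len(n_trials_per_task)) {
      trial_counter <- trial_counter + 1L
      source_sig <- numeric(n)
      for (k in 1:3) {
        amp <- osc[1, k]
        phase <- 0
        if (jitter) {
          amp <- amp * stats::runif(1, 0.8, 1.2)
          phase <- stats::runif(1, 0, 2 * pi)
        }
        source_sig <- source_sig + amp * sin(2 * pi * osc[2, k] * t + phase)
      }
      samples <- matrix(0, nrow = length(channels), ncol = n)
      for (ch in seq_along(channels)) {
        noise <- if (p$noise_scale > 0) p$noise_scale * pink_noise(n, fs) else 0
        samples[ch, ] <- gains[ch] * source_sig + noise
      }
      trials[[trial_counter]] <- trial_recording(
        samples, fs, duration_s, p$task_label,
        trial_id = sprintf("%s_%03d", p$task_label, i),
        channel_names = channels)
    }
  }
  trials
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Write a trial set to a CSV + JSON fixture
#'
#' The fixture is a pair of plain-text files: `<path>.csv` holds one row per
#' (trial, channel) with the raw samples in wide columns, and `<path>.json`
#' holds the metadata (sampling rate, duration, channel names, trial ids and
#' task labels).  The round-trip through [read_fixture()] reproduces samples
#' to full stored precision and all metadata.
#'
#' @param trials List of `trial_recording` objects (may be empty).
#' @param path Path prefix; `.csv` and `.json` are appended.
#' @return Invisibly, the two file paths.
#' @export
write_fixture <- function(trials, path) {
  csv_path <- paste0(path, ".csv")
  json_path <- paste0(path, ".json")
  if (length(trials) == 0) {
    meta <- list(fs = NULL, duration_s = NULL, channel_names = character(0),
                 trials = data.frame(trial_id = character(0),
                                     task_label = character(0)))
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    data.table::fwrite(data.table::data.table(trial_id = character(0),
                                              channel = character(0)),
                       csv_path)
    return(invisible(c(csv = csv_path, json = json_path)))
  }
  fs <- trials[[1]]$fs
  channel_names <- trials[[1]]$channel_names
  meta <- list(
    fs = fs,
    duration_s = trials[[1]]$duration_s,
    channel_names = channel_names,
    trials = data.frame(
      trial_id = vapply(trials, function(x) as.character(x$trial_id), ""),
      task_label = vapply(trials, function(x) x$task_label, "")))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  rows <- lapply(trials, function(tr) {
    dt <- data.table::as.data.table(tr$samples)
    data.table::setnames(dt, paste0("s", seq_len(ncol(tr$samples))))
    cbind(data.table::data.table(trial_id = as.character(tr$trial_id),
                                 channel = tr$channel_names), dt)
  })
  data.table::fwrite(data.table::rbindlist(rows), csv_path)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a trial set fixture written by [write_fixture()]
#'
#' @param path Path prefix used when writing (without extension).
#' @return List of `trial_recording` objects.
#' @export
read_fixture <- function(path) {
  csv_path <- paste0(path, ".csv")
  json_path <- paste0(path, ".json")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (length(meta$channel_names) == 0) return(list())
  dat <- data.table::fread(csv_path)
  n_ch <- length(meta$channel_names)
  trials <- vector("list", nrow(meta$trials))
  for (i in seq_len(nrow(meta$trials))) {
    tid <- meta$trials$trial_id[i]
    block <- dat[dat$trial_id == tid, ]
    if (nrow(block) != n_ch) {
      stop("fixture parse error: trial ", tid, " has ", nrow(block),
           " sample rows but ", n_ch, " channels are declared")
    }
    samples <- as.matrix(block[, -(1:2)])
    trials[[i]] <- trial_recording(
      samples, meta$fs, meta$duration_s, meta$trials$task_label[i],
      trial_id = tid, channel_names = block$channel)
  }
  trials
}
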