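# Feature extraction.
#
# The band-peak extractor is the package's core method: from one epoch's
# Welch PSD it takes the largest local peak value in the alpha band (f1)
# and the two largest local peak values in the beta band (f2 >= f3).
# Two baseline extractors are provided for comparison: time-domain
# min/max/mean/sd, and alpha/beta band power.

#' Frequency band
#'
#' Band membership is half-open by default (`lo <= f < hi`); the beta
#' default is right-closed so every bin on \[8, 30\] Hz belongs to exactly
#' one band, with the shared 13 Hz edge assigned to beta.
#'
#' @param name Band name.
#' @param lo,hi Band edges in Hz, `lo < hi`.
#' @param right_closed Whether `hi` itself belongs to the band.
#' @return Object of class `freq_band`.
#' @export
freq_band <- function(name, lo, hi, right_closed = FALSE) {
  stopifnot(lo < hi)
  structure(list(name = name, lo = lo, hi = hi, right_closed = right_closed),
            class = "freq_band")
}

#' @rdname freq_band
#' @export
alpha_band <- function() freq_band("alpha", 8, 13, right_closed = FALSE)

#' @rdname freq_band
#' @export
beta_band <- function() freq_band("beta", 13, 30, right_closed = TRUE)

band_mask <- function(band, freqs) {
  if (band$right_closed) freqs >= band$lo & freqs <= band$hi
  else freqs >= band$lo & freqs < band$hi
}

#' Find the largest local PSD peaks inside a band
#'
#' A peak is an interior spectrum bin strictly greater than both of its
#' neighbors, restricted to bins inside the band.  Peaks are returned in
#' descending PSD order, ties broken toward the lower frequency.  If fewer
#' than `k` such peaks exist, the list is padded with the largest remaining
#' band bins (band-edge bins included), still in descending order, so the
#' result always has `k` rows whenever the band has at least `k` bins.
#'
#' @param spectrum A `power_spectrum`.
#' @param band A `freq_band`.
#' @param k Number of peaks to return (>= 1).
#' @return Data frame with columns `freq`, `value` and `is_peak`
#'   (FALSE on padded rows), `k` rows.
#' @export
find_band_peaks <- function(spectrum, band, k = 1) {
  stopifnot(inherits(spectrum, "power_spectrum"), k >= 1)
  freqs <- spectrum$freqs
  psd <- spectrum$psd
  in_band <- which(band_mask(band, freqs))
  if (length(in_band) < 3) {
    stop("band ", band$name, " [", band$lo, ", ", band$hi, "] covers only ",
         length(in_band), " bins at resolution ", spectrum$resolution,
         " Hz; need at least 3")
  }
  n <- length(psd)
  interior <- in_band[in_band > 1 & in_band < n]
  is_peak <- psd[interior] > psd[interior - 1] & psd[interior] > psd[interior + 1]
  peaks <- interior[is_peak]
  ord <- function(idx) idx[order(-psd[idx], freqs[idx])]
  peaks <- ord(peaks)
  chosen <- utils::head(peaks, k)
  n_pad <- k - length(chosen)
  padded <- integer(0)
  if (n_pad > 0) {
    remaining <- setdiff(in_band, chosen)
    padded <- utils::head(ord(remaining), n_pad)
  }
  sel <- c(chosen, padded)
  data.frame(freq = freqs[sel], value = psd[sel],
             is_peak = c(rep(TRUE, length(chosen)), rep(FALSE, length(padded))))
}

#' Feature vector container
#'
#' @param values Finite numeric feature values.
#' @param feature_names Names, same length as `values`.
#' @param extractor_id Which extractor produced the vector
#'   (`"bandpeak"`, `"minmaxmeanstd"` or `"bandpower"`).
#' @param meta Named list of epoch provenance (channel, task, trial, part).
#' @return Object of class `feature_vector`.
#' @export
feature_vector <- function(values, feature_names, extractor_id, meta = list()) {
  stopifnot(length(values) == length(feature_names), all(is.finite(values)))
  names(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 extractor_id = extractor_id, meta = meta),
            class = "feature_vector")
}

epoch_meta <- function(spectrum_or_epoch) {
  if (inherits(spectrum_or_epoch, "power_spectrum")) spectrum_or_epoch$meta
  else spectrum_or_epoch[c("channel_name", "task_label", "trial_id", "part_index")]
}

#' Band-peak features of a power spectrum
#'
#' The three-dimensional feature vector `(f1, f2, f3)`: `f1` is the highest
#' PSD peak value in the alpha band and `f2 >= f3` are the two highest PSD
#' peak values in the beta band.  Peak PSD values (linear scale, not dB)
#' are the features; the peak frequencies are kept as metadata only.
#'
#' @param spectrum A `power_spectrum`.
#' @param alpha,beta `freq_band` objects (defaults: alpha 8-13 Hz
#'   right-open, beta 13-30 Hz right-closed).
#' @return A `feature_vector` of length 3 with a `peak_freqs` entry in its
#'   metadata.
#' @export
extract_bandpeak_features <- function(spectrum, alpha = alpha_band(),
                                      beta = beta_band()) {
  pa <- find_band_peaks(spectrum, alpha, k = 1)
  pb <- find_band_peaks(spectrum, beta, k = 2)
  meta <- epoch_meta(spectrum)
  meta$peak_freqs <- c(pa$freq, pb$freq)
  feature_vector(c(pa$value, pb$value), c("f1", "f2", "f3"),
                 "bandpeak", meta)
}

#' Time-domain summary features of an epoch
#'
#' Baseline extractor: minimum, maximum, mean and sample standard deviation
#' (n - 1 denominator) of the raw epoch samples.
#'
#' @param epoch An `eeg_epoch` or numeric vector.
#' @return A `feature_vector` of length 4.
#' @export
extract_minmaxmeanstd <- function(epoch) {
  x <- if (inherits(epoch, "eeg_epoch")) epoch$samples else as.numeric(epoch)
  if (length(x) == 0) stop("cannot summarize an empty epoch")
  s <- if (length(x) > 1) stats::sd(x) else 0
  meta <- if (inherits(epoch, "eeg_epoch")) epoch_meta(epoch) else list()
  feature_vector(c(min(x), max(x), mean(x), s),
                 c("min", "max", "mean", "std"), "minmaxmeanstd", meta)
}

#' Band-power features of a power spectrum
#'
#' Baseline extractor: the PSD integrated over the alpha and beta bands by
#' trapezoidal rule on the bin grid.
#'
#' @inheritParams extract_bandpeak_features
#' @return A `feature_vector` of length 2.
#' @export
extract_bandpower <- function(spectrum, alpha = alpha_band(),
                              beta = beta_band()) {
  band_pow <- function(band) {
    idx <- which(band_mask(band, spectrum$freqs))
    if (length(idx) < 2) {
      stop("band ", band$name, " lies outside the spectrum's frequency range")
    }
    pracma::trapz(spectrum$freqs[idx], spectrum$psd[idx])
  }
  feature_vector(c(band_pow(alpha), band_pow(beta)),
                 c("alpha_power", "beta_power"), "bandpower",
                 epoch_meta(spectrum))
}

#' Extract a feature table from a list of epochs
#'
#' Runs one extractor over every epoch and assembles the results into a
#' data frame with provenance columns (`trial_id`, `part`, `channel`,
#' `task`, `extractor`) followed by the feature columns.
#'
#' @param epochs List of `eeg_epoch` objects.
#' @param extractor_id One of `"bandpeak"`, `"minmaxmeanstd"`,
#'   `"bandpower"`.
#' @param params `welch_params` used for the spectral extractors.
#' @param alpha,beta Band definitions for the spectral extractors.
#' @return Data frame, one row per epoch.
#' @export
feature_table <- function(epochs, extractor_id = "bandpeak",
                          params = welch_params(),
                          alpha = alpha_band(), beta = beta_band()) {
  extractor_id <- match.arg(extractor_id,
                            c("bandpeak", "minmaxmeanstd", "bandpower"))
  fvs <- lapply(epochs, function(ep) {
    if (extractor_id == "minmaxmeanstd") {
      extract_minmaxmeanstd(ep)
    } else {
      sp <- welch_psd(ep, params)
      if (extractor_id == "bandpeak") extract_bandpeak_features(sp, alpha, beta)
      else extract_bandpower(sp, alpha, beta)
    }
  })
  vals <- do.call(rbind, lapply(fvs, function(f) f$values))
  meta <- data.frame(
    trial_id = vapply(epochs, function(e) as.character(e$trial_id), ""),
    part = vapply(epochs, function(e) e$part_index, 0L),
    channel = vapply(epochs, function(e) e$channel_name, ""),
    task = vapply(epochs, function(e) e$task_label, ""),
    extractor = extractor_id)
  cbind(meta, as.data.frame(vals))
}

#' Feature columns of a feature table
#'
#' @param features A data frame from [feature_table()].
#' @return Numeric matrix of the feature columns.
#' @export
feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features),
                               c("trial_id", "part", "channel", "task",
                                 "extractor")), drop = FALSE])
}
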