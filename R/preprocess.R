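#' Preprocessing configuration
#'
#' Defaults pin the corpus contract: downsample to 200 Hz, 0-75 Hz bandpass
#' (a zero-phase lowpass, DC retained), uniform 180 s trial segments.
#'
#' @param target_rate target sampling rate in Hz (default 200).
#' @param band_low lower band edge in Hz; 0 means lowpass only (default 0).
#' @param band_high upper band edge in Hz (default 75).
#' @param segment_length trial segment length in seconds (default 180).
#' @return A \code{preprocess_config} list.
#' @export
preprocess_config <- function(target_rate = 200, band_low = 0, band_high = 75,
                              segment_length = 180) {
  stopifnot(target_rate > 0, band_low >= 0, band_high > band_low,
            segment_length > 0)
  structure(list(target_rate = target_rate, band_low = band_low,
                 band_high = band_high, segment_length = segment_length,
                 filter = "fft zero-phase, raised-cosine transition 0.5 Hz"),
            class = "preprocess_config")
}

#' Resample a recording to a new rate
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling, which
#' is inherently anti-aliased) or zero-padded (upsampling). Duration is
#' preserved within one sample period; channel count and order are unchanged.
#' A no-op when the rate already matches.
#'
#' @param rec a \code{raw_recording}.
#' @param target_rate new rate in Hz (> 0).
#' @return Resampled \code{raw_recording}.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "raw_recording"), target_rate > 0)
  if (any(!is.finite(rec$data))) stop("recording contains non-finite samples")
  if (target_rate == rec$sample_rate) return(rec)
  n_out <- round(ncol(rec$data) * target_rate / rec$sample_rate)
  raw_recording(fft_resample(rec$data, n_out), target_rate,
                channel_names = rec$channel_names, label = rec$label)
}

#' Bandpass-filter a recording (zero phase)
#'
#' \code{low = 0} behaves as a pure lowpass: DC is retained. The filter is a
#' frequency-domain mask with a 0.5 Hz raised-cosine transition, applied with
#' zero phase, so windowed features downstream see no group delay.
#'
#' @param rec a \code{raw_recording}.
#' @param low lower edge in Hz (>= 0; 0 = lowpass).
#' @param high upper edge in Hz; must be below Nyquist.
#' @return Filtered \code{raw_recording}, same shape and rate.
#' @export
bandpass_recording <- function(rec, low = 0, high = 75) {
  stopifnot(inherits(rec, "raw_recording"))
  if (low < 0 || high <= low) stop("need 0 <= low < high")
  if (high >= rec$sample_rate / 2) {
    stop("`high` (", high, " Hz) must be below the Nyquist frequency ",
         rec$sample_rate / 2, " Hz")
  }
  raw_recording(fft_filter(rec$data, rec$sample_rate, low, high),
                rec$sample_rate, channel_names = rec$channel_names,
                label = rec$label)
}

#' Crop a recording to its first `length` seconds
#'
#' Trials of heterogeneous length are reduced to a uniform window by keeping
#' the leading segment; metadata (rate, channels, label) is preserved.
#'
#' @param rec a \code{raw_recording}.
#' @param length segment length in seconds.
#' @return Cropped \code{raw_recording}.
#' @export
segment_recording <- function(rec, length = 180) {
  stopifnot(inherits(rec, "raw_recording"), length > 0)
  n_keep <- round(length * rec$sample_rate)
  n_have <- ncol(rec$data)
  if (n_have < n_keep) {
    stop(sprintf(
      "recording too short: %.2f s available, %.2f s requested (deficit %.2f s)",
      n_have / rec$sample_rate, length, (n_keep - n_have) / rec$sample_rate))
  }
  if (n_keep == n_have) return(rec)
  raw_recording(rec$data[, seq_len(n_keep), drop = FALSE], rec$sample_rate,
                channel_names = rec$channel_names, label = rec$label)
}

#' Full preprocessing chain: resample, bandpass, segment
#'
#' @param rec a \code{raw_recording}.
#' @param config a \code{preprocess_config}.
#' @return Preprocessed \code{raw_recording}.
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  rec <- resample_recording(rec, config$target_rate)
  rec <- bandpass_recording(rec, config$band_low, config$band_high)
  segment_recording(rec, config$segment_length)
}
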