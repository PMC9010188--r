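# Zero-phase spectral filtering and Fourier resampling.
#
# No IIR design toolbox is assumed: filters are realized as frequency-domain
# magnitude masks (brick wall with a short raised-cosine transition) applied
# to the full-length DFT and inverted. This is exactly zero-phase, exactly
# reproducible, and attenuates out-of-band power far beyond the 20 dB/octave
# contract. The same masks are used to synthesize band-limited noise and to
# decompose recordings into bands, closing the generator/analyzer loop.

# Two-sided bin frequencies |f| in Hz for an n-point DFT at rate fs.
fft_bin_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k <- ifelse(k > n / 2, n - k, k)
  k * fs / n
}

# Raised-cosine band mask over |f|: unit gain in [low, high], half-cosine
# roll-off of total width `transition` centred on each edge. low = 0 (or
# NULL) means pure lowpass with DC retained.
band_mask <- function(freqs, low, high, transition = 0.5) {
  h <- transition / 2
  g <- rep(1, length(freqs))
  if (!is.null(high) && is.finite(high)) {
    up <- freqs > high - h & freqs < high + h
    g[freqs >= high + h] <- 0
    g[up] <- 0.5 * (1 + cos(pi * (freqs[up] - (high - h)) / (2 * h)))
  }
  if (!is.null(low) && low > 0) {
    lo <- freqs > low - h & freqs < low + h
    g[freqs <= low - h] <- 0
    g[lo] <- g[lo] * 0.5 * (1 - cos(pi * (freqs[lo] - (low - h)) / (2 * h)))
  }
  g
}

# Zero-phase filter of a channels x samples matrix through a band mask.
# low = 0 keeps DC (lowpass semantics); high = NULL keeps the top end.
fft_filter <- function(data, sample_rate, low, high, transition = 0.5) {
  n <- ncol(data)
  g <- band_mask(fft_bin_freqs(n, sample_rate), low, high, transition)
  x <- stats::mvfft(t(data))          # column-wise DFTs (one per channel)
  y <- Re(stats::mvfft(x * g, inverse = TRUE)) / n
  t(y)
}

# Fourier-domain resampling of a channels x samples matrix to n_out samples
# per channel (spectrum truncation / zero-padding; inherently anti-aliased).
fft_resample <- function(data, n_out) {
  n <- ncol(data)
  if (n_out == n) return(data)
  x <- stats::mvfft(t(data))
  m <- min(n, n_out)
  half <- floor((m - 1) / 2)
  y <- matrix(0 + 0i, nrow = n_out, ncol = ncol(x))
  y[1, ] <- x[1, ]
  if (half > 0) {
    y[2:(half + 1), ] <- x[2:(half + 1), ]
    y[(n_out - half + 1):n_out, ] <- x[(n - half + 1):n, ]
  }
  if (m %% 2 == 0) {
    # shared Nyquist bin: split (downsampling) or keep real (upsampling)
    nyq <- x[m / 2 + 1, ]
    if (n_out < n) {
      y[n_out / 2 + 1, ] <- Re(nyq)
    } else {
      y[m / 2 + 1, ] <- nyq / 2
      y[n_out - m / 2 + 1, ] <- Conj(nyq) / 2
    }
  }
  out <- Re(stats::mvfft(y, inverse = TRUE)) / n
  t(out)
}
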