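# Shared fixtures. Everything is generated in code; durations are kept short
# wherever the contract under test does not pin them.

# single-channel sinusoid recording
sine_recording <- function(freq, sample_rate, duration, amp = 1, n_ch = 1L) {
  t <- seq_len(duration * sample_rate) / sample_rate
  data <- matrix(rep(amp * sin(2 * pi * freq * t), each = n_ch), nrow = n_ch)
  raw_recording(data, sample_rate)
}

# small labeled synthetic corpus (shared across tests needing images)
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      recs <- generate_dataset(4, duration = 20, sample_rate = 200, seed = 5)
      cache <<- list(
        recs = recs,
        imgs = lapply(recs, featurize_recording),
        labels = vapply(recs, function(r) r$label, integer(1)))
    }
    cache
  }
})

# empirical variance in [low, high] Hz via the periodogram — an oracle
# independent of the package's band filters
periodogram_band_var <- function(x, fs, low, high) {
  n <- length(x)
  pg <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  f <- ifelse(f > fs / 2, fs - f, f)
  sum(pg[f >= low - 0.5 & f <= high + 0.5]) / n
}

# Vasicek spacing estimator of differential entropy (nonparametric oracle)
vasicek_entropy <- function(x, m = round(sqrt(length(x)))) {
  n <- length(x)
  xs <- sort(x)
  lo <- pmax(seq_len(n) - m, 1L)
  hi <- pmin(seq_len(n) + m, n)
  mean(log(n / (2 * m) * (xs[hi] - xs[lo])))
}
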