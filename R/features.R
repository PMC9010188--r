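# Band-wise differential-entropy features and the 224 x 224 feature image.

# Variance floor applied before the log so constant windows yield a finite,
# documented floor value instead of -Inf.
DE_VAR_FLOOR <- 1e-12

#' Differential entropy of a Gaussian signal window
#'
#' For a window modeled as Gaussian with variance sigma^2, the differential
#' entropy has the closed form \eqn{\frac{1}{2}\log(2\pi e \sigma^2)} (nats).
#' The sample variance is floored at 1e-12 so degenerate (constant) windows
#' return the finite floor value \code{0.5 * log(2 * pi * exp(1) * 1e-12)}
#' rather than -Inf.
#'
#' @param samples numeric vector, at least 2 samples.
#' @return DE in nats; monotone increasing in the window's sample variance
#'   and invariant to its mean.
#' @export
#' @examples
#' differential_entropy(rnorm(200))        # approx 0.5 * log(2 * pi * e)
differential_entropy <- function(samples) {
  if (length(samples) < 2L) stop("a window needs at least 2 samples")
  if (any(!is.finite(samples))) stop("window contains non-finite samples")
  0.5 * log(2 * pi * exp(1) * max(stats::var(samples), DE_VAR_FLOOR))
}

# DE floor value for constant windows.
de_floor_value <- function() 0.5 * log(2 * pi * exp(1) * DE_VAR_FLOOR)

#' Construct a DE tensor container
#'
#' @param values channels x windows x bands numeric array (nats).
#' @param window_length seconds per window.
#' @param bands band table (default \code{canonical_bands()}).
#' @return Object of class \code{de_tensor}.
#' @export
de_tensor <- function(values, window_length = 1, bands = canonical_bands()) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  validate_bands(bands)
  if (dim(values)[3] != nrow(bands)) {
    stop("third dimension must match the number of bands (", nrow(bands), ")")
  }
  if (any(!is.finite(values))) stop("DE tensor contains non-finite values")
  structure(list(values = values, window_length = window_length, bands = bands,
                 version = "de_tensor/1"),
            class = "de_tensor")
}

#' @export
print.de_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<de_tensor> %d channels x %d windows x %d bands (window %g s)\n",
              d[1], d[2], d[3], x$window_length))
  invisible(x)
}

is_conformant_tensor <- function(x) {
  inherits(x, "de_tensor") && identical(dim(x$values), c(62L, 180L, 5L))
}

#' Extract the band-wise DE tensor from a preprocessed recording
#'
#' Per channel and canonical band, the signal is band-filtered (same spectral
#' masks as the generator), cut into non-overlapping windows of
#' \code{window_length} seconds, and each window's differential entropy is
#' computed from its sample variance. A 180 s recording with 1 s windows
#' yields the pipeline-conformant 62 x 180 x 5 tensor.
#'
#' @param rec a preprocessed \code{raw_recording} (200 Hz, <= 75 Hz content).
#' @param window_length window length in seconds (default 1).
#' @param bands band table (default canonical).
#' @return A \code{de_tensor} of shape channels x windows x bands.
#' @export
extract_de_tensor <- function(rec, window_length = 1, bands = canonical_bands()) {
  stopifnot(inherits(rec, "raw_recording"), window_length > 0)
  validate_bands(bands)
  n <- ncol(rec$data)
  spw <- window_length * rec$sample_rate
  if (abs(spw - round(spw)) > 1e-8) stop("window_length * sample_rate must be integral")
  spw <- as.integer(round(spw))
  if (n %% spw != 0L) {
    stop("duration (", n / rec$sample_rate, " s) is not a multiple of the ",
         "window length (", window_length, " s); segment the recording first")
  }
  n_win <- n %/% spw
  n_ch <- nrow(rec$data)
  vals <- array(NA_real_, dim = c(n_ch, n_win, nrow(bands)))
  # one forward DFT per channel, one mask + inverse per band
  x <- stats::mvfft(t(rec$data))
  freqs <- fft_bin_freqs(n, rec$sample_rate)
  for (b in seq_len(nrow(bands))) {
    g <- band_mask(freqs, bands$low[b], bands$high[b])
    comp <- Re(stats::mvfft(x * g, inverse = TRUE)) / n   # samples x channels
    dim(comp) <- c(spw, n_win, n_ch)
    # per-window sample variance, vectorized over windows x channels
    m <- colMeans(comp)
    ss <- colSums(comp^2)
    v <- (ss - spw * m^2) / (spw - 1)
    vals[, , b] <- t(0.5 * log(2 * pi * exp(1) * pmax(v, DE_VAR_FLOOR)))
  }
  de_tensor(vals, window_length = window_length, bands = bands)
}

#' Linear-dynamic-system configuration
#'
#' @param window smoothing span in seconds/windows (default 20, the span the
#'   moving-average fallback uses).
#' @param state_noise,obs_noise nonnegative variances, or "auto" to estimate
#'   both from the series by method of moments on first differences.
#' @param method "kalman" (random-walk state-space model, fixed-interval
#'   smoothing) or "moving_average" (centered window of \code{window} points).
#' @return An \code{lds_config} list.
#' @export
lds_config <- function(window = 20, state_noise = "auto", obs_noise = "auto",
                       method = c("kalman", "moving_average")) {
  stopifnot(window > 0)
  method <- match.arg(method)
  chk <- function(x) identical(x, "auto") ||
    (is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0)
  if (!chk(state_noise) || !chk(obs_noise)) {
    stop("state_noise and obs_noise must be nonnegative numbers or \"auto\"")
  }
  structure(list(window = window, state_noise = state_noise,
                 obs_noise = obs_noise, method = method),
            class = "lds_config")
}

#' Smooth a feature time series with a linear dynamic system
#'
#' The series is modeled as a scalar random walk observed in Gaussian noise
#' (x_t = x_{t-1} + w_t, y_t = x_t + v_t) and smoothed by a forward Kalman
#' filter plus backward (fixed-interval) pass. With "auto" noise variances,
#' the observation noise r is estimated as minus the lag-1 autocovariance of
#' the first differences and the state noise q as var(diff) - 2r, both
#' floored at a small positive value; for a first-order random walk these
#' moment identities are exact. A centered moving average over
#' \code{config$window} points is available as a documented fallback.
#'
#' Contracts: same output length; a constant (or length-1) series is returned
#' unchanged; the variance of first differences never increases.
#'
#' @param series numeric vector (length >= 1), finite values.
#' @param config an \code{lds_config}.
#' @return Smoothed numeric vector of the same length.
#' @export
lds_smooth <- function(series, config = lds_config()) {
  stopifnot(inherits(config, "lds_config"))
  if (any(!is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  if (n < 1L) stop("series must be non-empty")
  if (n == 1L || all(series == series[1L])) return(series)
  if (config$method == "moving_average") {
    return(moving_average(series, config$window))
  }
  d <- diff(series)
  if (identical(config$obs_noise, "auto") || identical(config$state_noise, "auto")) {
    c0 <- stats::var(d)
    c1 <- if (length(d) >= 2L)
      mean((d[-length(d)] - mean(d)) * (d[-1L] - mean(d))) else 0
    floor_v <- max(c0, .Machine$double.eps) * 1e-6
    r_auto <- max(-c1, floor_v)
    q_auto <- max(c0 - 2 * r_auto, floor_v)
  }
  r <- if (identical(config$obs_noise, "auto")) r_auto else max(config$obs_noise, 1e-12)
  q <- if (identical(config$state_noise, "auto")) q_auto else max(config$state_noise, 1e-12)
  kalman_rts_smooth(series, q, r)
}

# Fixed-interval (RTS) smoother for the scalar random-walk model.
kalman_rts_smooth <- function(y, q, r) {
  n <- length(y)
  xf <- numeric(n); pf <- numeric(n)   # filtered mean / variance
  xp <- numeric(n); pp <- numeric(n)   # one-step predictions
  xp[1] <- y[1]; pp[1] <- r + q        # diffuse-ish prior anchored at y1
  for (t in seq_len(n)) {
    if (t > 1L) { xp[t] <- xf[t - 1L]; pp[t] <- pf[t - 1L] + q }
    k <- pp[t] / (pp[t] + r)
    xf[t] <- xp[t] + k * (y[t] - xp[t])
    pf[t] <- (1 - k) * pp[t]
  }
  xs <- xf
  for (t in (n - 1L):1L) {
    g <- pf[t] / (pf[t] + q)
    xs[t] <- xf[t] + g * (xs[t + 1L] - xf[t])
  }
  xs
}

moving_average <- function(y, window) {
  n <- length(y)
  w <- max(1L, min(as.integer(round(window)), n))
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Apply LDS smoothing to every (channel, band) series of a DE tensor
#'
#' @param tensor a \code{de_tensor}.
#' @param config an \code{lds_config}.
#' @return Smoothed \code{de_tensor} of identical shape.
#' @export
lds_smooth_tensor <- function(tensor, config = lds_config()) {
  stopifnot(inherits(tensor, "de_tensor"))
  d <- dim(tensor$values)
  out <- tensor$values
  if (d[2] == 1L) return(tensor)   # nothing to smooth along time
  for (b in seq_len(d[3])) {
    out[, , b] <- t(apply(tensor$values[, , b, drop = FALSE][, , 1],
                          1L, lds_smooth, config = config))
  }
  de_tensor(out, tensor$window_length, tensor$bands)
}

#' Min-max standardization to [0, 1]
#'
#' \eqn{y_i = (x_i - \min x) / (\max x - \min x)}. Affine-invariant (for
#' positive scale), order-preserving, min maps to 0 and max to 1. A constant
#' sequence (max = min) maps to all 0.5 with a warning, so degenerate inputs
#' stay in range instead of producing NaN.
#'
#' @param x non-empty numeric vector/array.
#' @return Object of the same shape with values in [0, 1].
#' @export
#' @examples
#' minmax_standardize(c(2, 4, 6))   # 0, 0.5, 1
minmax_standardize <- function(x) {
  if (length(x) == 0L) stop("sequence must be non-empty")
  if (any(!is.finite(x))) stop("sequence contains non-finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("degenerate range (max == min): returning mid-scale 0.5")
    x[] <- 0.5
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Bilinear resize of a matrix to nr x nc, endpoints aligned to the corners.
bilinear_resize <- function(m, nr, nc) {
  sr <- if (nr == 1L) rep(1, 1) else 1 + (seq_len(nr) - 1) * (nrow(m) - 1) / (nr - 1)
  sc <- if (nc == 1L) rep(1, 1) else 1 + (seq_len(nc) - 1) * (ncol(m) - 1) / (nc - 1)
  r0 <- pmin(floor(sr), nrow(m) - 1L); r0[nrow(m) == 1L] <- 1L
  c0 <- pmin(floor(sc), ncol(m) - 1L); c0[ncol(m) == 1L] <- 1L
  fr <- sr - r0; fc <- sc - c0
  r1 <- pmin(r0 + 1L, nrow(m)); c1 <- pmin(c0 + 1L, ncol(m))
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  cc <- m[r1, c0, drop = FALSE]; dd <- m[r1, c1, drop = FALSE]
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc + cc * wr * (1 - wc) + dd * wr * wc
}

#' Flatten a DE tensor to its 2-D band-stacked plane
#'
#' Row block \code{(b-1)*channels + c} holds channel c of band b; columns are
#' time windows. For the conformant 62 x 180 x 5 tensor this is a 310 x 180
#' plane. The layout is the documented bridge between the 55,800 tensor
#' values and the 224 x 224 image grid.
#'
#' @param tensor a \code{de_tensor}.
#' @return Numeric matrix (channels * bands) x windows.
#' @export
de_plane <- function(tensor) {
  stopifnot(inherits(tensor, "de_tensor"))
  d <- dim(tensor$values)
  plane <- matrix(NA_real_, nrow = d[1] * d[3], ncol = d[2])
  for (b in seq_len(d[3])) {
    plane[((b - 1) * d[1] + 1):(b * d[1]), ] <- tensor$values[, , b]
  }
  plane
}

#' Convert a conformant DE tensor into a standardized 224 x 224 feature image
#'
#' The 62 x 180 x 5 tensor is laid out as a 310 x 180 plane (bands stacked
#' vertically, see \code{\link{de_plane}}), bilinearly resampled to
#' 224 x 224, and min-max standardized over the whole image. The
#' pre-standardization extrema are kept on the object for audit.
#'
#' @param tensor a conformant \code{de_tensor} (62 x 180 x 5).
#' @return Object of class \code{feature_image} with fields \code{values}
#'   (224 x 224 in [0, 1]), \code{scale_min}, \code{scale_max}.
#' @export
to_feature_image <- function(tensor) {
  if (!is_conformant_tensor(tensor)) {
    stop("feature imaging requires a conformant 62 x 180 x 5 DE tensor; got ",
         paste(dim(tensor$values), collapse = " x "))
  }
  plane <- de_plane(tensor)
  img <- bilinear_resize(plane, 224L, 224L)
  rng <- range(img)
  # relative tolerance: interpolation of a constant plane wobbles at eps scale
  degenerate <- (rng[2] - rng[1]) <= 1e-12 * max(abs(rng), 1)
  vals <- if (degenerate) {
    warning("degenerate range (max == min): returning mid-scale 0.5")
    matrix(0.5, 224L, 224L)
  } else {
    (img - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(values = vals, scale_min = rng[1], scale_max = rng[2],
                 version = "feature_image/1"),
            class = "feature_image")
}

#' @export
print.feature_image <- function(x, ...) {
  cat(sprintf("<feature_image> 224 x 224 in [0, 1] (pre-scale range [%.4g, %.4g])\n",
              x$scale_min, x$scale_max))
  invisible(x)
}

#' Resample the window (time) axis of a DE tensor to a target length
#'
#' Linear interpolation per (channel, band) series. Used by the detector to
#' bridge short acquisition sessions (e.g. 30 windows from a 30 s session)
#' to the 180-window geometry the classifier was trained on.
#'
#' @param tensor a \code{de_tensor}.
#' @param n_windows target window count.
#' @return A \code{de_tensor} with \code{n_windows} windows.
#' @export
resample_window_axis <- function(tensor, n_windows = 180L) {
  stopifnot(inherits(tensor, "de_tensor"), n_windows >= 1L)
  d <- dim(tensor$values)
  if (d[2] == n_windows) return(tensor)
  out <- array(NA_real_, dim = c(d[1], n_windows, d[3]))
  xin <- seq_len(d[2])
  xout <- if (d[2] == 1L) rep(1, n_windows) else
    seq(1, d[2], length.out = n_windows)
  for (b in seq_len(d[3])) {
    sl <- tensor$values[, , b]
    if (d[2] == 1L) {
      out[, , b] <- matrix(sl, d[1], n_windows)
    } else {
      out[, , b] <- t(apply(sl, 1L, function(y)
        stats::approx(xin, y, xout = xout)$y))
    }
  }
  de_tensor(out, tensor$window_length, tensor$bands)
}

#' Full feature chain: preprocessed recording to feature image
#'
#' Extract the DE tensor (1 s windows), LDS-smooth each (channel, band)
#' series, resample the window axis to 180 if needed, and image.
#'
#' @param rec preprocessed \code{raw_recording}.
#' @param lds an \code{lds_config}.
#' @param window_length DE window in seconds (default 1).
#' @return A \code{feature_image}.
#' @export
featurize_recording <- function(rec, lds = lds_config(), window_length = 1) {
  tensor <- extract_de_tensor(rec, window_length = window_length)
  tensor <- lds_smooth_tensor(tensor, lds)
  if (dim(tensor$values)[2] != 180L) tensor <- resample_window_axis(tensor, 180L)
  to_feature_image(tensor)
}
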