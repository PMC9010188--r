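#' Emotion-class band-variance profiles
#'
#' A class profile states, for one emotion label, the signal variance (uV^2)
#' the generator puts into each canonical band. The defaults encode a simple,
#' deliberately separable world: positive affect carries elevated beta+gamma
#' power, negative affect elevated delta+theta power, and neutral is flat.
#' Real emotional EEG is not this clean; the profiles exist so that the
#' differential-entropy features of the three classes are recoverable by the
#' classifier in end-to-end tests.
#'
#' @param label emotion label in \{-1, 0, +1\}.
#' @param band_variance named numeric vector, one positive variance (uV^2)
#'   per canonical band, names delta/theta/alpha/beta/gamma.
#' @return Object of class \code{class_profile}.
#' @export
class_profile <- function(label, band_variance) {
  label <- validate_label(label)
  if (is.null(label)) stop("a class profile requires a label in {-1, 0, +1}")
  bands <- canonical_bands()$name
  if (is.null(names(band_variance))) names(band_variance) <- bands
  if (!identical(sort(names(band_variance)), sort(bands))) {
    stop("`band_variance` must have one entry per canonical band: ",
         paste(bands, collapse = ", "))
  }
  band_variance <- band_variance[bands]
  if (any(!is.finite(band_variance)) || any(band_variance <= 0)) {
    stop("all band variances must be finite and > 0")
  }
  structure(list(label = label, band_variance = band_variance),
            class = "class_profile")
}

#' Default class profiles for the three emotion labels
#'
#' @return Named list of \code{class_profile}s with names "-1", "0", "+1".
#' @export
default_class_profiles <- function() {
  base <- 10  # uV^2 per band for the flat neutral profile
  hi <- 30
  list(
    "-1" = class_profile(-1, c(delta = hi, theta = hi, alpha = base,
                               beta = base, gamma = base)),
    "0"  = class_profile(0,  c(delta = base, theta = base, alpha = base,
                               beta = base, gamma = base)),
    "+1" = class_profile(1,  c(delta = base, theta = base, alpha = base,
                               beta = hi, gamma = hi))
  )
}

# Deterministic sub-seed scheme: recording k of a dataset drawn with master
# seed s uses sub_seed(s, k). Documented so any single recording can be
# regenerated in isolation.
sub_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(counter)) %% 2147483647)
}

#' Generate one synthetic 62-channel EEG recording
#'
#' The signal is a sum over the five canonical bands of independently
#' band-limited Gaussian noise: per channel, white Gaussian noise is passed
#' through the same spectral band masks the feature extractor uses, and each
#' band component is rescaled so its realized sample variance equals the
#' profile's stated variance for that band. Identical arguments (including
#' the seed) give bit-identical output.
#'
#' @param profile a \code{class_profile}.
#' @param duration recording length in seconds (>= 1).
#' @param sample_rate sampling rate in Hz; must be at least twice the highest
#'   band edge (>= 100 Hz).
#' @param seed integer RNG seed.
#' @param n_channels channel count (default 62, the pipeline layout).
#' @return A \code{raw_recording} with \code{label} taken from the profile.
#' @export
#' @examples
#' rec <- generate_recording(default_class_profiles()[["+1"]],
#'                           duration = 4, sample_rate = 200, seed = 7)
#' dim(rec$data)
generate_recording <- function(profile, duration, sample_rate, seed,
                               n_channels = 62L) {
  stopifnot(inherits(profile, "class_profile"))
  if (!is.numeric(duration) || duration < 1) {
    stop("`duration` must be at least 1 second")
  }
  bands <- canonical_bands()
  nyq_needed <- 2 * max(bands$high)
  if (sample_rate < nyq_needed) {
    stop("`sample_rate` (", sample_rate, " Hz) is below the Nyquist rate ",
         nyq_needed, " Hz required for the gamma band (31-50 Hz)")
  }
  n <- round(duration * sample_rate)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # One white-noise draw per channel, masked per band in the frequency
  # domain (equivalent to filtering with the analyzer's band filters). Each
  # band's gain is set so the realized time-domain sample variance equals
  # the profile's stated variance exactly: the masks are zero at DC, so by
  # Parseval that variance is sum(|X g|^2) / (n (n-1)). Disjoint masks make
  # the per-band gains combinable into a single transfer function, i.e. one
  # forward and one inverse DFT per channel.
  white <- matrix(stats::rnorm(n_channels * n), nrow = n_channels)
  x <- stats::mvfft(t(white))
  freqs <- fft_bin_freqs(n, sample_rate)
  pow <- Mod(x)^2
  gain <- matrix(0, nrow = n, ncol = n_channels)
  for (b in seq_len(nrow(bands))) {
    g <- band_mask(freqs, bands$low[b], bands$high[b])
    v <- colSums(pow * g^2) / (n * (n - 1))
    s <- sqrt(profile$band_variance[[b]] / pmax(v, .Machine$double.eps))
    gain <- gain + outer(g, s)
  }
  data <- t(Re(stats::mvfft(x * gain, inverse = TRUE)) / n)
  raw_recording(data, sample_rate, label = profile$label)
}

#' Generate a balanced labeled dataset of synthetic recordings
#'
#' Produces \code{3 * n_per_class} recordings, \code{n_per_class} per emotion
#' label, in interleaved label order (-1, 0, +1, -1, ...). Recording k uses
#' the derived sub-seed \code{(seed + 1000003 * k) mod (2^31 - 1)}, so the
#' whole corpus is reproducible from the master seed and any single
#' recording can be regenerated independently.
#'
#' @param n_per_class recordings per class (>= 1).
#' @param duration seconds per recording (default 180, one trial).
#' @param sample_rate Hz (default 200).
#' @param seed master integer seed.
#' @param profiles named list of three \code{class_profile}s (default
#'   \code{default_class_profiles()}).
#' @return List of \code{raw_recording}s.
#' @export
generate_dataset <- function(n_per_class, duration = 180, sample_rate = 200,
                             seed = 1L, profiles = default_class_profiles()) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("`n_per_class` must be >= 1")
  }
  stopifnot(length(profiles) == 3L)
  labels <- vapply(profiles, function(p) p$label, integer(1))
  if (length(unique(labels)) != 3L) stop("profiles must cover three distinct labels")
  out <- vector("list", 3L * n_per_class)
  k <- 0L
  for (i in seq_len(n_per_class)) {
    for (p in profiles) {
      k <- k + 1L
      out[[k]] <- generate_recording(p, duration, sample_rate,
                                     seed = sub_seed(seed, k))
    }
  }
  out
}

# Save/restore the global RNG state so generators are pure functions of
# their seed argument without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
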