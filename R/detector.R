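# Session-level scoring: one worn-detector measurement -> class
# probabilities -> a 1-100 pleasure score, and baseline-vs-stimulus
# improvement deltas.

#' Detector session configuration
#'
#' A measurement session spans 60 s in total; EEG is acquired during the
#' first 30 s at 200 Hz (one sample every 5 ms), and the remainder of the
#' session is analysis/display time. Only the acquisition window is
#' consumed by \code{classify_session}.
#'
#' @param total_duration seconds (default 60).
#' @param acquisition_duration seconds of EEG actually analyzed (default 30).
#' @param sample_rate Hz (default 200).
#' @return A \code{session_config}.
#' @export
session_config <- function(total_duration = 60, acquisition_duration = 30,
                           sample_rate = 200) {
  stopifnot(total_duration > 0, acquisition_duration > 0, sample_rate > 0)
  if (acquisition_duration > total_duration) {
    stop("acquisition_duration must not exceed total_duration")
  }
  structure(list(total_duration = total_duration,
                 acquisition_duration = acquisition_duration,
                 sample_rate = sample_rate),
            class = "session_config")
}

#' Classify one detector session
#'
#' Runs the full inference chain on the session's acquisition window:
#' preprocess (resample to the session rate, 0-75 Hz zero-phase lowpass,
#' crop to the acquisition window), band-wise differential entropy in 1 s
#' windows, LDS smoothing, window-axis resampling to the 180-window training
#' geometry (sessions are shorter than training trials; the bridge is linear
#' interpolation along time), feature imaging, and the classifier's softmax.
#' Deterministic: the same recording and checkpoint always give identical
#' probabilities.
#'
#' @param rec a 62-channel \code{raw_recording} covering at least the
#'   acquisition window.
#' @param net a trained \code{resnet_classifier} (e.g. from
#'   \code{train_classifier}'s \code{$net} or \code{read_checkpoint}).
#' @param config a \code{session_config}.
#' @param lds an \code{lds_config}.
#' @return Named class-probability vector (negative, neutral, positive).
#' @export
classify_session <- function(rec, net, config = session_config(),
                             lds = lds_config()) {
  assert_pipeline_recording(rec)
  stopifnot(inherits(net, "resnet_classifier"),
            inherits(config, "session_config"))
  pp <- preprocess_config(target_rate = config$sample_rate,
                          segment_length = config$acquisition_duration)
  rec <- preprocess_recording(rec, pp)
  img <- featurize_recording(rec, lds = lds)
  predict_classifier(net, img)
}

#' Map class probabilities to a 1-100 pleasure score
#'
#' \code{score = clamp(round(100 * (p_pos + 0.5 * p_neu)), 1, 100)}: certain
#' positive affect displays 100, certain neutral 50, certain negative 1
#' (clamped from 0). The mapping is strictly increasing in the positive
#' probability for fixed neutral probability — higher positive probability,
#' higher displayed pleasure.
#'
#' @param p probability 3-vector (negative, neutral, positive), summing to 1.
#' @return Integer score in [1, 100].
#' @export
#' @examples
#' pleasure_score(c(0, 1, 0))   # 50
pleasure_score <- function(p) {
  if (length(p) != 3L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-6) {
    stop("`p` must be a nonnegative probability 3-vector summing to 1")
  }
  raw <- 100 * (p[[3]] + 0.5 * p[[2]])
  as.integer(min(max(round(raw), 1), 100))
}

#' Result of one detector session
#'
#' @param probabilities class-probability 3-vector.
#' @param context "baseline" (worn in everyday life before the experiment)
#'   or "stimulus" (worn while experiencing the artwork).
#' @param timestamp POSIXct (defaults to now).
#' @return A \code{session_result} with the derived pleasure score.
#' @export
session_result <- function(probabilities, context = c("baseline", "stimulus"),
                           timestamp = Sys.time()) {
  context <- match.arg(context)
  score <- pleasure_score(probabilities)
  structure(list(probabilities = probabilities, pleasure_score = score,
                 context = context, timestamp = timestamp),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s: pleasure %d (p = %.3f / %.3f / %.3f)\n",
              x$context, x$pleasure_score,
              x$probabilities[[1]], x$probabilities[[2]], x$probabilities[[3]]))
  invisible(x)
}

#' Pleasure improvement between a baseline and a stimulus session
#'
#' The signed delta stimulus - baseline on the 1-100 scale: how much more
#' pleasant the subject's state was while experiencing the artwork than in
#' everyday life.
#'
#' @param baseline,stimulus \code{session_result}s, or bare scores in
#'   [1, 100].
#' @return Signed numeric delta.
#' @export
improvement <- function(baseline, stimulus) {
  score_of <- function(x) {
    if (inherits(x, "session_result")) x <- x$pleasure_score
    if (!is.numeric(x) || length(x) != 1L || x < 1 || x > 100) {
      stop("scores must be single values in [1, 100]")
    }
    x
  }
  score_of(stimulus) - score_of(baseline)
}
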