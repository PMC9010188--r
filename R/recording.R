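#' The 62-channel scalp layout
#'
#' Channel identities and order are pinned to the 62-electrode extended
#' 10-20 layout used by the reference emotion corpus, so that recordings from
#' any source line up channel-for-channel with the trained model.
#'
#' @return Character vector of 62 channel names in canonical order.
#' @export
eeg_channel_layout <- function() {
  c("FP1", "FPZ", "FP2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "CB1", "O1", "OZ", "O2", "CB2")
}

#' Construct a raw multichannel EEG recording
#'
#' A \code{raw_recording} is the pipeline's unit of EEG: a channels x samples
#' numeric matrix in microvolts plus its sampling rate, channel names, and an
#' optional emotion label in \{-1, 0, +1\} (negative / neutral / positive).
#'
#' @param data numeric matrix, channels as rows, samples as columns (uV).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param channel_names character vector, one name per row; defaults to the
#'   canonical 62-channel layout when the matrix has 62 rows, otherwise
#'   "ch1", "ch2", ...
#' @param label optional emotion label, one of -1, 0, +1, or NULL.
#' @return Object of class \code{raw_recording}.
#' @export
raw_recording <- function(data, sample_rate, channel_names = NULL, label = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number (Hz)")
  }
  if (any(!is.finite(data))) {
    stop("recording contains non-finite samples")
  }
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) == 62L) eeg_channel_layout() else
      paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` length (", length(channel_names),
         ") does not match channel count (", nrow(data), ")")
  }
  label <- validate_label(label)
  rownames(data) <- channel_names
  structure(
    list(data = data, sample_rate = as.numeric(sample_rate),
         channel_names = as.character(channel_names), label = label),
    class = "raw_recording"
  )
}

validate_label <- function(label) {
  if (is.null(label) || (length(label) == 1L && is.na(label))) return(NULL)
  if (!(length(label) == 1L && label %in% c(-1, 0, 1))) {
    stop("`label` must be -1 (negative), 0 (neutral) or +1 (positive)")
  }
  as.integer(label)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate,
              if (is.null(x$label)) "" else sprintf(", label %+d", x$label)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a \code{raw_recording}.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  ncol(rec$data) / rec$sample_rate
}

#' Check that a recording conforms to the 62-channel pipeline contract
#'
#' @param rec a \code{raw_recording}.
#' @param require_62 require exactly 62 channels (default TRUE).
#' @return \code{rec}, invisibly; error otherwise.
#' @export
assert_pipeline_recording <- function(rec, require_62 = TRUE) {
  stopifnot(inherits(rec, "raw_recording"))
  if (require_62 && nrow(rec$data) != 62L) {
    stop("recording has ", nrow(rec$data), " channels; the pipeline expects the ",
         "62-channel 10-20 layout (see eeg_channel_layout())")
  }
  if (any(!is.finite(rec$data))) stop("recording contains non-finite samples")
  invisible(rec)
}
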