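#' Canonical EEG frequency bands
#'
#' The five-band partition used throughout the pipeline: delta 1-3 Hz,
#' theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz, gamma 31-50 Hz. Band-wise
#' differential entropy is computed per band, and the synthetic generator
#' shapes its per-class variance profile on the same grid, so generator and
#' analyzer always agree on the band edges.
#'
#' @return A data.frame with columns \code{name}, \code{low}, \code{high}
#'   (Hz), one row per band, in fixed delta..gamma order.
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 8, 14, 31),
    high = c(3, 7, 13, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' Validate a band definition table
#'
#' @param bands data.frame with columns name, low, high.
#' @return The validated table, invisibly.
#' @keywords internal
validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "low", "high") %in% names(bands)))
  if (any(!(bands$low > 0 & bands$low < bands$high))) {
    stop("each band must satisfy 0 < low < high (Hz)")
  }
  invisible(bands)
}

#' Number of canonical bands
#' @keywords internal
n_bands <- function() nrow(canonical_bands())
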