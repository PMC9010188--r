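# Detector-vs-questionnaire evaluation arithmetic: per-pair absolute error
# on the 1-100 scale, mean error, accuracy as 100 - mean error, and
# between-artwork contrast consistency.

#' Per-pair detector-vs-reference error report
#'
#' Errors are element-wise absolute differences of paired scores on the
#' 1-100 scale; \code{mean_error} is their arithmetic mean and
#' \code{accuracy_percent = 100 - mean_error} (the reading under which a
#' mean error of 2.77 corresponds to an accuracy of about 97%).
#'
#' @param detector_scores,reference_scores equal-length non-empty numeric
#'   vectors of scores in [1, 100].
#' @return An \code{evaluation_report} with fields \code{per_pair_errors},
#'   \code{mean_error}, \code{accuracy_percent}, \code{n_pairs}.
#' @export
#' @examples
#' pairwise_error(c(80), c(82))   # mean error 2, accuracy 98
pairwise_error <- function(detector_scores, reference_scores) {
  check_scores(detector_scores)
  check_scores(reference_scores)
  if (length(detector_scores) != length(reference_scores)) {
    stop("score lists must have equal length (got ",
         length(detector_scores), " vs ", length(reference_scores), ")")
  }
  errs <- abs(detector_scores - reference_scores)
  structure(list(per_pair_errors = errs,
                 mean_error = mean(errs),
                 accuracy_percent = 100 - mean(errs),
                 n_pairs = length(errs)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d pairs: mean error %.2f, accuracy %.2f%%\n",
              x$n_pairs, x$mean_error, x$accuracy_percent))
  invisible(x)
}

#' Between-group contrast consistency
#'
#' Each side contributes the difference of its two group means (first -
#' second); the discrepancy is the absolute difference of the two contrasts.
#' With detector-side means (34.2, 22) and questionnaire-side means
#' (82, 70) the contrasts are 12.2 and 12 and the discrepancy 0.2.
#'
#' @param detector_group_means,reference_group_means numeric length-2
#'   vectors of group means.
#' @return A \code{contrast_result} with \code{detector_contrast},
#'   \code{reference_contrast}, \code{discrepancy}.
#' @export
contrast_consistency <- function(detector_group_means, reference_group_means) {
  stopifnot(length(detector_group_means) == 2L,
            length(reference_group_means) == 2L,
            all(is.finite(detector_group_means)),
            all(is.finite(reference_group_means)))
  dc <- detector_group_means[[1]] - detector_group_means[[2]]
  rc <- reference_group_means[[1]] - reference_group_means[[2]]
  structure(list(detector_contrast = dc, reference_contrast = rc,
                 discrepancy = abs(dc - rc)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result> detector %.4g vs reference %.4g (discrepancy %.4g)\n",
    x$detector_contrast, x$reference_contrast, x$discrepancy))
  invisible(x)
}

#' Mean of questionnaire pleasure ratings
#'
#' @param scores non-empty vector of ratings in [1, 100].
#' @return Arithmetic mean.
#' @export
questionnaire_mean <- function(scores) {
  check_scores(scores)
  mean(scores)
}

check_scores <- function(x) {
  if (length(x) == 0L || !is.numeric(x)) stop("scores must be a non-empty numeric vector")
  if (any(!is.finite(x)) || any(x < 1) || any(x > 100)) {
    stop("scores must lie in [1, 100]")
  }
  invisible(x)
}

#' Evaluate a detector study table against questionnaire references
#'
#' Convenience wrapper over the whole evaluation arithmetic. The study
#' table has one row per (subject, artwork) with baseline and stimulus
#' detector scores; the questionnaire table has one row per (respondent,
#' artwork) rating. Two comparison modes are exposed because the underlying
#' protocol is ambiguous about which detector quantity is compared with the
#' questionnaire mean: \code{"stimulus"} compares raw stimulus-session
#' scores, \code{"improvement"} compares improvement deltas.
#'
#' @param study data.frame with columns subject, artwork, baseline, stimulus.
#' @param questionnaire data.frame with columns respondent, artwork, rating.
#' @param artworks length-2 vector naming the two artworks to contrast.
#' @param compare "stimulus" or "improvement".
#' @return List with \code{improvement_means} (named per artwork),
#'   \code{questionnaire_means}, \code{report} (an
#'   \code{evaluation_report} over per-subject pairs for the contrasted
#'   artworks), and \code{contrast} (a \code{contrast_result}).
#' @export
evaluate_study <- function(study, questionnaire, artworks,
                           compare = c("stimulus", "improvement")) {
  compare <- match.arg(compare)
  stopifnot(all(c("subject", "artwork", "baseline", "stimulus") %in% names(study)),
            all(c("respondent", "artwork", "rating") %in% names(questionnaire)),
            length(artworks) == 2L)
  study$improvement <- mapply(improvement, study$baseline, study$stimulus)
  imp_means <- c(tapply(study$improvement, study$artwork, mean))
  q_means <- c(tapply(questionnaire$rating, questionnaire$artwork, mean))
  a1 <- as.character(artworks[[1]]); a2 <- as.character(artworks[[2]])
  if (!all(c(a1, a2) %in% names(imp_means)) ||
      !all(c(a1, a2) %in% names(q_means))) {
    stop("both artworks must appear in the study and questionnaire tables")
  }
  sub <- study[study$artwork %in% artworks, ]
  det_side <- if (compare == "stimulus") sub$stimulus else sub$improvement
  ref_side <- q_means[as.character(sub$artwork)]
  report <- pairwise_error(det_side, as.numeric(ref_side))
  contrast <- contrast_consistency(c(imp_means[[a1]], imp_means[[a2]]),
                                   c(q_means[[a1]], q_means[[a2]]))
  list(improvement_means = imp_means, questionnaire_means = q_means,
       report = report, contrast = contrast)
}
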