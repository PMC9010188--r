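test_that("pairwise_error computes absolute errors and the accuracy reading", {
  r <- pairwise_error(80, 82)
  expect_equal(r$mean_error, 2)
  expect_equal(r$accuracy_percent, 98)
  expect_equal(r$n_pairs, 1L)

  same <- pairwise_error(c(10, 50, 90), c(10, 50, 90))
  expect_equal(same$mean_error, 0)
  expect_equal(same$accuracy_percent, 100)

  # a mean absolute error of 2.77 reads as 97% accuracy at integer precision
  det <- c(80, 75, 62, 90)
  ref <- det + 2.77
  r277 <- pairwise_error(det, ref)
  expect_equal(r277$mean_error, 2.77)
  expect_equal(r277$accuracy_percent, 97.23)
  expect_equal(round(r277$accuracy_percent), 97)

  expect_error(pairwise_error(c(50, 60), 50), "equal length")
  expect_error(pairwise_error(c(50, 120), c(50, 60)), "\\[1, 100\\]")
})

test_that("pairwise_error is symmetric and couples accuracy to mean error", {
  set.seed(14)
  for (k in 1:10) {
    a <- runif(8, 1, 100); b <- runif(8, 1, 100)
    r1 <- pairwise_error(a, b); r2 <- pairwise_error(b, a)
    expect_equal(r1$per_pair_errors, r2$per_pair_errors)
    expect_equal(r1$accuracy_percent + r1$mean_error, 100)
  }
})

test_that("contrast_consistency reproduces the worked group-mean contrast", {
  r <- contrast_consistency(c(34.2, 22), c(82, 70))
  expect_equal(r$detector_contrast, 12.2)
  expect_equal(r$reference_contrast, 12)
  expect_equal(r$discrepancy, 0.2)

  expect_equal(contrast_consistency(c(5, 1), c(9, 5))$discrepancy, 0)
  # swapping group order on both sides keeps the discrepancy
  r_swap <- contrast_consistency(c(22, 34.2), c(70, 82))
  expect_equal(r_swap$discrepancy, r$discrepancy)
  # adding a constant to all four means changes nothing
  r_shift <- contrast_consistency(c(34.2, 22) + 7, c(82, 70) + 7)
  expect_equal(r_shift$discrepancy, r$discrepancy)
})

test_that("questionnaire_mean averages valid ratings only", {
  expect_equal(questionnaire_mean(rep(82, 28)), 82)
  expect_equal(questionnaire_mean(c(70, 90)), 80)
  expect_error(questionnaire_mean(c(50, 101)), "\\[1, 100\\]")
  expect_error(questionnaire_mean(numeric(0)), "non-empty")
})

test_that("evaluate_study reproduces the study's printed summaries", {
  study <- read.csv(system.file("extdata", "study_sessions_synthetic.csv",
                                package = "eegaffect"))
  quest <- read.csv(system.file("extdata", "questionnaire_synthetic.csv",
                                package = "eegaffect"))
  res <- evaluate_study(study, quest, artworks = c(1, 5))
  expect_equal(unname(res$improvement_means[c("1", "5")]), c(34.2, 22))
  expect_equal(unname(res$questionnaire_means[c("1", "5")]), c(82, 70))
  expect_equal(res$report$mean_error, 2.77)
  expect_equal(round(res$report$accuracy_percent), 97)
  expect_equal(res$contrast$detector_contrast, 12.2)
  expect_equal(res$contrast$reference_contrast, 12)
  expect_equal(res$contrast$discrepancy, 0.2, tolerance = 1e-9)

  # improvement-based comparison is exposed as the alternative reading
  res_imp <- evaluate_study(study, quest, artworks = c(1, 5),
                            compare = "improvement")
  expect_s3_class(res_imp$report, "evaluation_report")
  expect_error(evaluate_study(study, quest, artworks = c(1, 9)),
               "must appear")
})
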