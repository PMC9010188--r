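test_that("generated recordings have the forced shape, label and determinism", {
  p <- default_class_profiles()
  rec <- generate_recording(p[["+1"]], duration = 4, sample_rate = 200, seed = 7)
  expect_identical(dim(rec$data), c(62L, 800L))
  expect_identical(rec$label, 1L)
  expect_identical(rec$channel_names, eeg_channel_layout())
  expect_true(all(is.finite(rec$data)))

  rec2 <- generate_recording(p[["+1"]], duration = 4, sample_rate = 200, seed = 7)
  expect_identical(rec$data, rec2$data)

  rec3 <- generate_recording(p[["+1"]], duration = 4, sample_rate = 200, seed = 8)
  expect_false(identical(rec$data, rec3$data))
})

test_that("generation rejects sub-Nyquist rates and short durations", {
  p <- default_class_profiles()[["0"]]
  expect_error(generate_recording(p, 4, sample_rate = 80, seed = 1), "Nyquist")
  expect_error(generate_recording(p, 0.5, 200, seed = 1), "at least 1 second")
})

test_that("realized band variance tracks the profile (periodogram oracle)", {
  profiles <- default_class_profiles()
  hot <- class_profile(1, c(delta = 10, theta = 10, alpha = 10, beta = 10,
                            gamma = 100))
  rec_hot <- generate_recording(hot, 180, 200, seed = 11)
  rec_neu <- generate_recording(profiles[["0"]], 180, 200, seed = 11)
  v_hot <- mean(apply(rec_hot$data[1:8, ], 1, periodogram_band_var,
                      fs = 200, low = 31, high = 50))
  v_neu <- mean(apply(rec_neu$data[1:8, ], 1, periodogram_band_var,
                      fs = 200, low = 31, high = 50))
  expect_lt(abs(v_hot / v_neu - 10) / 10, 0.2)
  # and the neutral profile itself is on target
  expect_lt(abs(v_neu - 10) / 10, 0.2)
})

test_that("class profiles validate their variances and labels", {
  expect_error(class_profile(2, c(delta = 1, theta = 1, alpha = 1, beta = 1,
                                  gamma = 1)), "label")
  expect_error(class_profile(1, c(delta = -1, theta = 1, alpha = 1, beta = 1,
                                  gamma = 1)), "> 0")
  expect_error(class_profile(1, c(a = 1, b = 1, c = 1, d = 1, e = 1)),
               "canonical band")
  profs <- default_class_profiles()
  sigs <- lapply(profs, function(p) unname(p$band_variance))
  expect_false(identical(sigs[[1]], sigs[[2]]))
  expect_false(identical(sigs[[2]], sigs[[3]]))
})

test_that("generate_dataset yields balanced, seed-reproducible corpora", {
  recs <- generate_dataset(5, duration = 1, sample_rate = 200, seed = 3)
  expect_length(recs, 15L)
  labels <- vapply(recs, function(r) r$label, integer(1))
  expect_identical(as.vector(table(labels)), c(5L, 5L, 5L))

  recs2 <- generate_dataset(5, duration = 1, sample_rate = 200, seed = 3)
  expect_identical(lapply(recs, `[[`, "data"), lapply(recs2, `[[`, "data"))
  expect_identical(labels, vapply(recs2, function(r) r$label, integer(1)))

  expect_error(generate_dataset(0), ">= 1")
})

test_that("a 225-per-class corpus matches the 675-group corpus size", {
  recs <- generate_dataset(225, duration = 1, sample_rate = 200, seed = 1)
  expect_length(recs, 675L)
  labels <- vapply(recs, function(r) r$label, integer(1))
  expect_identical(as.vector(table(labels)), c(225L, 225L, 225L))
})

test_that("default profiles yield class-separated DE features", {
  # >= 30 recordings per class; short trials keep this property test cheap
  profs <- default_class_profiles()
  per_band_means <- function(p, seeds) {
    t(vapply(seeds, function(s) {
      rec <- generate_recording(p, duration = 10, sample_rate = 200, seed = s,
                                n_channels = 8L)
      tens <- extract_de_tensor(rec)
      apply(tens$values, 3, mean)
    }, numeric(5)))
  }
  seeds <- 1:30
  m_neg <- per_band_means(profs[["-1"]], seeds)
  m_neu <- per_band_means(profs[["0"]], seeds + 100)
  m_pos <- per_band_means(profs[["+1"]], seeds + 200)
  sep <- function(a, b) {
    any(abs(colMeans(a) - colMeans(b)) >
          pmax(apply(a, 2, sd), apply(b, 2, sd)))
  }
  expect_true(sep(m_neg, m_neu))
  expect_true(sep(m_neu, m_pos))
  expect_true(sep(m_neg, m_pos))
})
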