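test_that("differential entropy matches the Gaussian closed form", {
  # closed-form zero point: sigma^2 = 1/(2*pi*e) gives DE = 0
  x <- rnorm(5000)
  x0 <- as.numeric(scale(x)) * sqrt(1 / (2 * pi * exp(1)))
  expect_equal(differential_entropy(x0), 0, tolerance = 1e-10)
  # unit variance gives 0.5 * ln(2*pi*e) ~ 1.4189
  x1 <- as.numeric(scale(x))
  expect_equal(differential_entropy(x1), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-10)
  expect_error(differential_entropy(1), "at least 2")
})

test_that("DE is mean-invariant and monotone in variance", {
  set.seed(4)
  x <- rnorm(500, sd = 2)
  expect_equal(differential_entropy(x), differential_entropy(x + 100))
  des <- vapply(c(0.1, 0.5, 1, 2, 5, 20), function(s)
    differential_entropy(x / sd(x) * s), numeric(1))
  expect_true(all(diff(des) > 0))
})

test_that("constant windows hit the documented floor, never -Inf", {
  f <- differential_entropy(rep(3.7, 100))
  expect_true(is.finite(f))
  expect_equal(f, 0.5 * log(2 * pi * exp(1) * 1e-12))
})

test_that("extract_de_tensor has the contract shape and band ordering", {
  rec <- generate_recording(default_class_profiles()[["0"]], 12, 200,
                            seed = 9, n_channels = 4L)
  tens <- extract_de_tensor(rec, window_length = 1)
  expect_identical(dim(tens$values), c(4L, 12L, 5L))
  expect_true(all(is.finite(tens$values)))
  expect_identical(tens$bands$name, canonical_bands()$name)

  expect_error(extract_de_tensor(segment_recording(rec, 11.5), 1),
               "not a multiple")
})

test_that("band DE differences follow 0.5*log of the band-variance ratio", {
  hot <- class_profile(1, c(delta = 10, theta = 10, alpha = 10, beta = 10,
                            gamma = 100))
  rec <- generate_recording(hot, 60, 200, seed = 13, n_channels = 8L)
  tens <- extract_de_tensor(rec)
  # oracle: closed form on the measured band variances. Beta and gamma have
  # comparable bandwidth, so the log-variance estimator bias of 1 s windows
  # cancels in their difference; narrow low bands (delta) carry a large
  # small-sample bias and are checked for ordering only.
  de_gap <- mean(tens$values[, , 5]) - mean(tens$values[, , 4])
  v_gamma <- mean(apply(rec$data, 1, periodogram_band_var, fs = 200,
                        low = 31, high = 50))
  v_beta <- mean(apply(rec$data, 1, periodogram_band_var, fs = 200,
                       low = 14, high = 30))
  expect_equal(de_gap, 0.5 * log(v_gamma / v_beta), tolerance = 0.05)
  # DE ordering matches band-variance ordering
  expect_gt(mean(tens$values[, , 5]), mean(tens$values[, , 1]))
})

test_that("a constant channel produces floor DE in every band", {
  data <- rbind(rep(1.5, 2000), rnorm(2000))
  rec <- raw_recording(data, 200)
  tens <- extract_de_tensor(rec)
  expect_true(all(abs(tens$values[1, , ] - 0.5 * log(2 * pi * exp(1) * 1e-12)) < 0.5))
})

test_that("lds_smooth honors its fixed points and noise-rejection contract", {
  expect_identical(lds_smooth(rep(2.5, 50)), rep(2.5, 50))
  expect_identical(lds_smooth(7), 7)
  expect_error(lds_smooth(c(1, NA, 3)), "non-finite")

  # alternating +-eps around a constant collapses to the constant
  eps <- 0.05
  y <- 3 + eps * rep_len(c(1, -1), 120)
  sm <- lds_smooth(y)
  expect_true(all(abs(sm - 3) < eps))
  # oracle comparison: no worse than a 20-point moving average
  ma <- lds_smooth(y, lds_config(method = "moving_average"))
  expect_lte(max(abs(sm - 3)), max(abs(ma - 3)) + 1e-9)
})

test_that("lds_smooth never roughens and preserves the mean", {
  set.seed(8)
  for (k in 1:10) {
    y <- cumsum(rnorm(150, sd = 0.3)) + rnorm(150)
    sm <- lds_smooth(y)
    expect_length(sm, length(y))
    expect_lte(var(diff(sm)), var(diff(y)) + 1e-12)
  }
  y_stat <- rnorm(200, mean = 5)
  sm <- lds_smooth(y_stat)
  expect_lt(abs(mean(sm) - mean(y_stat)) / abs(mean(y_stat)), 0.01)
})

test_that("minmax_standardize maps range to [0, 1] and is affine-invariant", {
  expect_equal(minmax_standardize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 0.8, 1)
  expect_equal(minmax_standardize(x), x)
  set.seed(2)
  for (k in 1:10) {
    z <- rnorm(30)
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 50)
    expect_equal(minmax_standardize(a * z + b), minmax_standardize(z),
                 tolerance = 1e-10)
  }
  expect_warning(out <- minmax_standardize(rep(3, 5)), "degenerate")
  expect_equal(out, rep(0.5, 5))
  expect_error(minmax_standardize(numeric(0)), "non-empty")
})

test_that("feature images are 224 x 224 in [0, 1] with audit extrema", {
  tc <- tiny_corpus()
  img <- tc$imgs[[1]]
  expect_s3_class(img, "feature_image")
  expect_identical(dim(img$values), c(224L, 224L))
  expect_true(all(img$values >= 0 & img$values <= 1))
  expect_lt(img$scale_min, img$scale_max)

  const <- de_tensor(array(1.3, dim = c(62, 180, 5)))
  expect_warning(cimg <- to_feature_image(const), "degenerate")
  expect_true(all(cimg$values == 0.5))

  bad <- de_tensor(array(0, dim = c(10, 10, 5)))
  expect_error(to_feature_image(bad), "62 x 180 x 5")
})

test_that("band edits stay in their mapped image rows before standardization", {
  set.seed(6)
  base <- array(rnorm(62 * 180 * 5), dim = c(62, 180, 5))
  mod <- base
  mod[, , 3] <- mod[, , 3] + 5           # alpha band only
  p1 <- de_plane(de_tensor(base))
  p2 <- de_plane(de_tensor(mod))
  r1 <- eegaffect:::bilinear_resize(p1, 224, 224)
  r2 <- eegaffect:::bilinear_resize(p2, 224, 224)
  changed <- which(rowSums(abs(r1 - r2)) > 1e-9)
  # rows sampled from source rows 125..186 (the alpha block of the 310-row
  # plane) under corner-aligned bilinear mapping
  src <- 1 + (seq_len(224) - 1) * (310 - 1) / (224 - 1)
  expected <- which(ceiling(src) >= 125 & floor(src) <= 186)
  expect_true(all(changed %in% expected))
  expect_gt(length(changed), 0)
})

test_that("tensor -> image chain is deterministic and serializes bit-exactly", {
  tc <- tiny_corpus()
  rec <- tc$recs[[1]]
  t1 <- extract_de_tensor(segment_recording(rec, 20))
  t2 <- extract_de_tensor(segment_recording(rec, 20))
  expect_identical(t1$values, t2$values)

  path <- withr::local_tempfile(fileext = ".rds")
  save_container(t1, path)
  t3 <- load_container(path, "de_tensor")
  expect_identical(t1, t3)
  sm1 <- lds_smooth_tensor(t1)
  sm3 <- lds_smooth_tensor(t3)
  img1 <- to_feature_image(resample_window_axis(sm1, 180))
  img3 <- to_feature_image(resample_window_axis(sm3, 180))
  expect_identical(img1$values, img3$values)
})

test_that("window-axis resampling bridges short sessions to 180 windows", {
  rec <- generate_recording(default_class_profiles()[["0"]], 30, 200,
                            seed = 21, n_channels = 4L)
  tens <- extract_de_tensor(rec)
  out <- resample_window_axis(tens, 180L)
  expect_identical(dim(out$values), c(4L, 180L, 5L))
  # endpoint values are preserved by linear interpolation
  expect_equal(out$values[, 1, ], tens$values[, 1, ])
  expect_equal(out$values[, 180, ], tens$values[, 30, ])
  expect_identical(resample_window_axis(tens, 30L), tens)
})
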