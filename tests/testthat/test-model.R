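test_that("relu follows its piecewise definition", {
  expect_identical(relu(5), 5)
  expect_identical(relu(-3), 0)
  expect_identical(relu(0), 0)
  expect_equal(relu(c(-2, 0, 7)), c(0, 0, 7))
  expect_error(relu(NA_real_), "finite")
})

test_that("softmax normalizes, shifts invariantly, and survives big logits", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  for (c0 in c(-50, 0, 123.4)) {
    expect_equal(softmax(c(c0, c0 + log(2), c0)), c(0.25, 0.5, 0.25))
  }
  p <- softmax(c(1000, 0, 0))
  expect_false(any(is.nan(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # oracle: evaluated in shifted (exact) form, exp(-1000) underflows to 0
  expect_equal(p, c(1, 0, 0), tolerance = 1e-300)
  expect_error(softmax(numeric(0)), "non-empty")

  set.seed(3)
  for (k in 1:20) {
    x <- rnorm(3, sd = 10)
    p <- softmax(x)
    expect_true(all(p > 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_equal(softmax(x + rnorm(1, sd = 100)), p, tolerance = 1e-9)
  }
})

test_that("categorical cross-entropy matches both printed forms", {
  expect_equal(categorical_crossentropy(c(1, 0, 0), c(1, 0, 0)), 0,
               tolerance = 1e-10)
  # two-term (binary-sum) form on the uniform prediction
  expect_equal(
    categorical_crossentropy(c(1, 0, 0), rep(1 / 3, 3), form = "binary_sum"),
    -(log(1 / 3) + 2 * log(2 / 3)), tolerance = 1e-12)
  # multiclass form
  expect_equal(categorical_crossentropy(c(1, 0, 0), rep(1 / 3, 3)), log(3),
               tolerance = 1e-12)
  # batch mean: duplicating an item leaves the loss unchanged
  y <- rbind(c(0, 1, 0), c(0, 1, 0))
  a <- rbind(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3))
  expect_equal(categorical_crossentropy(y, a),
               categorical_crossentropy(y[1, ], a[1, ]))
  expect_error(categorical_crossentropy(c(1, 0), c(1, 0, 0)), "same length")
})

test_that("the full-depth preset matches the published structure", {
  cfg <- network_config("resnet50")
  expect_identical(cfg$stage_block_counts, c(3L, 4L, 6L, 3L))
  expect_error(network_config("resnet50", input_shape = c(128L, 128L)),
               "224")
  expect_error(network_config("resnet50", stage_block_counts = c(2, 2, 2, 2)),
               "3, 4, 6, 3")
})

test_that("small networks build, predict a softmax 3-vector, and are seeded", {
  net <- build_network(network_config("small", input_shape = c(32L, 32L)),
                       seed = 4)
  expect_identical(stage_block_counts(net), c(1L, 1L, 1L, 1L))
  expect_identical(n_residual_blocks(net), 4L)
  expect_identical(n_weighted_layers(net), 14L)  # 1 + 3*4 + 1

  img <- matrix(runif(32 * 32), 32)
  p <- predict_classifier(net, img)
  expect_length(p, 3L)
  expect_named(p, c("negative", "neutral", "positive"))
  expect_equal(sum(p), 1, tolerance = 1e-9)

  net2 <- build_network(network_config("small", input_shape = c(32L, 32L)),
                        seed = 4)
  expect_identical(net$params, net2$params)
  expect_error(eegaffect:::net_forward(net, matrix(0, 16, 16)), "32 x 32")
})

test_that("a zeroed residual branch leaves the shortcut untouched", {
  net <- build_network(network_config("small", input_shape = c(32L, 32L)),
                       seed = 1)
  blk <- net$arch$stages[[1]][[1]]
  expect_false(blk$has_proj)   # stage 1 keeps channel count: identity shortcut
  for (cv in c("conv1", "conv2", "conv3")) {
    id <- blk[[cv]]$id
    net$params[[id]]$W[] <- 0
    net$params[[id]]$b[] <- 0
  }
  x <- array(abs(rnorm(8 * 8 * blk$conv1$cin)), dim = c(8, 8, blk$conv1$cin))
  out <- residual_block_forward(x, blk, net$params)
  expect_identical(out, x)   # relu(0 + x) = x for nonnegative x
})

test_that("split_dataset reproduces the corpus split arithmetic", {
  sp <- split_dataset(675, seed = 1)
  expect_length(sp$train, 607L)
  expect_length(sp$test, 68L)
  expect_identical(sort(c(sp$train, sp$test)), 1:675)

  sp10 <- split_dataset(10, seed = 2)
  expect_length(sp10$train, 9L)
  expect_length(sp10$test, 1L)

  expect_identical(split_dataset(100, seed = 7), split_dataset(100, seed = 7))
  expect_false(identical(split_dataset(100, seed = 7),
                         split_dataset(100, seed = 8)))
  expect_error(split_dataset(3, ratio = c(99, 1), seed = 1), "degenerate")
})

test_that("select_best_epoch takes the earliest argmax", {
  rec <- function(acc) data.frame(epoch = seq_along(acc), test_accuracy = acc)
  expect_identical(select_best_epoch(rec(c(0.5, 0.7, 0.6))), 2L)
  expect_identical(select_best_epoch(rec(c(0.7, 0.7))), 1L)
  expect_identical(select_best_epoch(rec(0.4)), 1L)
})

test_that("training produces one record per epoch and is seed-reproducible", {
  set.seed(11)
  labels <- rep(c(-1, 0, 1), 3)
  imgs <- lapply(labels, function(l) matrix(0.5 + 0.3 * l, 32, 32))
  net <- build_network(network_config("small", input_shape = c(32L, 32L)),
                       seed = 5)
  cfg <- training_config(epochs = 3, seed = 5)
  fit1 <- train_classifier(net, list(images = imgs, labels = labels),
                           list(images = imgs, labels = labels), cfg)
  expect_identical(nrow(fit1$records), 3L)
  expect_identical(fit1$records$epoch, 1:3)
  expect_true(all(fit1$records$test_accuracy >= 0 &
                    fit1$records$test_accuracy <= 1))
  fit2 <- train_classifier(net, list(images = imgs, labels = labels),
                           list(images = imgs, labels = labels), cfg)
  expect_identical(fit1$records, fit2$records)
  expect_identical(fit1$best$params, fit2$best$params)

  expect_error(train_classifier(net, list(images = list(), labels = integer(0)),
                                list(images = imgs, labels = labels), cfg),
               "non-empty")
})

test_that("label/class mapping is the fixed documented bijection", {
  expect_identical(label_to_class(c(-1, 0, 1)), 1:3)
  expect_identical(class_to_label(1:3), c(-1L, 0L, 1L))
  expect_error(label_to_class(2), "labels")
})
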