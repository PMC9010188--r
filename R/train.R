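# Forward/backward passes and the Adam training loop.
#
# Convolutions are im2col patch matrices (C++) times BLAS matrix products.
# Images are processed one at a time; batch gradients are accumulated and
# averaged, so "batch 5" has its usual mini-batch-SGD meaning without a
# 4-D tensor layer in R.

conv_forward <- function(x, sp, params) {
  d <- dim(x)
  cols <- im2col_cpp(as.numeric(x), d[1], d[2], d[3],
                     sp$kh, sp$kw, sp$stride, sp$pad)
  p <- params[[sp$id]]
  out <- cols %*% p$W
  out <- sweep(out, 2L, p$b, "+")
  ho <- (d[1] + 2L * sp$pad - sp$kh) %/% sp$stride + 1L
  wo <- (d[2] + 2L * sp$pad - sp$kw) %/% sp$stride + 1L
  dim(out) <- c(ho, wo, sp$cout)
  list(out = out, cache = list(cols = cols, in_dim = d))
}

conv_backward <- function(dout, sp, params, cache) {
  d <- dim(dout)
  dmat <- matrix(dout, nrow = d[1] * d[2])
  grads <- list(W = crossprod(cache$cols, dmat), b = colSums(dmat))
  dcols <- tcrossprod(dmat, params[[sp$id]]$W)
  dx <- col2im_cpp(dcols, cache$in_dim[1], cache$in_dim[2], cache$in_dim[3],
                   sp$kh, sp$kw, sp$stride, sp$pad)
  dim(dx) <- cache$in_dim
  list(dx = dx, grads = grads)
}

#' Forward pass through one bottleneck residual block
#'
#' Computes relu(F(x) + shortcut(x)) where F is the 1x1 -> 3x3 -> 1x1
#' convolution branch and the shortcut is the identity, or a learned 1x1
#' projection when channel count or stride changes. Exposed for structural
#' tests (e.g. the identity-mapping property with a zeroed branch).
#'
#' @param x input H x W x C array.
#' @param blk block spec from \code{net$arch$stages[[s]][[b]]}.
#' @param params the network's parameter list.
#' @param want_cache keep intermediate activations for backprop.
#' @return The block output array (or list(out, cache) if \code{want_cache}).
#' @export
residual_block_forward <- function(x, blk, params, want_cache = FALSE) {
  c1 <- conv_forward(x, blk$conv1, params)
  a1 <- pmax(c1$out, 0)
  c2 <- conv_forward(a1, blk$conv2, params)
  a2 <- pmax(c2$out, 0)
  c3 <- conv_forward(a2, blk$conv3, params)
  if (blk$has_proj) {
    pr <- conv_forward(x, blk$proj, params)
    sc <- pr$out
  } else {
    pr <- NULL
    sc <- x
  }
  pre <- c3$out + sc
  out <- pmax(pre, 0)
  if (!want_cache) return(out)
  list(out = out,
       cache = list(c1 = c1$cache, c2 = c2$cache, c3 = c3$cache,
                    proj = if (!is.null(pr)) pr$cache,
                    m1 = c1$out > 0, m2 = c2$out > 0, mout = pre > 0))
}

residual_block_backward <- function(dout, blk, params, cache, grads) {
  dpre <- dout * cache$mout
  b3 <- conv_backward(dpre, blk$conv3, params, cache$c3)
  grads[[blk$conv3$id]] <- acc_grad(grads[[blk$conv3$id]], b3$grads)
  da2 <- b3$dx * cache$m2
  b2 <- conv_backward(da2, blk$conv2, params, cache$c2)
  grads[[blk$conv2$id]] <- acc_grad(grads[[blk$conv2$id]], b2$grads)
  da1 <- b2$dx * cache$m1
  b1 <- conv_backward(da1, blk$conv1, params, cache$c1)
  grads[[blk$conv1$id]] <- acc_grad(grads[[blk$conv1$id]], b1$grads)
  dx <- b1$dx
  if (blk$has_proj) {
    bp <- conv_backward(dpre, blk$proj, params, cache$proj)
    grads[[blk$proj$id]] <- acc_grad(grads[[blk$proj$id]], bp$grads)
    dx <- dx + bp$dx
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = grads)
}

acc_grad <- function(old, new) {
  if (is.null(old)) new else list(W = old$W + new$W, b = old$b + new$b)
}

# Full forward pass for one image (H x W matrix in [0, 1]).
net_forward <- function(net, image, want_cache = FALSE) {
  cfg <- net$config
  if (!identical(dim(image)[1:2], as.integer(cfg$input_shape))) {
    stop("input image must be ", cfg$input_shape[1], " x ", cfg$input_shape[2],
         " for this network")
  }
  x <- array(image, dim = c(dim(image)[1:2], 1L))
  st <- conv_forward(x, net$arch$stem, net$params)
  a <- pmax(st$out, 0)
  d <- dim(a)
  mp <- maxpool_fwd_cpp(as.numeric(a), d[1], d[2], d[3], 3L, 2L, 1L)
  x <- array(mp$out, dim = mp$dim)
  caches <- if (want_cache) {
    list(stem = st$cache, stem_mask = st$out > 0, pool = mp, pool_in_dim = d,
         blocks = list())
  }
  for (s in 1:4) for (b in seq_along(net$arch$stages[[s]])) {
    blk <- net$arch$stages[[s]][[b]]
    r <- residual_block_forward(x, blk, net$params, want_cache = want_cache)
    if (want_cache) {
      caches$blocks[[sprintf("s%db%d", s, b)]] <-
        c(r$cache, list(in_dim = dim(x)))
      x <- r$out
    } else {
      x <- r
    }
  }
  gap_dim <- dim(x)
  v <- apply(x, 3L, mean)
  logits <- as.numeric(v %*% net$params$fc$W) + net$params$fc$b
  probs <- softmax(logits)
  if (!want_cache) return(probs)
  list(probs = probs, logits = logits, gap = v, gap_dim = gap_dim,
       caches = caches)
}

# Backward pass for one image given dlogits (= probs - onehot for CE loss).
net_backward <- function(net, fwd, dlogits) {
  grads <- list()
  grads$fc <- list(W = outer(fwd$gap, dlogits),
                   b = dlogits)
  dv <- as.numeric(net$params$fc$W %*% dlogits)
  gd <- fwd$gap_dim
  dx <- array(rep(dv, each = gd[1] * gd[2]) / (gd[1] * gd[2]), dim = gd)
  for (s in 4:1) for (b in rev(seq_along(net$arch$stages[[s]]))) {
    blk <- net$arch$stages[[s]][[b]]
    key <- sprintf("s%db%d", s, b)
    r <- residual_block_backward(dx, blk, net$params,
                                 fwd$caches$blocks[[key]], grads)
    grads <- r$grads
    dx <- r$dx
  }
  pool <- fwd$caches$pool
  din <- maxpool_bwd_cpp(as.numeric(dx), pool$argmax,
                         prod(fwd$caches$pool_in_dim))
  dim(din) <- fwd$caches$pool_in_dim
  din <- din * fwd$caches$stem_mask
  bs <- conv_backward(din, net$arch$stem, net$params, fwd$caches$stem)
  grads$stem <- acc_grad(grads$stem, bs$grads)
  grads
}

#' Predict class probabilities for a feature image
#'
#' @param net a \code{resnet_classifier}.
#' @param image a \code{feature_image} or a numeric matrix matching the
#'   network's input shape.
#' @return Named probability vector (negative, neutral, positive).
#' @export
predict_classifier <- function(net, image) {
  stopifnot(inherits(net, "resnet_classifier"))
  if (inherits(image, "feature_image")) image <- image$values
  p <- net_forward(net, image)
  stats::setNames(p, class_names())
}

classifier_accuracy <- function(net, images, labels) {
  pred <- vapply(images, function(im) {
    im <- if (inherits(im, "feature_image")) im$values else im
    which.max(net_forward(net, im))
  }, integer(1))
  mean(pred == label_to_class(labels))
}

#' Train a residual classifier
#'
#' Mini-batch Adam training with categorical cross-entropy. After each
#' epoch the held-out accuracy is measured on \code{test_set}; the weights
#' of the earliest epoch attaining the maximum accuracy are retained as the
#' selected model (best-round selection). The run is reproducible from
#' \code{config$seed}: it controls the per-epoch shuffles, and network
#' initialization is already pinned by \code{build_network}'s seed.
#'
#' @param net a \code{resnet_classifier}.
#' @param train_set,test_set lists with fields \code{images} (list of
#'   \code{feature_image}s or matrices) and \code{labels} (in \{-1, 0, +1\}).
#' @param config a \code{training_config}.
#' @param checkpoint_dir optional directory; per-epoch checkpoints (params +
#'   config + seed) are written there as versioned RDS containers.
#' @param verbose print per-epoch progress.
#' @return List with \code{records} (data.frame epoch / train_loss /
#'   test_accuracy), \code{best} (list(epoch, params)), \code{final_params},
#'   and the trained \code{net} carrying the selected best parameters.
#' @export
train_classifier <- function(net, train_set, test_set,
                             config = training_config(),
                             checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "resnet_classifier"),
            inherits(config, "training_config"))
  imgs <- lapply(train_set$images, function(im)
    if (inherits(im, "feature_image")) im$values else im)
  test_imgs <- lapply(test_set$images, function(im)
    if (inherits(im, "feature_image")) im$values else im)
  n <- length(imgs)
  if (n == 0L || length(test_imgs) == 0L) {
    stop("train and test sets must both be non-empty")
  }
  if (length(train_set$labels) != n) stop("one label per training image required")
  y <- one_hot(train_set$labels, net$config$n_classes)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  adam <- list(m = list(), v = list(), t = 0L)
  records <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        test_accuracy = numeric(0))
  best <- list(epoch = NA_integer_, accuracy = -Inf, params = NULL)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    n_batches <- ceiling(n / config$batch_size)
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
      gsum <- list()
      bloss <- 0
      for (i in idx) {
        fwd <- net_forward(net, imgs[[i]], want_cache = TRUE)
        bloss <- bloss + categorical_crossentropy(y[i, ], fwd$probs)
        g <- net_backward(net, fwd, fwd$probs - y[i, ])
        for (id in names(g)) gsum[[id]] <- acc_grad(gsum[[id]], g[[id]])
      }
      k <- length(idx)
      for (id in names(gsum)) {
        gsum[[id]]$W <- gsum[[id]]$W / k
        gsum[[id]]$b <- gsum[[id]]$b / k
      }
      adam <- adam_step(net, gsum, adam, config)
      net <- adam$net
      epoch_loss <- epoch_loss + bloss
    }
    acc <- classifier_accuracy(net, test_imgs, test_set$labels)
    records <- rbind(records, data.frame(
      epoch = epoch, train_loss = epoch_loss / n, test_accuracy = acc))
    if (acc > best$accuracy) {   # strict: ties keep the earlier epoch
      best <- list(epoch = epoch, accuracy = acc, params = net$params)
    }
    if (!is.null(checkpoint_dir)) {
      write_checkpoint(file.path(checkpoint_dir,
                                 sprintf("epoch_%03d.rds", epoch)),
                       net, config, epoch, acc)
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  test accuracy %.4f",
                      epoch, epoch_loss / n, acc))
    }
  }
  best_net <- net
  best_net$params <- best$params
  list(records = records,
       best = list(epoch = best$epoch, accuracy = best$accuracy,
                   params = best$params),
       final_params = net$params,
       net = best_net)
}

adam_step <- function(net, grads, state, config) {
  state$t <- state$t + 1L
  t <- state$t
  for (id in names(grads)) {
    for (slot in c("W", "b")) {
      g <- grads[[id]][[slot]]
      key <- paste0(id, ".", slot)
      m <- if (is.null(state$m[[key]])) g * 0 else state$m[[key]]
      v <- if (is.null(state$v[[key]])) g * 0 else state$v[[key]]
      m <- config$beta1 * m + (1 - config$beta1) * g
      v <- config$beta2 * v + (1 - config$beta2) * g^2
      mh <- m / (1 - config$beta1^t)
      vh <- v / (1 - config$beta2^t)
      net$params[[id]][[slot]] <- net$params[[id]][[slot]] -
        config$learning_rate * mh / (sqrt(vh) + config$epsilon)
      state$m[[key]] <- m
      state$v[[key]] <- v
    }
  }
  state$net <- net
  state
}
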