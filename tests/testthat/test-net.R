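# small deterministic fixtures for the loss and fusion algebra
fixture_soft <- function(p, mask) soft_label_map(p, mask)

test_that("dice+focal loss: perfect prediction, hand-computed uniform case", {
  mask <- array(TRUE, c(2, 2, 2))
  lab <- array(c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L), c(2, 2, 2))
  onehot <- matrix(0, 8, 3); onehot[cbind(1:8, lab[mask])] <- 1

  perfect <- fixture_soft(onehot, mask)
  expect_lt(dice_focal_loss(perfect, lab), 1e-6)

  uniform <- fixture_soft(matrix(1 / 3, 8, 3), mask)
  # independent closed-form evaluation of soft Dice + focal
  eps <- 1e-7
  dice_k <- sapply(1:3, function(k) {
    (2 * sum(rep(1 / 3, 8) * onehot[, k]) + eps) /
      (8 / 3 + sum(onehot[, k]) + eps)
  })
  want <- mean(1 - dice_k) + mean(-(1 - 1 / 3)^2 * log(1 / 3))
  expect_equal(dice_focal_loss(uniform, lab), want, tolerance = 1e-12)

  # permutation invariance of the voxel order
  set.seed(1)
  p <- matrix(runif(24), 8, 3); p <- p / rowSums(p)
  perm <- sample(8)
  lab2 <- array(lab[mask][perm], dim(mask))
  expect_equal(dice_focal_loss(fixture_soft(p, mask), lab),
               dice_focal_loss(fixture_soft(p[perm, ], mask), lab2))

  expect_error(dice_focal_loss(perfect, array(1L, c(3, 3, 3))),
               "shape mismatch")
})

test_that("fusion algebra: uniform identity, worked product, absorbing one-hot", {
  mask <- array(TRUE, c(1, 1, 1))
  Y <- fixture_soft(matrix(c(0.5, 0.3, 0.2), 1), mask)
  X <- fixture_soft(matrix(c(0.6, 0.3, 0.1), 1), mask)
  fused <- fuse_probability_maps(Y, X)
  expect_equal(as.vector(pancseg:::soft_as_matrix(fused)),
               c(0.30, 0.09, 0.02) / 0.41, tolerance = 1e-10)

  U <- fixture_soft(matrix(1 / 3, 1, 3), mask)
  expect_equal(pancseg:::soft_as_matrix(fuse_probability_maps(Y, U)),
               pancseg:::soft_as_matrix(Y), tolerance = 1e-12)

  hot <- fixture_soft(matrix(c(0, 1, 0), 1), mask)
  expect_equal(pancseg:::soft_as_matrix(fuse_probability_maps(hot, Y)),
               matrix(c(0, 1, 0), 1), tolerance = 1e-12)

  # commutativity and channel sum = 1
  set.seed(2)
  m2 <- array(TRUE, c(4, 3, 2))
  a <- matrix(runif(72), 24, 3); a <- a / rowSums(a)
  b <- matrix(runif(72), 24, 3); b <- b / rowSums(b)
  A <- fixture_soft(a, m2); B <- fixture_soft(b, m2)
  expect_equal(pancseg:::soft_as_matrix(fuse_probability_maps(A, B)),
               pancseg:::soft_as_matrix(fuse_probability_maps(B, A)))
  expect_equal(rowSums(pancseg:::soft_as_matrix(fuse_probability_maps(A, B))),
               rep(1, 24), tolerance = 1e-6)

  # all-zero product falls back to uniform
  z1 <- fixture_soft(matrix(c(1, 0, 0), 1), mask)
  z2 <- fixture_soft(matrix(c(0, 1, 0), 1), mask)
  expect_equal(as.vector(pancseg:::soft_as_matrix(fuse_probability_maps(z1, z2))),
               rep(1 / 3, 3))
})

test_that("analytic gradients match finite differences through the net", {
  set.seed(7)
  d <- c(8, 8, 8)
  mask <- array(FALSE, d); mask[3:6, 3:6, 3:6] <- TRUE
  vol <- pancreas_volume(array(runif(prod(d)), d) * mask, mask)
  labels <- array(0L, d); labels[mask] <- sample(1:3, sum(mask), TRUE)
  Xp <- matrix(runif(sum(mask) * 3), ncol = 3)
  X <- soft_label_map(Xp / rowSums(Xp), mask)
  cfg <- net_config(depth = 1, base_channels = 2, seed = 5)
  params <- pancseg:::adam_init(pancseg:::net_init_params(cfg))
  # non-zero biases keep pre-activations away from the ReLU kink at 0
  params <- pancseg:::walk_params(params, function(p, nm) {
    p$b <- rnorm(length(p$b), 0, 0.05); p
  })
  onehot <- matrix(0, sum(mask), 3)
  onehot[cbind(seq_len(sum(mask)), labels[mask])] <- 1
  px <- pancseg:::soft_as_matrix(X)
  lossfun <- function(p) {
    fwd <- pancseg:::case_forward(p, vol, X, cfg)
    pancseg:::fused_loss_grad(fwd$py, px, onehot, cfg)$loss
  }
  fwd <- pancseg:::case_forward(params, vol, X, cfg)
  fl <- pancseg:::fused_loss_grad(fwd$py, px, onehot, cfg)
  gz <- fwd$py * (fl$gY - rowSums(fl$gY * fwd$py))
  g <- pancseg:::case_backward(params, fwd, vol, gz, cfg)

  eps <- 1e-6
  relerr <- function(getset, ganal) {
    W <- getset$get(params)
    ii <- sample(length(W), min(6, length(W)))
    max(sapply(ii, function(i) {
      p2 <- getset$set(params, `[<-`(W, i, W[i] + eps))
      p3 <- getset$set(params, `[<-`(W, i, W[i] - eps))
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      abs(num - ganal[i]) / max(abs(num), abs(ganal[i]), 1e-7)
    }))
  }
  spots <- list(
    list(get = function(p) p$enc[[1]]$W,
         set = function(p, W) { p$enc[[1]]$W <- W; p }, g = g$enc[[1]]$W),
    list(get = function(p) p$bott$W,
         set = function(p, W) { p$bott$W <- W; p }, g = g$bott$W),
    list(get = function(p) p$dec[[1]]$W,
         set = function(p, W) { p$dec[[1]]$W <- W; p }, g = g$dec[[1]]$W),
    list(get = function(p) p$out$W,
         set = function(p, W) { p$out$W <- W; p }, g = g$out$W),
    list(get = function(p) p$enc[[1]]$b,
         set = function(p, b) { p$enc[[1]]$b <- b; p }, g = g$enc[[1]]$b))
  for (s in spots)
    expect_lt(relerr(list(get = s$get, set = s$set), s$g), 1e-4)
})

# tiny training set shared by the training-behaviour tests
tiny_net_data <- function(n = 3, seed = 77) {
  ds <- generate_phantom_dataset(n, phantom_spec(shape = c(16, 16, 16),
                                                 preset = "straight",
                                                 radius_head = 3,
                                                 radius_tail = 2),
                                 seed = seed)
  lapply(ds$cases, function(cs) {
    pre <- preprocess_volume(cs$volume, cs$labels, padding = 1)
    f <- subregion_features(pre$volume, pre$labels)
    fit <- fit_subregion_bayes(f, pre$labels)
    list(volume = pre$volume, labels = pre$labels, X = predict(fit, f))
  })
}

test_that("training reduces the loss and is seed-reproducible", {
  data <- tiny_net_data()
  cfg <- net_config(depth = 1, base_channels = 2, epochs = 6, seed = 9,
                    lr = 1e-3)
  net1 <- fit_segmentation_net(data, cfg)
  expect_lt(net1$log$loss[nrow(net1$log)], net1$log$loss[1])
  net2 <- fit_segmentation_net(data, cfg)
  # identical up to BLAS reduction order (bit-identical single-threaded)
  expect_equal(net1$log, net2$log, tolerance = 1e-10)
  expect_equal(net1$params$out$W, net2$params$out$W, tolerance = 1e-10)
})

test_that("uniform-X fusion training equals the plain-network path bit-for-bit", {
  data <- tiny_net_data()
  uni <- lapply(data, function(cs) {
    cs$X <- soft_label_map(matrix(1 / 3, sum(cs$volume$mask), 3),
                           cs$volume$mask)
    cs
  })
  cfg_fuse <- net_config(depth = 1, base_channels = 2, epochs = 3, seed = 4,
                         input_bayes = FALSE, fusion = TRUE)
  cfg_plain <- net_config(depth = 1, base_channels = 2, epochs = 3, seed = 4,
                          input_bayes = FALSE, fusion = FALSE)
  nf <- fit_segmentation_net(uni, cfg_fuse)
  np <- fit_segmentation_net(uni, cfg_plain)
  expect_equal(nf$log$loss, np$log$loss, tolerance = 1e-10)
  expect_equal(nf$params$out$W, np$params$out$W, tolerance = 1e-10)
})

test_that("prediction respects the mask and one-hot X dominates fusion", {
  data <- tiny_net_data(2)
  cfg <- net_config(depth = 1, base_channels = 2, epochs = 2, seed = 3)
  net <- fit_segmentation_net(data, cfg)
  pr <- predict(net, data[[1]]$volume, data[[1]]$X)
  expect_true(all(pr$labels[!data[[1]]$volume$mask] == 0))
  expect_true(all(pr$labels[data[[1]]$volume$mask] > 0))
  # deterministic prediction with frozen weights (up to BLAS reduction order)
  pr2 <- predict(net, data[[1]]$volume, data[[1]]$X)
  expect_equal(pr$prob$probs, pr2$prob$probs, tolerance = 1e-12)

  # one-hot X forces the fused argmax regardless of Y (Y > 0 via softmax)
  mask <- data[[1]]$volume$mask
  hard <- data[[1]]$labels[mask]
  hot <- matrix(0, length(hard), 3); hot[cbind(seq_along(hard), hard)] <- 1
  prh <- predict(net, data[[1]]$volume, soft_label_map(hot, mask))
  expect_identical(prh$labels[mask], hard)
})

test_that("network weights JSON round-trips and restores predictions", {
  data <- tiny_net_data(2)
  cfg <- net_config(depth = 1, base_channels = 2, epochs = 2, seed = 13)
  net <- fit_segmentation_net(data, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_pancseg_net(net, path)
  back <- read_pancseg_net(path)
  p1 <- predict(net, data[[1]]$volume, data[[1]]$X)
  p2 <- predict(back, data[[1]]$volume, data[[1]]$X)
  expect_equal(p1$prob$probs, p2$prob$probs, tolerance = 1e-12)
})
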