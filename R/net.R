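# Compact 3D encoder-decoder segmentation network.
#
# A small U-style network (3x3x3 convolutions + ReLU, 2x average-pool
# down-sampling, nearest-neighbour up-sampling with skip concatenation,
# 1x1x1 output head) producing a 3-class probability map Y over the
# cropped pancreas volume. Training minimizes soft Dice + focal loss
# (1:1) on the fused map Yhat = normalize(Y * X), where X is the Bayes
# anatomical soft label, with Adam. Forward, backward and the optimizer
# are implemented directly on R arrays: convolutions are shift-based
# im2col + BLAS matrix products, which keeps desk-scale volumes (32^3)
# fast without external deep-learning dependencies.

# 27 kernel offsets (includes the centre tap)
KERNEL_OFFSETS <- as.matrix(expand.grid(ox = -1:1, oy = -1:1, oz = -1:1))

# zero-padded gather shift: out[v] = a[v + o]
shift3 <- function(a, o) {
  d <- dim(a)
  out <- array(0, d)
  lo <- pmax(1, 1 - o)
  hi <- pmin(d, d - o)
  if (any(hi < lo)) return(out)  # shift exceeds a (possibly singleton) axis
  vx <- lo[1]:hi[1]; vy <- lo[2]:hi[2]; vz <- lo[3]:hi[3]
  out[vx, vy, vz] <- a[vx + o[1], vy + o[2], vz + o[3]]
  out
}

conv3_fw <- function(x4, W, b) {
  d <- dim(x4); sp <- d[1:3]; Cin <- d[4]; N <- prod(sp)
  cols <- matrix(0, N, 27L * Cin)
  k <- 0L
  for (c in seq_len(Cin)) {
    xc <- x4[, , , c]
    for (o in 1:27) {
      k <- k + 1L
      cols[, k] <- shift3(xc, KERNEL_OFFSETS[o, ])
    }
  }
  out <- cols %*% W
  out <- sweep(out, 2, b, "+")
  list(out = array(out, c(sp, ncol(W))), cols = cols, sp = sp, Cin = Cin)
}

conv3_bw <- function(cache, W, dout4) {
  sp <- cache$sp; N <- prod(sp); Cout <- ncol(W)
  dout <- matrix(dout4, N, Cout)
  dW <- crossprod(cache$cols, dout)
  db <- colSums(dout)
  dcols <- tcrossprod(dout, W)
  dx <- array(0, c(sp, cache$Cin))
  k <- 0L
  for (c in seq_len(cache$Cin)) {
    acc <- array(0, sp)
    for (o in 1:27) {
      k <- k + 1L
      acc <- acc + shift3(array(dcols[, k], sp), -KERNEL_OFFSETS[o, ])
    }
    dx[, , , c] <- acc
  }
  list(dx = dx, dW = dW, db = db)
}

conv1_fw <- function(x4, W, b) {
  d <- dim(x4); N <- prod(d[1:3])
  out <- matrix(x4, N, d[4]) %*% W
  out <- sweep(out, 2, b, "+")
  list(out = array(out, c(d[1:3], ncol(W))), x = x4)
}

conv1_bw <- function(cache, W, dout4) {
  d <- dim(cache$x); N <- prod(d[1:3])
  dout <- matrix(dout4, N, ncol(W))
  list(dx = array(tcrossprod(dout, W), d),
       dW = crossprod(matrix(cache$x, N, d[4]), dout),
       db = colSums(dout))
}

pool_avg_fw <- function(x4) {
  d <- dim(x4)
  ix <- seq(1, d[1], 2); iy <- seq(1, d[2], 2); iz <- seq(1, d[3], 2)
  out <- (x4[ix, iy, iz, , drop = FALSE] + x4[ix + 1, iy, iz, , drop = FALSE] +
          x4[ix, iy + 1, iz, , drop = FALSE] + x4[ix + 1, iy + 1, iz, , drop = FALSE] +
          x4[ix, iy, iz + 1, , drop = FALSE] + x4[ix + 1, iy, iz + 1, , drop = FALSE] +
          x4[ix, iy + 1, iz + 1, , drop = FALSE] + x4[ix + 1, iy + 1, iz + 1, , drop = FALSE]) / 8
  out
}

up2_fw <- function(x4) {
  d <- dim(x4)
  x4[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
     rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

# adjoint of up2_fw (sum over the 8 children); also used as avg-pool
# backward after dividing by 8
pool_sum <- function(x4) {
  d <- dim(x4)
  ix <- seq(1, d[1], 2); iy <- seq(1, d[2], 2); iz <- seq(1, d[3], 2)
  x4[ix, iy, iz, , drop = FALSE] + x4[ix + 1, iy, iz, , drop = FALSE] +
    x4[ix, iy + 1, iz, , drop = FALSE] + x4[ix + 1, iy + 1, iz, , drop = FALSE] +
    x4[ix, iy, iz + 1, , drop = FALSE] + x4[ix + 1, iy, iz + 1, , drop = FALSE] +
    x4[ix, iy + 1, iz + 1, , drop = FALSE] + x4[ix + 1, iy + 1, iz + 1, , drop = FALSE]
}

ccat4 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1:3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

#' Configuration of the segmentation network
#'
#' @param depth number of down-/up-sampling steps (default 3; the desk
#'   preset uses 2).
#' @param base_channels feature channels at the first level; doubled per
#'   level.
#' @param input_bayes feed the 3 Bayes soft-label channels alongside the
#'   intensity channel as network input (4 input channels); `FALSE` gives
#'   a 1-channel (intensity only) network.
#' @param fusion multiply the network probability map with the Bayes map
#'   and renormalize, in every training epoch and at prediction
#'   (`FALSE` = plain-network ablation path).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size mini-batch size (default 2).
#' @param epochs maximum training epochs (default 500).
#' @param gamma focal-loss focusing exponent (default 2).
#' @param dice_weight,focal_weight loss mixing weights (default 1:1).
#' @param seed RNG seed for weight init and epoch shuffling.
#' @param preset `"full"` leaves the above defaults; `"desk"` switches to
#'   a small configuration (depth 2, 4 base channels, 15 epochs) sized for
#'   32^3 phantoms on one CPU.
#' @return An object of class `net_config`.
#' @export
net_config <- function(depth = 3, base_channels = 8, input_bayes = TRUE,
                       fusion = TRUE, lr = 1e-4, batch_size = 2,
                       epochs = 500, gamma = 2, dice_weight = 1,
                       focal_weight = 1, seed = 1L,
                       preset = c("full", "desk")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    if (missing(depth)) depth <- 2
    if (missing(base_channels)) base_channels <- 4
    if (missing(epochs)) epochs <- 15
  }
  if (depth < 1) stop("depth must be >= 1")
  if (dice_weight <= 0 || focal_weight <= 0) stop("loss weights must be > 0")
  structure(list(depth = depth, base_channels = base_channels,
                 input_bayes = input_bayes, fusion = fusion, lr = lr,
                 batch_size = batch_size, epochs = epochs, gamma = gamma,
                 dice_weight = dice_weight, focal_weight = focal_weight,
                 seed = as.integer(seed), classes = 3L, preset = preset),
            class = "net_config")
}

net_init_params <- function(cfg) {
  Cin <- if (cfg$input_bayes) 4L else 1L
  nch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  he <- function(nin, nout, taps) {
    matrix(rnorm(taps * nin * nout, 0, sqrt(2 / (taps * nin))),
           taps * nin, nout)
  }
  params <- list(enc = list(), dec = list())
  cprev <- Cin
  for (l in seq_len(cfg$depth)) {
    params$enc[[l]] <- list(W = he(cprev, nch[l], 27), b = rep(0, nch[l]))
    cprev <- nch[l]
  }
  nb <- cfg$base_channels * 2^cfg$depth
  params$bott <- list(W = he(cprev, nb, 27), b = rep(0, nb))
  cprev <- nb
  for (l in rev(seq_len(cfg$depth))) {
    params$dec[[l]] <- list(W = he(cprev + nch[l], nch[l], 27),
                            b = rep(0, nch[l]))
    cprev <- nch[l]
  }
  params$out <- list(W = he(cprev, cfg$classes, 1), b = rep(0, cfg$classes))
  params
}

net_forward <- function(params, x4, cfg) {
  caches <- list(enc = list(), dec = list())
  h <- x4
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    cv <- conv3_fw(h, params$enc[[l]]$W, params$enc[[l]]$b)
    rm_ <- cv$out > 0
    a <- cv$out * rm_
    skips[[l]] <- a
    caches$enc[[l]] <- list(conv = cv, relu = rm_)
    h <- pool_avg_fw(a)
  }
  cv <- conv3_fw(h, params$bott$W, params$bott$b)
  rm_ <- cv$out > 0
  caches$bott <- list(conv = cv, relu = rm_)
  h <- cv$out * rm_
  for (l in rev(seq_len(cfg$depth))) {
    u <- up2_fw(h)
    cat_ <- ccat4(u, skips[[l]])
    cv <- conv3_fw(cat_, params$dec[[l]]$W, params$dec[[l]]$b)
    rm_ <- cv$out > 0
    caches$dec[[l]] <- list(conv = cv, relu = rm_, c_up = dim(u)[4])
    h <- cv$out * rm_
  }
  cv <- conv1_fw(h, params$out$W, params$out$b)
  caches$out <- cv
  list(logits = cv$out, caches = caches)
}

net_backward <- function(params, caches, dlogits, cfg) {
  grads <- list(enc = vector("list", cfg$depth),
                dec = vector("list", cfg$depth))
  bw <- conv1_bw(caches$out, params$out$W, dlogits)
  grads$out <- list(W = bw$dW, b = bw$db)
  dh <- bw$dx
  for (l in seq_len(cfg$depth)) {   # decoder: full-resolution level first
    cc <- caches$dec[[l]]
    dh <- dh * cc$relu
    bw <- conv3_bw(cc$conv, params$dec[[l]]$W, dh)
    grads$dec[[l]] <- list(W = bw$dW, b = bw$db)
    cu <- cc$c_up
    # split the concat gradient: up-sampled path vs the skip connection
    caches$enc[[l]]$dskip <-
      bw$dx[, , , cu + seq_len(dim(bw$dx)[4] - cu), drop = FALSE]
    dh <- pool_sum(bw$dx[, , , seq_len(cu), drop = FALSE])
  }
  # bottleneck
  dh <- dh * caches$bott$relu
  bw <- conv3_bw(caches$bott$conv, params$bott$W, dh)
  grads$bott <- list(W = bw$dW, b = bw$db)
  dh <- bw$dx
  for (l in rev(seq_len(cfg$depth))) {  # encoder, deepest first
    # gradient reaching this level's activation: from the pool below
    # (dh, via avg-pool backward) plus the skip connection
    da <- up2_fw(dh) / 8 + caches$enc[[l]]$dskip
    da <- da * caches$enc[[l]]$relu
    bw <- conv3_bw(caches$enc[[l]]$conv, params$enc[[l]]$W, da)
    grads$enc[[l]] <- list(W = bw$dW, b = bw$db)
    dh <- bw$dx
  }
  grads
}

# flatten/apply over the nested parameter list
walk_params <- function(params, f) {
  for (l in seq_along(params$enc)) params$enc[[l]] <- f(params$enc[[l]], paste0("enc", l))
  params$bott <- f(params$bott, "bott")
  for (l in seq_along(params$dec)) params$dec[[l]] <- f(params$dec[[l]], paste0("dec", l))
  params$out <- f(params$out, "out")
  params
}

adam_init <- function(params) {
  walk_params(params, function(p, nm)
    list(W = p$W, b = p$b,
         mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  upd <- function(p, g) {
    p$mW <- beta1 * p$mW + (1 - beta1) * g$W
    p$vW <- beta2 * p$vW + (1 - beta2) * g$W^2
    p$mb <- beta1 * p$mb + (1 - beta1) * g$b
    p$vb <- beta2 * p$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    p$W <- p$W - lr * (p$mW / c1) / (sqrt(p$vW / c2) + eps)
    p$b <- p$b - lr * (p$mb / c1) / (sqrt(p$vb / c2) + eps)
    p
  }
  state$enc <- Map(upd, state$enc, grads$enc)
  state$bott <- upd(state$bott, grads$bott)
  state$dec <- Map(upd, state$dec, grads$dec)
  state$out <- upd(state$out, grads$out)
  state
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  add1 <- function(x, y) list(W = x$W + y$W, b = x$b + y$b)
  list(enc = Map(add1, a$enc, b$enc), bott = add1(a$bott, b$bott),
       dec = Map(add1, a$dec, b$dec), out = add1(a$out, b$out))
}

grads_scale <- function(g, s) {
  sc1 <- function(x) list(W = x$W * s, b = x$b * s)
  list(enc = lapply(g$enc, sc1), bott = sc1(g$bott),
       dec = lapply(g$dec, sc1), out = sc1(g$out))
}

# ---- loss -----------------------------------------------------------------

# soft Dice + focal loss and its gradient w.r.t. the predicted
# probabilities p (mask voxels x 3); t is the matching one-hot matrix
dice_focal_core <- function(p, t, gamma = 2, dice_weight = 1,
                            focal_weight = 1, eps = 1e-7) {
  n <- nrow(p)
  num <- 2 * colSums(p * t) + eps
  den <- colSums(p) + colSums(t) + eps
  l_dice <- mean(1 - num / den)
  g_dice <- -(sweep(2 * t, 2, den, "/") -
              sweep(matrix(1, n, 3), 2, num / den^2, "*")) / 3

  pt <- pmax(rowSums(p * t), 1e-12)
  l_focal <- mean(-(1 - pt)^gamma * log(pt))
  dpt <- (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt) / n
  g_focal <- t * dpt

  list(loss = dice_weight * l_dice + focal_weight * l_focal,
       grad = dice_weight * g_dice + focal_weight * g_focal)
}

#' Combined soft-Dice and focal loss
#'
#' Mean over the three subregion classes of (1 - soft Dice) plus the focal
#' loss (focusing exponent `gamma`), mixed at `dice_weight:focal_weight`
#' (default 1:1). Evaluated over pancreas voxels only.
#'
#' @param pred a `soft_label_map` (normalized per voxel).
#' @param target integer label array (1 head, 2 body, 3 tail on the mask).
#' @param gamma focal focusing exponent.
#' @param dice_weight,focal_weight loss mixing weights.
#' @return Scalar loss (>= 0).
#' @export
dice_focal_loss <- function(pred, target, gamma = 2, dice_weight = 1,
                            focal_weight = 1) {
  if (!identical(dim(target), dim(pred$mask)))
    stop("shape mismatch between prediction and target")
  p <- soft_as_matrix(pred)
  lab <- target[pred$mask]
  t <- matrix(0, length(lab), 3)
  t[cbind(seq_along(lab), lab)] <- 1
  dice_focal_core(p, t, gamma, dice_weight, focal_weight)$loss
}

#' Fuse two probability maps by voxel-wise product
#'
#' The joint map of the network probabilities Y and the Bayes soft labels
#' X: per voxel and class, `Yhat proportional to Y * X`, renormalized so
#' the three class probabilities sum to exactly 1. Voxels where all three
#' products vanish fall back to the uniform distribution (1/3 each).
#'
#' @param Y,X `soft_label_map`s on the same mask.
#' @return The fused `soft_label_map`.
#' @export
fuse_probability_maps <- function(Y, X) {
  if (!identical(dim(Y$mask), dim(X$mask)) || !identical(Y$mask, X$mask))
    stop("probability maps must share shape and mask")
  py <- soft_as_matrix(Y); px <- soft_as_matrix(X)
  s <- py * px
  rs <- rowSums(s)
  zero <- rs <= 0
  s[zero, ] <- 1 / 3
  rs[zero] <- 1
  soft_label_map(s / rs, Y$mask)
}

# fusion + loss with gradient w.r.t. the network probabilities py
fused_loss_grad <- function(py, px, t, cfg) {
  if (is.null(px)) {
    out <- dice_focal_core(py, t, cfg$gamma, cfg$dice_weight, cfg$focal_weight)
    return(list(loss = out$loss, gY = out$grad, yhat = py))
  }
  s <- py * px
  rs <- rowSums(s)
  zero <- rs <= 0
  yhat <- s / ifelse(zero, 1, rs)
  yhat[zero, ] <- 1 / 3
  out <- dice_focal_core(yhat, t, cfg$gamma, cfg$dice_weight, cfg$focal_weight)
  g <- out$grad
  inner <- rowSums(g * yhat)
  gY <- (px / ifelse(zero, 1, rs)) * (g - inner)
  gY[zero, ] <- 0
  list(loss = out$loss, gY = gY, yhat = yhat)
}

# softmax over mask voxels of a logits array; returns mask-voxels x 3
softmax_mask <- function(logits, mask) {
  z <- matrix(vapply(1:3, function(s) logits[, , , s][mask],
                     numeric(sum(mask))), ncol = 3)
  z <- z - pmax(z[, 1], z[, 2], z[, 3])
  e <- exp(z)
  e / rowSums(e)
}

pad_to_multiple <- function(x4, m) {
  d <- dim(x4)
  target <- ceiling(d[1:3] / m) * m
  if (all(target == d[1:3])) return(list(x = x4, orig = d[1:3]))
  out <- array(0, c(target, d[4]))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x4
  list(x = out, orig = d[1:3])
}

# build the network input tensor for one case
net_input <- function(vol, X, cfg) {
  d <- dim(vol$mask)
  Cin <- if (cfg$input_bayes) 4L else 1L
  x <- array(0, c(d, Cin))
  x[, , , 1] <- vol$intensities
  if (cfg$input_bayes) {
    if (is.null(X)) stop("input_bayes = TRUE requires a Bayes soft-label map")
    x[, , , 2:4] <- X$probs
  }
  x
}

# forward one case through the net; returns the per-voxel network
# probabilities (mask voxels x 3) plus caches for backprop
case_forward <- function(params, vol, X, cfg) {
  x <- net_input(vol, X, cfg)
  pp <- pad_to_multiple(x, 2^cfg$depth)
  fw <- net_forward(params, pp$x, cfg)
  o <- pp$orig
  logits <- fw$logits[seq_len(o[1]), seq_len(o[2]), seq_len(o[3]), ,
                      drop = FALSE]
  py <- softmax_mask(logits, vol$mask)
  list(py = py, fw = fw, pad_dim = dim(pp$x)[1:3], orig = o)
}

# scatter the loss gradient (w.r.t. logits) back into the padded grid and
# run the network backward pass
case_backward <- function(params, fwd, vol, gz, cfg) {
  dlog <- array(0, c(fwd$pad_dim, 3))
  for (s in 1:3) {
    ch <- array(0, fwd$orig)
    ch[vol$mask] <- gz[, s]
    dlog[seq_len(fwd$orig[1]), seq_len(fwd$orig[2]), seq_len(fwd$orig[3]), s] <- ch
  }
  net_backward(params, fwd$fw$caches, dlog, cfg)
}

#' Train the segmentation network
#'
#' Per epoch and case: forward pass to the network probability map Y,
#' voxel-wise fusion with the case's Bayes soft label X (when
#' `config$fusion`), Dice+focal loss on the fused map, backprop, Adam
#' update per mini-batch. The checkpoint with the best mean training Dice
#' is kept. Fully deterministic given `config$seed`.
#'
#' @param dataset list of cases; each case is a list with `volume`
#'   (preprocessed [pancreas_volume]), `labels` (integer array) and `X`
#'   (the case's Bayes `soft_label_map`, may be `NULL` when neither
#'   `input_bayes` nor `fusion` is used).
#' @param config a [net_config()].
#' @param verbose print the per-epoch loss.
#' @return An object of class `pancseg_net`: fitted weights (best
#'   checkpoint), the config, and `log` (per-epoch loss and per-class
#'   training Dice).
#' @export
fit_segmentation_net <- function(dataset, config = net_config(),
                                 verbose = FALSE) {
  if (length(dataset) < 2) stop("need at least 2 training cases")
  set.seed(config$seed)
  state <- adam_init(net_init_params(config))
  n <- length(dataset)

  onehots <- lapply(dataset, function(cs) {
    lab <- cs$labels[cs$volume$mask]
    t <- matrix(0, length(lab), 3)
    t[cbind(seq_along(lab), lab)] <- 1
    t
  })
  pxs <- lapply(dataset, function(cs)
    if (config$fusion) soft_as_matrix(cs$X) else NULL)

  log_rows <- vector("list", config$epochs)
  best <- list(dsc = -Inf, params = NULL, epoch = 0L)
  tstep <- 0L

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    dsc_acc <- c(0, 0, 0)
    bstart <- seq(1, n, by = config$batch_size)
    for (bs in bstart) {
      ids <- ord[bs:min(bs + config$batch_size - 1, n)]
      gacc <- NULL
      for (i in ids) {
        cs <- dataset[[i]]
        fwd <- case_forward(state, cs$volume, cs$X, config)
        fl <- fused_loss_grad(fwd$py, pxs[[i]], onehots[[i]], config)
        if (!is.finite(fl$loss))
          stop(sprintf("non-finite loss at epoch %d (case %d)", ep, i))
        ep_loss <- ep_loss + fl$loss / n
        # training Dice of the hard fused prediction
        pred <- max.col(fl$yhat, ties.method = "first")
        ref <- max.col(onehots[[i]], ties.method = "first")
        for (k in 1:3) {
          tp <- sum(pred == k & ref == k)
          dsc_acc[k] <- dsc_acc[k] +
            (if (sum(pred == k) + sum(ref == k) == 0) 1
             else 2 * tp / (sum(pred == k) + sum(ref == k))) / n
        }
        # softmax backward: from dL/dY to dL/dlogits
        gz <- fwd$py * (fl$gY - rowSums(fl$gY * fwd$py))
        gcase <- case_backward(state, fwd, cs$volume, gz, config)
        gacc <- grads_add(gacc, gcase)
      }
      tstep <- tstep + 1L
      state <- adam_step(state, grads_scale(gacc, 1 / length(ids)),
                         config$lr, tstep)
    }
    mean_dsc <- mean(dsc_acc)
    log_rows[[ep]] <- data.frame(epoch = ep, loss = ep_loss,
                                 dsc_head = dsc_acc[1], dsc_body = dsc_acc[2],
                                 dsc_tail = dsc_acc[3], dsc_mean = mean_dsc)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  train DSC %.4f", ep, ep_loss,
                      mean_dsc))
    if (mean_dsc > best$dsc) {
      best <- list(dsc = mean_dsc, params = state, epoch = ep)
    }
  }
  structure(list(params = best$params, config = config,
                 log = do.call(rbind, log_rows), best_epoch = best$epoch),
            class = "pancseg_net")
}

#' @export
print.pancseg_net <- function(x, ...) {
  cat(sprintf("<pancseg_net> depth %d, %d base channels, %s input, fusion %s\n",
              x$config$depth, x$config$base_channels,
              if (x$config$input_bayes) "image+Bayes" else "image-only",
              if (x$config$fusion) "on" else "off"))
  cat(sprintf("  trained %d epochs, best training DSC %.4f at epoch %d\n",
              nrow(x$log), max(x$log$dsc_mean), x$best_epoch))
  invisible(x)
}

#' Predict subregion labels for one case
#'
#' Runs the network forward, fuses the probability map with the case's
#' Bayes soft label (when the model was configured with fusion) and takes
#' the per-voxel argmax restricted to the pancreas mask; background
#' stays 0.
#'
#' @param object a fitted `pancseg_net`.
#' @param volume preprocessed [pancreas_volume].
#' @param X the case's Bayes `soft_label_map` (required when the config
#'   uses it).
#' @param ... unused.
#' @return list with `prob` (the fused `soft_label_map`) and `labels`
#'   (integer array).
#' @export
predict.pancseg_net <- function(object, volume, X = NULL, ...) {
  cfg <- object$config
  fwd <- case_forward(object$params, volume, X, cfg)
  if (cfg$fusion) {
    if (is.null(X)) stop("fusion requires a Bayes soft-label map")
    px <- soft_as_matrix(X)
    s <- fwd$py * px
    rs <- rowSums(s)
    zero <- rs <= 0
    p <- s / ifelse(zero, 1, rs)
    p[zero, ] <- 1 / 3
  } else {
    p <- fwd$py
  }
  prob <- soft_label_map(p, volume$mask)
  list(prob = prob, labels = bayes_segment(prob))
}

#' Save / load a fitted network as JSON
#'
#' Weights, config and seed are embedded; the file is plain text.
#'
#' @param object a `pancseg_net`.
#' @param path JSON file.
#' @return Invisibly `path` (write) or the restored `pancseg_net` (read).
#' @export
write_pancseg_net <- function(object, path) {
  ser1 <- function(p) list(W = as.vector(p$W), dim = dim(p$W), b = p$b)
  jsonlite::write_json(list(
    schema = "pancseg.net.v1",
    config = unclass(object$config),
    best_epoch = object$best_epoch,
    log = object$log,
    enc = lapply(object$params$enc, ser1),
    bott = ser1(object$params$bott),
    dec = lapply(object$params$dec, ser1),
    out = ser1(object$params$out)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pancseg_net
#' @export
read_pancseg_net <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$schema, "pancseg.net.v1"))
    stop("unrecognized model file schema")
  de1 <- function(p) {
    d <- unlist(p$dim)
    list(W = matrix(unlist(p$W), d[1], d[2]), b = unlist(p$b),
         mW = 0, vW = 0, mb = 0, vb = 0)
  }
  cfg <- lapply(j$config, function(x) if (is.list(x)) unlist(x) else x)
  class(cfg) <- "net_config"
  log <- as.data.frame(lapply(
    setNames(nm = names(j$log[[1]])),
    function(cc) vapply(j$log, function(r) as.numeric(r[[cc]]), numeric(1))))
  params <- list(enc = lapply(j$enc, de1), bott = de1(j$bott),
                 dec = lapply(j$dec, de1), out = de1(j$out))
  structure(list(params = params, config = cfg, log = log,
                 best_epoch = j$best_epoch), class = "pancseg_net")
}
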