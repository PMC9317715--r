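# Naive Bayes soft labels for pancreatic subregions.
#
# Each subregion s in {head, body, tail} gets univariate Gaussian
# class-conditionals for the two anatomical features alpha' (length
# fraction) and beta' (swept-volume fraction), fit by pooled supervised
# estimation over all training cases. The per-voxel posterior
#   P(s | x) propto N(alpha'; mu_a[s], sd_a[s]) p_a(s)
#                  * N(beta'; mu_b[s], sd_b[s]) p_b(s)
# is renormalized over the three classes, giving a 3-channel soft-label
# map. Priors default to equal (one per feature, applied once each);
# constant priors cancel in the renormalization.

#' Fit per-subregion Gaussians of the anatomical features
#'
#' Pools voxels across the supplied training cases and estimates, for each
#' subregion, the mean and (unbiased) standard deviation of `alpha` and
#' `beta`. Standard deviations are floored at `sigma_floor` so degenerate
#' subregions cannot produce density spikes.
#'
#' @param features a `subregion_features` object or list of them
#'   (one per training case).
#' @param labels an integer label array or list of them, matching
#'   `features` case by case.
#' @param priors numeric(3) class priors, applied once per feature;
#'   default equal. Must be nonnegative; normalized to sum 1.
#' @param sigma_floor minimum standard deviation (dimensionless fraction
#'   scale, default 1e-3).
#' @return An object of class `subregion_bayes` holding the Gaussian
#'   parameters, priors and pooled sample counts.
#' @export
fit_subregion_bayes <- function(features, labels, priors = rep(1 / 3, 3),
                                sigma_floor = 1e-3) {
  if (inherits(features, "subregion_features")) features <- list(features)
  if (!is.list(labels) || is.array(labels)) labels <- list(labels)
  if (length(features) != length(labels))
    stop("features and labels must have one element per training case")
  if (length(features) < 1L) stop("need at least one training case")
  priors <- as.numeric(priors)
  if (length(priors) != 3L || any(priors < 0) || sum(priors) <= 0)
    stop("priors must be 3 nonnegative numbers")
  priors <- priors / sum(priors)

  pooled <- lapply(SUBREGIONS, function(s) {
    av <- unlist(lapply(seq_along(features), function(i) {
      features[[i]]$alpha[labels[[i]] == s]
    }))
    bv <- unlist(lapply(seq_along(features), function(i) {
      features[[i]]$beta[labels[[i]] == s]
    }))
    list(alpha = av[!is.na(av)], beta = bv[!is.na(bv)])
  })
  n <- vapply(pooled, function(p) length(p$alpha), numeric(1))
  if (any(n == 0))
    stop("subregion(s) absent from all training labels: ",
         paste(SUBREGION_NAMES[n == 0], collapse = ", "))
  if (any(n < 2))
    stop("every subregion needs at least 2 pooled voxels")

  msd <- function(v) c(mean(v), max(sd(v), sigma_floor))
  pa <- vapply(pooled, function(p) msd(p$alpha), numeric(2))
  pb <- vapply(pooled, function(p) msd(p$beta), numeric(2))

  obj <- structure(list(
    mu_alpha = setNames(pa[1, ], SUBREGION_NAMES),
    sigma_alpha = setNames(pa[2, ], SUBREGION_NAMES),
    mu_beta = setNames(pb[1, ], SUBREGION_NAMES),
    sigma_beta = setNames(pb[2, ], SUBREGION_NAMES),
    priors = setNames(priors, SUBREGION_NAMES),
    n_voxels = setNames(n, SUBREGION_NAMES),
    sigma_floor = sigma_floor), class = "subregion_bayes")

  if (is.unsorted(obj$mu_alpha, strictly = TRUE))
    warning("alpha means do not follow the head < body < tail anatomical order")
  obj
}

#' @export
print.subregion_bayes <- function(x, ...) {
  cat("<subregion_bayes> Gaussian class-conditionals (alpha', beta')\n")
  tab <- data.frame(mu_alpha = x$mu_alpha, sigma_alpha = x$sigma_alpha,
                    mu_beta = x$mu_beta, sigma_beta = x$sigma_beta,
                    prior = x$priors, n = x$n_voxels)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.subregion_bayes <- function(object, ...) print(object)

#' @export
coef.subregion_bayes <- function(object, ...) {
  cbind(mu_alpha = object$mu_alpha, sigma_alpha = object$sigma_alpha,
        mu_beta = object$mu_beta, sigma_beta = object$sigma_beta,
        prior = object$priors)
}

#' Plot the fitted class-conditional densities
#'
#' @param x a `subregion_bayes` model.
#' @param feature `"alpha"` or `"beta"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.subregion_bayes <- function(x, feature = c("alpha", "beta"), ...) {
  feature <- match.arg(feature)
  mu <- x[[paste0("mu_", feature)]]
  sg <- x[[paste0("sigma_", feature)]]
  t <- seq(0, 1, length.out = 400)
  dens <- sapply(1:3, function(s) dnorm(t, mu[s], sg[s]))
  plot(t, dens[, 1], type = "l", col = 2, xlab = sprintf("%s'", feature),
       ylab = "class-conditional density", ...)
  lines(t, dens[, 2], col = 4); lines(t, dens[, 3], col = 3)
  legend("top", legend = SUBREGION_NAMES, col = c(2, 4, 3), lty = 1, bty = "n")
  invisible(x)
}

# log N(x; mu, sigma)
log_dnorm <- function(x, mu, sigma) {
  -0.5 * log(2 * pi) - log(sigma) - 0.5 * ((x - mu) / sigma)^2
}

#' Posterior soft-label map from fitted Gaussians
#'
#' Evaluates, for every pancreas voxel, the three subregion posteriors
#' from the fitted class-conditionals and priors, renormalized to sum 1.
#' Computation is in log space with log-sum-exp normalization, so extreme
#' feature values cannot underflow.
#'
#' @param object a `subregion_bayes` model.
#' @param features a `subregion_features` object for the case to label.
#' @param ... unused.
#' @return An object of class `soft_label_map`: list with `probs` (4D
#'   array, last dimension the three subregion channels, 0 outside the
#'   mask) and `mask`.
#' @export
predict.subregion_bayes <- function(object, features, ...) {
  mask <- !is.na(features$alpha)
  av <- features$alpha[mask]
  bv <- features$beta[mask]
  logp <- vapply(1:3, function(s) {
    lp <- log_dnorm(av, object$mu_alpha[s], object$sigma_alpha[s]) +
          log_dnorm(bv, object$mu_beta[s], object$sigma_beta[s])
    if (object$priors[s] > 0) lp + 2 * log(object$priors[s]) else rep(-Inf, length(av))
  }, numeric(length(av)))
  logp <- matrix(logp, ncol = 3)
  m <- pmax(logp[, 1], logp[, 2], logp[, 3])
  p <- exp(logp - m)
  p <- p / rowSums(p)
  soft_label_map(p, mask)
}

#' Construct a soft-label map
#'
#' @param p matrix (mask voxels x 3) of class probabilities, or a 4D array.
#' @param mask 3D logical array; probabilities are 0 outside it.
#' @return An object of class `soft_label_map`.
#' @export
soft_label_map <- function(p, mask) {
  d <- dim(mask)
  if (is.matrix(p)) {
    probs <- array(0, dim = c(d, 3))
    for (s in 1:3) {
      ch <- array(0, dim = d); ch[mask] <- p[, s]
      probs[, , , s] <- ch
    }
  } else {
    probs <- p
    if (!identical(dim(probs), c(d, 3L))) stop("probs/mask shape mismatch")
    probs[array(rep(!mask, 3), dim = c(d, 3))] <- 0
  }
  structure(list(probs = probs, mask = mask), class = "soft_label_map")
}

#' @export
print.soft_label_map <- function(x, ...) {
  cat(sprintf("<soft_label_map> %s voxels, %d on mask\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  invisible(x)
}

# mask voxels x 3 matrix view of a soft label map
soft_as_matrix <- function(soft) {
  matrix(vapply(1:3, function(s) soft$probs[, , , s][soft$mask],
                numeric(sum(soft$mask))), ncol = 3)
}

#' Hard segmentation from a soft-label map
#'
#' Per-voxel argmax over the three subregion channels; ties resolved
#' toward the lower label index (head before body before tail).
#' Background stays 0.
#'
#' @param soft a `soft_label_map`.
#' @return Integer label array (0 background, 1 head, 2 body, 3 tail).
#' @export
bayes_segment <- function(soft) {
  p <- soft_as_matrix(soft)
  lab <- max.col(p, ties.method = "first")
  out <- array(0L, dim = dim(soft$mask))
  out[soft$mask] <- as.integer(lab)
  out
}

#' Serialize fitted Gaussians to JSON
#'
#' @param object a `subregion_bayes` model.
#' @param path output JSON file.
#' @return Invisibly `path`.
#' @export
write_subregion_bayes <- function(object, path) {
  jsonlite::write_json(list(
    schema = "pancseg.subregion_bayes.v1",
    mu_alpha = as.list(object$mu_alpha),
    sigma_alpha = as.list(object$sigma_alpha),
    mu_beta = as.list(object$mu_beta),
    sigma_beta = as.list(object$sigma_beta),
    priors = as.list(object$priors),
    n_voxels = as.list(object$n_voxels),
    sigma_floor = object$sigma_floor), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fitted Gaussians back from JSON
#'
#' @param path JSON file written by [write_subregion_bayes()].
#' @return A `subregion_bayes` model.
#' @export
read_subregion_bayes <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, "pancseg.subregion_bayes.v1"))
    stop("unrecognized parameter file schema")
  structure(list(
    mu_alpha = unlist(j$mu_alpha), sigma_alpha = unlist(j$sigma_alpha),
    mu_beta = unlist(j$mu_beta), sigma_beta = unlist(j$sigma_beta),
    priors = unlist(j$priors), n_voxels = unlist(j$n_voxels),
    sigma_floor = j$sigma_floor), class = "subregion_bayes")
}
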