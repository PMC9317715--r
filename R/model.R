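# The end-to-end anatomy-guided model: preprocessing -> geometric features
# -> Bayes soft labels -> segmentation network with per-epoch fusion.

#' Fit the anatomy-guided subregion segmentation model
#'
#' Runs the whole training pipeline on labeled cases: preprocessing (crop
#' to the padded pancreas bounding box, background zeroing, intensity
#' normalization), geometric feature extraction with the labeled head
#' endpoint, pooled Gaussian fitting of the Bayes soft-label model, and
#' training of the segmentation network with voxel-wise fusion of the two
#' probability maps.
#'
#' @param cases list of training cases; each a list with `volume` (a
#'   [pancreas_volume], raw intensities are fine), `labels` (integer
#'   array) and optionally `id`.
#' @param config a [net_config()].
#' @param padding crop margin in voxels.
#' @param alpha_metric,beta_method feature options, see
#'   [subregion_features()].
#' @param head_axis,head_side laterality convention used at prediction
#'   time (no labels available then).
#' @param priors,sigma_floor passed to [fit_subregion_bayes()].
#' @param verbose print training progress.
#' @return An object of class `pancseg_model` bundling the fitted
#'   `subregion_bayes` model, the trained `pancseg_net` and the options
#'   needed to reproduce the preprocessing at prediction time.
#' @export
pancseg_fit <- function(cases, config = net_config(), padding = 8,
                        alpha_metric = "geodesic", beta_method = "cumulative",
                        head_axis = 1L, head_side = "low",
                        priors = rep(1 / 3, 3), sigma_floor = 1e-3,
                        verbose = FALSE) {
  if (length(cases) < 2) stop("need at least 2 training cases")
  prepped <- lapply(cases, function(cs)
    preprocess_volume(cs$volume, cs$labels, padding = padding))
  feats <- lapply(prepped, function(pr)
    subregion_features(pr$volume, pr$labels, alpha_metric = alpha_metric,
                       beta_method = beta_method))
  bayes <- fit_subregion_bayes(feats, lapply(prepped, `[[`, "labels"),
                               priors = priors, sigma_floor = sigma_floor)
  xs <- lapply(feats, function(f) predict(bayes, f))
  net_data <- Map(function(pr, X) list(volume = pr$volume,
                                       labels = pr$labels, X = X),
                  prepped, xs)
  net <- fit_segmentation_net(net_data, config, verbose = verbose)
  structure(list(bayes = bayes, net = net, config = config,
                 padding = padding, alpha_metric = alpha_metric,
                 beta_method = beta_method, head_axis = head_axis,
                 head_side = head_side, n_train = length(cases)),
            class = "pancseg_model")
}

#' @export
print.pancseg_model <- function(x, ...) {
  cat(sprintf("<pancseg_model> trained on %d cases\n", x$n_train))
  print(x$bayes)
  print(x$net)
  invisible(x)
}

#' @export
summary.pancseg_model <- function(object, ...) {
  print(object)
  cat("\nTraining log (last epochs):\n")
  print(utils::tail(object$net$log, 3))
  invisible(object)
}

#' @export
coef.pancseg_model <- function(object, ...) coef(object$bayes)

#' Segment the pancreas subregions of a new case
#'
#' Applies the full inference path: preprocessing, inference-mode head
#' endpoint (double-sweep pseudo-diameter + laterality rule), Bayes soft
#' labels, network forward pass, fusion and argmax. Output labels are
#' placed back on the original grid.
#'
#' @param object a fitted `pancseg_model`.
#' @param volume a [pancreas_volume] (raw intensities are fine).
#' @param ... unused.
#' @return list with `labels` (fused prediction, original grid),
#'   `bayes_labels` (Bayes-only argmax, original grid), `prob` (fused
#'   `soft_label_map` on the cropped grid), `features`, `offset` and
#'   `cropped_volume`.
#' @export
predict.pancseg_model <- function(object, volume, ...) {
  pre <- preprocess_volume(volume, NULL, padding = object$padding)
  feats <- subregion_features(pre$volume,
                              alpha_metric = object$alpha_metric,
                              beta_method = object$beta_method,
                              head_axis = object$head_axis,
                              head_side = object$head_side)
  X <- predict(object$bayes, feats)
  use_net <- object$config$input_bayes || object$config$fusion
  pr <- predict(object$net, pre$volume, X = X)
  full <- uncrop_array(pr$labels, pre$offset, pre$original_dim, fill = 0L)
  bay <- uncrop_array(bayes_segment(X), pre$offset, pre$original_dim,
                      fill = 0L)
  list(labels = full, bayes_labels = bay, prob = pr$prob, features = feats,
       offset = pre$offset, cropped_volume = pre$volume)
}
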