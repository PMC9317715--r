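# Evaluation: Dice similarity, cross-validation, external validation and
# failure diagnostics (boundary-error fraction, head/tail confusions).

#' Dice similarity coefficient for one subregion
#'
#' `DSC = 2TP / (2TP + FP + FN)` where the positive class is the chosen
#' subregion and the negative class the union of the other two. Computed
#' over pancreas voxels; returns 1 when the subregion is empty in both
#' prediction and reference.
#'
#' @param pred,ref integer label arrays of identical shape (0 outside the
#'   pancreas).
#' @param cls subregion id (1 head, 2 body, 3 tail) or name.
#' @return Dice fraction in \[0, 1\].
#' @export
dsc <- function(pred, ref, cls) {
  if (!identical(dim(pred), dim(ref)))
    stop("shape mismatch between prediction and reference")
  if (is.character(cls)) cls <- SUBREGIONS[[cls]]
  p <- pred == cls
  r <- ref == cls
  tp <- sum(p & r)
  denom <- 2 * tp + sum(p & !r) + sum(!p & r)
  if (denom == 0) return(1)
  2 * tp / denom
}

#' Per-class and overall Dice report for one case
#'
#' @inheritParams dsc
#' @param weighted `FALSE` (default) averages the three class DSCs with
#'   equal weight; `TRUE` weights by reference voxel counts.
#' @return Named numeric: head, body, tail and overall DSC as percentages.
#' @export
dsc_report <- function(pred, ref, weighted = FALSE) {
  d <- vapply(SUBREGIONS, function(s) dsc(pred, ref, s), numeric(1))
  w <- if (weighted) {
    cnt <- vapply(SUBREGIONS, function(s) sum(ref == s), numeric(1))
    cnt / sum(cnt)
  } else rep(1 / 3, 3)
  c(head = 100 * d[[1]], body = 100 * d[[2]], tail = 100 * d[[3]],
    overall = 100 * sum(d * w))
}

#' Deterministic balanced cross-validation split
#'
#' Shuffles the case ids with the given seed and deals them into `folds`
#' subsets whose sizes differ by at most one; every case is tested exactly
#' once.
#'
#' @param case_ids character or integer vector of case identifiers.
#' @param folds number of folds (default 4).
#' @param seed RNG seed.
#' @return list of `folds` elements, each `list(train = , test = )`.
#' @export
crossval_split <- function(case_ids, folds = 4, seed = 1L) {
  n <- length(case_ids)
  if (n < folds) stop("need at least as many cases as folds")
  set.seed(seed)
  perm <- case_ids[sample.int(n)]
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_of <- rep(seq_len(folds), times = sizes)
  lapply(seq_len(folds), function(f)
    list(train = perm[fold_of != f], test = perm[fold_of == f]))
}

# abort if any test id leaks into its training set, or the folds are not
# a partition of the case ids
check_no_leakage <- function(splits, case_ids) {
  tests <- unlist(lapply(splits, `[[`, "test"))
  if (length(tests) != length(case_ids) || !setequal(tests, case_ids) ||
      anyDuplicated(tests))
    stop("cross-validation folds are not a partition of the case ids")
  for (sp in splits) {
    leak <- intersect(sp$train, sp$test)
    if (length(leak))
      stop("data leakage: case(s) in both training and test set: ",
           paste(leak, collapse = ", "))
  }
  invisible(TRUE)
}

dilate26 <- function(a) {
  out <- array(FALSE, dim(a))
  for (o in 1:27) {
    off <- KERNEL_OFFSETS[o, ]
    if (all(off == 0)) next
    out <- out | shift3(a, off) > 0
  }
  out
}

#' Failure diagnostics: boundary errors and head/tail confusions
#'
#' Quantifies the two failure modes that matter anatomically: the fraction
#' of misclassified voxels lying within `k` voxels (geodesically, inside
#' the mask) of the reference body/tail interface, and the number of
#' voxels confused between the non-adjacent head and tail.
#'
#' @inheritParams dsc
#' @param k border-zone half-width in voxels (default 3).
#' @return list with `boundary_error_fraction` (`NA` when there are no
#'   errors), `head_tail_confusions`, `n_errors`, `n_boundary_errors`.
#' @export
failure_diagnostics <- function(pred, ref, k = 3) {
  if (!identical(dim(pred), dim(ref)))
    stop("shape mismatch between prediction and reference")
  mask <- ref > 0L
  errors <- mask & (pred != ref)
  n_err <- sum(errors)
  confusions <- sum((ref == SUBREGIONS[["head"]] & pred == SUBREGIONS[["tail"]]) |
                    (ref == SUBREGIONS[["tail"]] & pred == SUBREGIONS[["head"]]))
  if (n_err == 0)
    return(list(boundary_error_fraction = NA_real_, head_tail_confusions = confusions,
                n_errors = 0L, n_boundary_errors = 0L))
  isB <- ref == SUBREGIONS[["body"]]
  isT <- ref == SUBREGIONS[["tail"]]
  border <- (isB & dilate26(isT)) | (isT & dilate26(isB))
  if (!any(border)) {
    n_bnd <- 0L
  } else {
    d <- cpp_geodesic(as.vector(mask), dim(mask), which(border), c(1, 1, 1))
    zone <- array(is.finite(d) & d <= k, dim(mask))
    n_bnd <- sum(errors & zone)
  }
  list(boundary_error_fraction = n_bnd / n_err,
       head_tail_confusions = confusions,
       n_errors = as.integer(n_err), n_boundary_errors = as.integer(n_bnd))
}

eval_one_case <- function(id, fold, model_name, pred, ref, k = 3,
                          weighted = FALSE) {
  d <- dsc_report(pred, ref, weighted = weighted)
  fd <- failure_diagnostics(pred, ref, k = k)
  data.frame(id = id, fold = fold, model = model_name,
             dsc_head = d[["head"]], dsc_body = d[["body"]],
             dsc_tail = d[["tail"]], dsc_overall = d[["overall"]],
             boundary_error_fraction = fd$boundary_error_fraction,
             head_tail_confusions = fd$head_tail_confusions,
             n_errors = fd$n_errors)
}

#' Cross-validated or external evaluation of the whole pipeline
#'
#' In `"crossval"` mode the Bayes fitting and network training are redone
#' per fold on that fold's training cases only (a leakage guard aborts if
#' any test id appears in its training set), and every test case is
#' segmented and scored. In `"external"` mode a supplied pretrained
#' `pancseg_model` only predicts; nothing is updated. Scores the fused
#' model and the Bayes-only baseline on every case; `ablation = TRUE`
#' additionally trains and scores a plain network (no Bayes input, no
#' fusion) per fold.
#'
#' @param dataset list of cases with `id`, `volume`, `labels`.
#' @param mode `"crossval"` or `"external"`.
#' @param config a [net_config()].
#' @param folds number of folds (crossval mode).
#' @param seed seed controlling the split and all training randomness.
#' @param model pretrained `pancseg_model` (external mode).
#' @param splits optional precomputed fold list (validated by the leakage
#'   guard before use).
#' @param ablation also evaluate the plain-network baseline.
#' @param border_k border-zone half-width for [failure_diagnostics()].
#' @param ... passed to [pancseg_fit()].
#' @return An object of class `pancseg_eval`: `per_case` (data frame),
#'   `summary` (mean DSC per model), `fold_models` (per-fold Bayes
#'   parameters and training logs) and the resolved `splits`.
#' @export
evaluate_pipeline <- function(dataset, mode = c("crossval", "external"),
                              config = net_config(), folds = 4, seed = 1L,
                              model = NULL, splits = NULL, ablation = FALSE,
                              border_k = 3, ...) {
  mode <- match.arg(mode)
  ids <- vapply(dataset, function(cs) as.character(cs$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate case ids")
  names(dataset) <- ids
  rows <- list()
  fold_models <- list()

  if (mode == "external") {
    if (is.null(model)) stop("external mode requires a pretrained model")
    for (id in ids) {
      cs <- dataset[[id]]
      pr <- predict(model, cs$volume)
      rows[[length(rows) + 1]] <-
        eval_one_case(id, 0L, "fused", pr$labels, cs$labels, k = border_k)
      rows[[length(rows) + 1]] <-
        eval_one_case(id, 0L, "bayes", pr$bayes_labels, cs$labels, k = border_k)
    }
    splits <- NULL
  } else {
    if (is.null(splits)) splits <- crossval_split(ids, folds, seed)
    check_no_leakage(splits, ids)
    for (f in seq_along(splits)) {
      sp <- splits[[f]]
      stopifnot(length(intersect(sp$train, sp$test)) == 0)
      cfg <- config
      cfg$seed <- config$seed + f - 1L
      fit <- pancseg_fit(dataset[sp$train], config = cfg, ...)
      fold_models[[f]] <- list(bayes = fit$bayes, net_log = fit$net$log)
      plain <- NULL
      if (ablation) {
        pcfg <- cfg
        pcfg$input_bayes <- FALSE
        pcfg$fusion <- FALSE
        plain <- pancseg_fit(dataset[sp$train], config = pcfg, ...)
      }
      for (id in sp$test) {
        cs <- dataset[[id]]
        pr <- predict(fit, cs$volume)
        rows[[length(rows) + 1]] <-
          eval_one_case(id, f, "fused", pr$labels, cs$labels, k = border_k)
        rows[[length(rows) + 1]] <-
          eval_one_case(id, f, "bayes", pr$bayes_labels, cs$labels,
                        k = border_k)
        if (!is.null(plain)) {
          pp <- predict(plain, cs$volume)
          rows[[length(rows) + 1]] <-
            eval_one_case(id, f, "plain", pp$labels, cs$labels, k = border_k)
        }
      }
    }
  }
  per_case <- do.call(rbind, rows)
  rownames(per_case) <- NULL
  summ <- do.call(rbind, lapply(split(per_case, per_case$model), function(d)
    data.frame(model = d$model[1], n = nrow(d),
               dsc_head = mean(d$dsc_head), dsc_body = mean(d$dsc_body),
               dsc_tail = mean(d$dsc_tail), dsc_overall = mean(d$dsc_overall),
               boundary_error_fraction =
                 mean(d$boundary_error_fraction, na.rm = TRUE),
               head_tail_confusions = sum(d$head_tail_confusions))))
  rownames(summ) <- NULL
  structure(list(per_case = per_case, summary = summ,
                 fold_models = fold_models, splits = splits, mode = mode),
            class = "pancseg_eval")
}

#' @export
print.pancseg_eval <- function(x, ...) {
  cat(sprintf("<pancseg_eval> %s, %d case evaluations\n", x$mode,
              nrow(x$per_case)))
  s <- x$summary
  for (cc in c("dsc_head", "dsc_body", "dsc_tail", "dsc_overall"))
    s[[cc]] <- sprintf("%.1f", s[[cc]])
  print(s)
  invisible(x)
}

#' Write an evaluation report as CSV + JSON
#'
#' @param report a `pancseg_eval`.
#' @param dir output directory (created if missing).
#' @return Invisibly the paths written.
#' @export
save_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "per_case.csv")
  p2 <- file.path(dir, "summary.csv")
  p3 <- file.path(dir, "report.json")
  write.csv(report$per_case, p1, row.names = FALSE)
  write.csv(report$summary, p2, row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            per_case = report$per_case),
                       p3, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(p1, p2, p3))
}
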