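# Per-anatomy classifiers and the visit-level model bundle.

#' Train one per-anatomy classifier
#'
#' `"rf"`: a random forest with 100 trees, class weights inversely
#' proportional to class frequencies, and the minimum node size for a
#' split set to 10% of the training samples (the dominant regularizer on
#' this task). `"lr"`: logistic regression with balanced case weights
#' mirroring the forest's class weighting, otherwise unregularized. Both
#' expose probabilities and are deterministic given the seed.
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Binary targets (0/1), both classes present.
#' @param kind `"rf"` or `"lr"`.
#' @param n_trees Trees for the forest (default 100).
#' @param min_split_frac Minimum node size for a split, as a fraction of
#'   `nrow(x)` (default 0.1).
#' @param balanced Use balanced class weights (default `TRUE`).
#' @param seed RNG seed for the forest.
#' @return An `anatomy_model` with a `predict` method returning
#'   probabilities.
#' @export
train_anatomy_model <- function(x, y, kind = c("rf", "lr"), n_trees = 100L,
                                min_split_frac = 0.1, balanced = TRUE,
                                seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (n < 20L) stop("need at least 20 training samples", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("single-class targets", call. = FALSE)
  fit <- if (kind == "rf") {
    wt <- if (balanced) c("0" = n / (2 * n0), "1" = n / (2 * n1)) else NULL
    with_seed(seed, randomForest::randomForest(
      x, factor(y, levels = c(0L, 1L)), ntree = n_trees, classwt = wt,
      nodesize = ceiling(min_split_frac * n)))
  } else {
    w <- if (balanced) ifelse(y == 1L, n / (2 * n1), n / (2 * n0)) else rep(1, n)
    df <- data.frame(x)
    df$.y <- y
    suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial(),
                                weights = w))
  }
  structure(list(kind = kind, fit = fit, features = colnames(x), seed = seed),
            class = "anatomy_model")
}

#' @export
predict.anatomy_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  newdata <- newdata[, object$features, drop = FALSE]
  if (object$kind == "rf") {
    as.numeric(stats::predict(object$fit, newdata, type = "prob")[, "1"])
  } else {
    as.numeric(stats::predict(object$fit, data.frame(newdata),
                              type = "response"))
  }
}

#' Fit the two-anatomy progression classifier
#'
#' Fits one classifier per anatomy (hands/APB and feet/AH) on that
#' anatomy's feature table; the bundle's prediction for a visit is the
#' arithmetic mean of the two per-anatomy probabilities. The anatomies
#' are modelled separately because their traces are disparate and a
#' joint model with all features overfits.
#'
#' @param x_by_anatomy Named list (`APB`, `AH`) of feature matrices with
#'   identical row order (one row per visit).
#' @param y Binary targets (0/1), aligned with the rows.
#' @param kind `"rf"` or `"lr"`.
#' @param n_trees,min_split_frac,balanced,seed Passed to
#'   [train_anatomy_model()].
#' @return An object of class `mep_model`.
#' @export
fit_progression <- function(x_by_anatomy, y, kind = c("rf", "lr"),
                            n_trees = 100L, min_split_frac = 0.1,
                            balanced = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.list(x_by_anatomy), length(x_by_anatomy) >= 1L,
            !is.null(names(x_by_anatomy)))
  models <- lapply(seq_along(x_by_anatomy), function(i) {
    train_anatomy_model(x_by_anatomy[[i]], y, kind = kind, n_trees = n_trees,
                        min_split_frac = min_split_frac, balanced = balanced,
                        seed = child_seed(seed, i))
  })
  names(models) <- names(x_by_anatomy)
  lit <- lapply(x_by_anatomy, function(m) {
    setdiff(colnames(m), catalog_feature_names())
  })
  ts_feats <- lapply(x_by_anatomy, function(m) {
    intersect(colnames(m), catalog_feature_names())
  })
  structure(list(kind = kind, models = models,
                 features = lapply(x_by_anatomy, colnames),
                 lit_features = lit, ts_features = ts_feats,
                 n = length(y), prevalence = mean(y), seed = seed),
            class = "mep_model")
}

#' Predict progression probabilities for visits
#'
#' @param object An `mep_model`.
#' @param newdata Named list of per-anatomy feature matrices with
#'   identical row order; every anatomy of the model must be present.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, the mean of the
#'   per-anatomy predictions.
#' @export
predict.mep_model <- function(object, newdata, ...) {
  missing_an <- setdiff(names(object$models), names(newdata))
  if (length(missing_an)) {
    stop(sprintf("missing anatomy feature table(s): %s",
                 paste(missing_an, collapse = ", ")), call. = FALSE)
  }
  per <- vapply(names(object$models), function(an) {
    predict(object$models[[an]], newdata[[an]])
  }, numeric(nrow(as.matrix(newdata[[1L]]))))
  if (is.null(dim(per))) per <- matrix(per, nrow = 1L)
  rowMeans(per)
}

#' Average the per-anatomy predictions for visits
#'
#' Alias of the `predict` method with the averaging rule made explicit:
#' the final prediction for a visit is the arithmetic mean of the hand
#' and foot classifier probabilities.
#'
#' @inheritParams predict.mep_model
#' @param bundle An `mep_model`.
#' @return Probability vector.
#' @export
predict_visit <- function(bundle, newdata) {
  stopifnot(inherits(bundle, "mep_model"))
  predict(bundle, newdata)
}

#' @export
print.mep_model <- function(x, ...) {
  cat(sprintf("<mep_model> %s, %d anatomies, trained on %d visits (prevalence %.3f)\n",
              toupper(x$kind), length(x$models), x$n, x$prevalence))
  for (an in names(x$models)) {
    cat(sprintf("  %s: %s\n", an, paste(x$features[[an]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.mep_model <- function(object, ...) {
  cat(sprintf("Two-year disability progression model (%s)\n",
              toupper(object$kind)))
  cat(sprintf("Trained on %d visits, positive rate %.3f\n\n", object$n,
              object$prevalence))
  for (an in names(object$models)) {
    cat(sprintf("Anatomy %s\n", an))
    cat(sprintf("  literature features: %s\n",
                paste(object$lit_features[[an]], collapse = ", ")))
    cat(sprintf("  time-series features: %s\n",
                if (length(object$ts_features[[an]]))
                  paste(object$ts_features[[an]], collapse = ", ")
                else "(none)"))
    m <- object$models[[an]]
    if (m$kind == "rf") {
      err <- m$fit$err.rate[nrow(m$fit$err.rate), "OOB"]
      cat(sprintf("  out-of-bag error: %.3f\n", err))
    } else {
      cf <- stats::coef(m$fit)
      cat("  coefficients:\n")
      print(round(cf, 4))
    }
  }
  invisible(object)
}

#' @export
coef.mep_model <- function(object, ...) {
  lapply(object$models, function(m) {
    if (m$kind == "lr") stats::coef(m$fit)
    else randomForest::importance(m$fit)[, 1]
  })
}
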