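#' Generate synthetic feature/blood-pressure training data
#'
#' A stand-in generator for clinical training archives (which are outside
#' this package's scope): feature vectors are drawn uniformly on `[0, 1]`
#' (matching the post-rescaling range of the extraction pipeline) and the
#' systolic/diastolic pressures are linear combinations of the features
#' plus Gaussian noise, so the planted ground truth is known exactly.
#' Per-window pressure ranges are drawn from folded normals so a
#' controllable share of windows violates the range filters.
#'
#' @param n Number of samples (>= 10).
#' @param seed RNG seed (bitwise-reproducible output for a fixed seed).
#' @param features Feature names (defaults to the package registry).
#' @param coef_sys,coef_dia Named coefficient vectors over (a subset of)
#'   the features; unnamed scalar recycles over all features.
#' @param intercept_sys,intercept_dia Intercepts, mmHg.
#' @param noise_sd Gaussian noise sd, mmHg.
#' @param range_sd Scale of the folded-normal per-window sys/dia ranges.
#' @return A data frame with one row per sample: feature columns,
#'   `systolic_bp`, `diastolic_bp`, `window_sys_range`, `window_dia_range`;
#'   the planted truth is stored in `attr(, "truth")`.
#' @export
generate_synthetic_training <- function(n, seed = 1,
                                        features = feature_names(),
                                        coef_sys = NULL, coef_dia = NULL,
                                        intercept_sys = 120,
                                        intercept_dia = 80,
                                        noise_sd = 5, range_sd = 6) {
  if (n < 10) stop("n must be >= 10")
  p <- length(features)
  full_coef <- function(cf, default_mag) {
    out <- stats::setNames(rep(0, p), features)
    if (is.null(cf)) {
      out[seq_len(min(5, p))] <- default_mag
    } else if (is.null(names(cf)) && length(cf) == 1) {
      out[] <- cf
    } else {
      bad <- setdiff(names(cf), features)
      if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
      out[names(cf)] <- cf
    }
    out
  }
  cs <- full_coef(coef_sys, 20)
  cd <- full_coef(coef_dia, 12)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  X <- matrix(stats::runif(n * p), n, p, dimnames = list(NULL, features))
  sys <- intercept_sys + as.numeric(X %*% cs) + stats::rnorm(n, 0, noise_sd)
  dia <- intercept_dia + as.numeric(X %*% cd) + stats::rnorm(n, 0, noise_sd)
  out <- data.frame(X, check.names = FALSE)
  out$systolic_bp <- sys
  out$diastolic_bp <- dia
  out$window_sys_range <- abs(stats::rnorm(n, 0, range_sd))
  out$window_dia_range <- abs(stats::rnorm(n, 0, range_sd * 0.6))
  attr(out, "truth") <- list(coef_sys = cs, coef_dia = cd,
                             intercept_sys = intercept_sys,
                             intercept_dia = intercept_dia,
                             noise_sd = noise_sd)
  out
}

.bp_cols <- c("systolic_bp", "diastolic_bp", "window_sys_range",
              "window_dia_range")

#' Training-data preprocessing: range filter, outlier removal, rescaling
#'
#' In order: (1) windows whose within-window systolic range exceeds
#' `max_sys_range` (20 mmHg) or diastolic range exceeds `max_dia_range`
#' (12 mmHg) are discarded; (2) samples with any feature beyond 3 standard
#' deviations of that feature's mean are removed, iterated to a fixed point
#' so the operation is idempotent; (3) every feature is min-max rescaled to
#' `[0, 1]` (constant features map to 0 with a warning).
#'
#' @param samples A data frame as produced by
#'   [generate_synthetic_training()] (feature columns plus BP and range
#'   columns).
#' @param max_sys_range,max_dia_range Range-filter thresholds, mmHg.
#' @param sd_limit Outlier threshold in feature standard deviations.
#' @return The filtered, rescaled data frame; counts of discarded samples
#'   in `attr(, "preprocess")`.
#' @export
preprocess_training <- function(samples, max_sys_range = 20,
                                max_dia_range = 12, sd_limit = 3) {
  feats <- setdiff(names(samples), .bp_cols)
  keep <- samples$window_sys_range <= max_sys_range &
    samples$window_dia_range <= max_dia_range
  n_range <- sum(!keep)
  out <- samples[keep, , drop = FALSE]
  n_outlier <- 0
  repeat {
    if (nrow(out) == 0) stop("no samples survive preprocessing")
    ok <- rep(TRUE, nrow(out))
    for (f in feats) {
      v <- out[[f]]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) next
      ok <- ok & abs(v - mean(v)) <= sd_limit * s
    }
    if (all(ok)) break
    n_outlier <- n_outlier + sum(!ok)
    out <- out[ok, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no samples survive preprocessing")
  for (f in feats) {
    v <- out[[f]]
    r <- range(v)
    if (diff(r) == 0) {
      warning("feature '", f, "' is constant; rescaled to 0")
      out[[f]] <- rep(0, length(v))
    } else {
      out[[f]] <- (v - r[1]) / diff(r)
    }
  }
  rownames(out) <- NULL
  attr(out, "preprocess") <- list(n_range_discarded = n_range,
                                  n_outliers_removed = n_outlier,
                                  n_kept = nrow(out))
  out
}

#' Construct a pluggable blood-pressure regression model
#'
#' All models implement the same contract: `bp_fit(model, data)` trains on
#' the feature columns against `systolic_bp` and `diastolic_bp`, and
#' `predict()` on the fitted object returns a two-column matrix of
#' predictions. Available types:
#' \describe{
#'   \item{`svm`}{Gaussian-kernel support vector regression (kernel scale
#'     1.5, i.e. `gamma = 1/1.5^2`), standardized inputs; needs
#'     \pkg{e1071}.}
#'   \item{`trees`}{bagged regression trees (a random forest with
#'     `mtry = p`, which is bagging); needs \pkg{randomForest}.}
#'   \item{`nn`}{single-hidden-layer network with 100 hidden units, linear
#'     output; needs \pkg{nnet}.}
#'   \item{`linear`}{ordinary least squares (no extra dependency).}
#'   \item{`custom`}{user-supplied `fit(x, y) -> object` and
#'     `predict(object, x) -> vector` functions, applied per target.}
#' }
#'
#' @param type Model type (see above).
#' @param ... For `custom`: `fit` and `predict` functions; otherwise passed
#'   to the backend.
#' @return An object of class `bp_model`.
#' @export
bp_model <- function(type = c("svm", "trees", "nn", "linear", "custom"),
                     ...) {
  type <- match.arg(type)
  opts <- list(...)
  if (type == "custom" &&
      (!is.function(opts$fit) || !is.function(opts$predict)))
    stop("custom models need `fit` and `predict` functions")
  structure(list(type = type, opts = opts, fitted = NULL),
            class = "bp_model")
}

.require_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("model backend needs the '", pkg, "' package")
}

#' Fit a blood-pressure model
#'
#' @param model A [bp_model()].
#' @param data Data frame with feature columns plus `systolic_bp` and
#'   `diastolic_bp`.
#' @return The fitted model (class `bp_model`, `fitted` populated).
#' @export
bp_fit <- function(model, data) {
  feats <- setdiff(names(data), .bp_cols)
  x <- as.matrix(data[, feats, drop = FALSE])
  fit_one <- function(yname) {
    y <- data[[yname]]
    switch(model$type,
      svm = {
        .require_pkg("e1071")
        do.call(e1071::svm,
                c(list(x = x, y = y, kernel = "radial",
                       gamma = 1 / 1.5^2, scale = TRUE),
                  model$opts))
      },
      trees = {
        .require_pkg("randomForest")
        do.call(randomForest::randomForest,
                c(list(x = x, y = y, mtry = ncol(x),
                       ntree = model$opts$ntree %||% 100),
                  model$opts[setdiff(names(model$opts), "ntree")]))
      },
      nn = {
        .require_pkg("nnet")
        utils::capture.output(
          fit <- do.call(nnet::nnet,
                         c(list(x = x, y = y, size = model$opts$size %||% 100,
                                linout = TRUE, trace = FALSE,
                                maxit = model$opts$maxit %||% 200,
                                MaxNWts = 50000, decay = 1e-4),
                          model$opts[setdiff(names(model$opts),
                                             c("size", "maxit"))])))
        fit
      },
      linear = stats::lm.fit(cbind(1, x), y),
      custom = model$opts$fit(x, y))
  }
  model$fitted <- list(systolic = fit_one("systolic_bp"),
                       diastolic = fit_one("diastolic_bp"),
                       features = feats)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.bp_model <- function(object, newdata, ...) {
  if (is.null(object$fitted)) stop("model has not been fitted")
  feats <- object$fitted$features
  missing <- setdiff(feats, names(newdata))
  if (length(missing))
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(newdata[, feats, drop = FALSE])
  pred_one <- function(fit) {
    switch(object$type,
      linear = as.numeric(cbind(1, x) %*% fit$coefficients),
      custom = as.numeric(object$opts$predict(fit, x)),
      nn = as.numeric(predict(fit, x)),
      as.numeric(predict(fit, x)))
  }
  cbind(systolic = pred_one(object$fitted$systolic),
        diastolic = pred_one(object$fitted$diastolic))
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("Blood-pressure regression model: type '%s' (%s)\n", x$type,
              if (is.null(x$fitted)) "unfitted" else "fitted"))
  invisible(x)
}

#' Train/test evaluation of a blood-pressure model
#'
#' Splits the data into a training fraction and a held-out test set, runs
#' k-fold cross-validation within the training set, refits on the full
#' training set, and summarizes held-out errors as mean error and error
#' standard deviation per target (the summary convention of automated
#' sphygmomanometer validation, which references mean error below 5 mmHg
#' and error sd against 8 mmHg).
#'
#' @param model A [bp_model()].
#' @param samples Preprocessed training table.
#' @param train_fraction Fraction used for training (default 0.7).
#' @param folds Cross-validation folds within the training set.
#' @param seed Split seed.
#' @return An object of class `bp_evaluation` with the held-out
#'   `mean_error` and `sd_error` (2-vectors: systolic, diastolic), the
#'   per-fold CV table, and the fitted model.
#' @export
evaluate_split <- function(model, samples, train_fraction = 0.7, folds = 10,
                           seed = 1) {
  n <- nrow(samples)
  if (n < folds) stop("fewer samples than folds")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- max(folds, round(train_fraction * n))
  train_i <- idx[seq_len(n_train)]
  test_i <- idx[-seq_len(n_train)]
  if (!length(test_i)) stop("empty test split; lower train_fraction")
  train <- samples[train_i, , drop = FALSE]
  fold_id <- rep_len(seq_len(folds), length(train_i))
  cv <- do.call(rbind, lapply(seq_len(folds), function(kf) {
    tr <- train[fold_id != kf, , drop = FALSE]
    te <- train[fold_id == kf, , drop = FALSE]
    fit <- bp_fit(model, tr)
    pr <- predict(fit, te)
    data.frame(fold = kf,
               sys_mean_error = mean(pr[, 1] - te$systolic_bp),
               dia_mean_error = mean(pr[, 2] - te$diastolic_bp))
  }))
  fit <- bp_fit(model, train)
  pr <- predict(fit, samples[test_i, , drop = FALSE])
  err <- cbind(systolic = pr[, 1] - samples$systolic_bp[test_i],
               diastolic = pr[, 2] - samples$diastolic_bp[test_i])
  structure(list(
    mean_error = colMeans(err),
    sd_error = apply(err, 2, stats::sd),
    cv = cv, model = fit,
    n_train = length(train_i), n_test = length(test_i)
  ), class = "bp_evaluation")
}

#' @export
print.bp_evaluation <- function(x, ...) {
  cat(sprintf(
    "Held-out evaluation (n_train=%d, n_test=%d):\n  systolic: mean error %.3g, sd %.3g mmHg\n  diastolic: mean error %.3g, sd %.3g mmHg\n",
    x$n_train, x$n_test, x$mean_error[1], x$sd_error[1],
    x$mean_error[2], x$sd_error[2]))
  invisible(x)
}

#' Sensitivity of a trained model to the synthetic cohort
#'
#' The true blood pressure of synthetic records is unknown, so algorithm
#' sensitivity to patient/device factors is assessed as the standard
#' deviation of the model's predictions across the cohort: an insensitive
#' algorithm predicts nearly the same pressure for every synthetic record.
#'
#' @param model A fitted [bp_model()].
#' @param cohort Feature table of the synthetic cohort (>= 2 rows).
#' @return An object of class `sensitivity_report` with `sd_systolic`,
#'   `sd_diastolic` (mmHg) and the prediction matrix.
#' @export
sensitivity_analysis <- function(model, cohort) {
  if (is.null(model$fitted)) stop("model has not been fitted")
  if (nrow(cohort) < 2) stop("cohort needs at least two rows")
  pr <- predict(model, cohort)
  # population standard deviation: the cohort is the entire set of
  # synthetic conditions under study, not a sample from a larger one,
  # which also makes the metric exactly invariant to duplicating the
  # cohort
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(sd_systolic = psd(pr[, 1]),
                 sd_diastolic = psd(pr[, 2]),
                 predictions = pr, model_type = model$type),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "Prediction sd over the synthetic cohort ('%s'): systolic %.4g mmHg, diastolic %.4g mmHg\n",
    x$model_type, x$sd_systolic, x$sd_diastolic))
  invisible(x)
}
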