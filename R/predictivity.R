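# Phenotype-from-composition evaluation: leave-one-out cross-validation,
# permutation null, learning curve, feature importance.

#' Configure the regression model used for predictivity analyses
#'
#' The default is a random-forest ensemble with the classic regression
#' defaults: 500 trees and \eqn{\lfloor p/3 \rfloor} candidate features per
#' split. The `"ranger"` engine is the default implementation; `"randomForest"`
#' fits the same model through the randomForest package, and gradient-boosting
#' (`"xgboost"`) and lasso (`"glmnet"`) baselines are available behind the
#' same evaluation contract.
#'
#' @param engine One of `"ranger"`, `"randomForest"`, `"xgboost"`, `"glmnet"`.
#' @param n_trees Ensemble size for the tree engines (default 500).
#' @param mtry_fraction Fraction of features tried per split for the forest
#'   engines (default 1/3; at least one feature is always tried).
#' @param ... Additional engine-specific arguments stored in the config.
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(engine = c("ranger", "randomForest", "xgboost", "glmnet"),
                         n_trees = 500, mtry_fraction = 1 / 3, ...) {
  engine <- match.arg(engine)
  stopifnot(n_trees >= 1, mtry_fraction > 0, mtry_fraction <= 1)
  structure(list(engine = engine, n_trees = n_trees,
                 mtry_fraction = mtry_fraction, extra = list(...)),
            class = "model_config")
}

# Coerce predictor input to a plain numeric matrix with feature names.
as_feature_matrix <- function(x) {
  if (inherits(x, "abundance_table")) x <- x$values
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  x
}

# Fit the configured regressor; `seed` controls all engine randomness.
fit_regressor <- function(x, y, config, seed) {
  mtry <- max(1L, floor(ncol(x) * config$mtry_fraction))
  switch(config$engine,
    ranger = ranger::ranger(
      x = x, y = y, num.trees = config$n_trees, mtry = mtry,
      num.threads = 1, seed = as.integer(seed)
    ),
    randomForest = with_seed(seed, {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("the randomForest package is not installed", call. = FALSE)
      }
      randomForest::randomForest(x = x, y = y, ntree = config$n_trees,
                                 mtry = mtry, importance = TRUE)
    }),
    xgboost = with_seed(seed, {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("the xgboost package is not installed", call. = FALSE)
      }
      xgboost::xgboost(
        x = x, y = y, nrounds = config$extra$nrounds %||% 200,
        max_depth = config$extra$max_depth %||% 3,
        learning_rate = config$extra$learning_rate %||% 0.1,
        subsample = config$extra$subsample %||% 0.8,
        nthreads = 1, verbosity = 0
      )
    }),
    glmnet = with_seed(seed, glmnet::cv.glmnet(x, y, alpha = 1, nfolds = 5))
  )
}

predict_regressor <- function(fit, config, newx) {
  switch(config$engine,
    ranger = predict(fit, data = newx, num.threads = 1)$predictions,
    randomForest = as.numeric(predict(fit, newx)),
    xgboost = as.numeric(predict(fit, newx)),
    glmnet = as.numeric(predict(fit, newx, s = "lambda.min"))
  )
}

#' Leave-one-out cross-validated predictions
#'
#' For each sample, fits the configured regressor on all other samples and
#' predicts the held-out one. Each fold uses a seed derived deterministically
#' from `seed` and the fold index, so prediction i depends only on the other
#' samples' data.
#'
#' @param x Feature matrix (samples x features) or `abundance_table`.
#' @param y Numeric outcome vector (one value per sample).
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Numeric vector of out-of-sample predictions, one per sample.
#' @export
loo_predictions <- function(x, y, config = model_config(), seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n != length(y)) stop("x and y disagree on sample count", call. = FALSE)
  if (n < 3) stop("need at least 3 samples for leave-one-out", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  if (var(y) == 0) warning("constant outcome: downstream R^2 is undefined")
  seeds <- child_seeds(seed, n)
  preds <- vapply(seq_len(n), function(i) {
    fit <- fit_regressor(x[-i, , drop = FALSE], y[-i], config, seeds[i])
    predict_regressor(fit, config, x[i, , drop = FALSE])
  }, numeric(1))
  names(preds) <- rownames(x)
  preds
}

#' Coefficient of determination of observed vs predicted values
#'
#' R-squared of the simple linear regression of observed on predicted values,
#' which equals the squared Pearson correlation of the two vectors. By
#' convention constant predictions score 0. Note that a strong
#' \emph{anti}-correlation also yields a high value; the measure quantifies
#' linear association, not agreement.
#'
#' @param observed Numeric vector (non-constant).
#' @param predicted Numeric vector of the same length.
#' @return R-squared in \[0, 1\].
#' @export
evaluate_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (length(observed) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (var(observed) == 0) stop("constant observed outcome", call. = FALSE)
  if (var(predicted) == 0) return(0)
  unname(cor(observed, predicted)^2)
}

#' Evaluate how well composition predicts a phenotype
#'
#' Runs full leave-one-out cross-validation and summarises predictive power as
#' the LOO R-squared of observed versus predicted outcomes.
#'
#' @param x Feature matrix or `abundance_table`.
#' @param y Outcome vector, or (when `x` is an `abundance_table`) the name of
#'   a metadata column such as `"survival_rate"`.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `"prediction_evaluation"` with elements
#'   `observed`, `predicted`, `loo_r2`, `config`, `seed`.
#' @export
evaluate_predictivity <- function(x, y, config = model_config(), seed = 1) {
  if (inherits(x, "abundance_table") && is.character(y) && length(y) == 1) {
    if (is.null(x$metadata) || !(y %in% names(x$metadata))) {
      stop(sprintf("metadata column '%s' not found", y), call. = FALSE)
    }
    y <- x$metadata[[y]]
  }
  y <- as.numeric(y)
  preds <- loo_predictions(x, y, config, seed)
  res <- list(observed = y, predicted = preds,
              loo_r2 = evaluate_r2(y, preds), config = config, seed = seed)
  class(res) <- "prediction_evaluation"
  res
}

#' @export
print.prediction_evaluation <- function(x, ...) {
  cat(sprintf("Leave-one-out predictivity (%s, %d samples)\n",
              x$config$engine, length(x$observed)))
  cat(sprintf("  LOO R^2 : %.3f\n", x$loo_r2))
  invisible(x)
}

#' @export
plot.prediction_evaluation <- function(x, ...) {
  graphics::plot(x$predicted, x$observed, xlab = "predicted outcome",
                 ylab = "observed outcome",
                 main = sprintf("LOO R^2 = %.2f", x$loo_r2), ...)
  graphics::abline(lm(x$observed ~ x$predicted), col = 2)
  invisible(x)
}

#' Permutation null distribution of the LOO R-squared
#'
#' Repeatedly permutes the outcome vector across samples, recomputes the full
#' leave-one-out R-squared each time, and reports the null distribution with
#' an empirical p-value for the observed R-squared,
#' \eqn{p = (1 + \#\{null \ge observed\})/(n_{perm}+1)}.
#'
#' @param x Feature matrix or `abundance_table`.
#' @param y Outcome vector.
#' @param n_perm Number of outcome permutations (default 100).
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `"permutation_null"` with elements `null`
#'   (vector of permuted-outcome R-squared values), `null_mean`, `null_sd`,
#'   `observed_r2`, `p_value`, `n_perm`.
#' @export
permutation_null <- function(x, y, n_perm = 100, config = model_config(), seed = 1) {
  if (n_perm < 1) stop("`n_perm` must be at least 1", call. = FALSE)
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  observed <- evaluate_r2(y, loo_predictions(x, y, config, seed))
  perms <- with_seed(seed, replicate(n_perm, sample.int(length(y)), simplify = FALSE))
  seeds <- child_seeds(seed + 7L, n_perm)
  null <- vapply(seq_len(n_perm), function(b) {
    yb <- y[perms[[b]]]
    evaluate_r2(yb, loo_predictions(x, yb, config, seeds[b]))
  }, numeric(1))
  res <- list(null = null, null_mean = mean(null), null_sd = sd(null),
              observed_r2 = observed,
              p_value = (1 + sum(null >= observed)) / (n_perm + 1),
              n_perm = n_perm)
  class(res) <- "permutation_null"
  res
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("Permutation null of LOO R^2 (%d outcome reshuffles)\n", x$n_perm))
  cat(sprintf("  observed R^2 : %.3f\n", x$observed_r2))
  cat(sprintf("  null mean/sd : %.4f / %.4f\n", x$null_mean, x$null_sd))
  cat(sprintf("  empirical p  : %.4g\n", x$p_value))
  invisible(x)
}

#' Learning curve: predictive power as a function of sample size
#'
#' For each subset size, draws `reps` random subsets of samples without
#' replacement, runs full leave-one-out cross-validation within each subset,
#' and records the R-squared. The overall trend is summarised by an ordinary
#' least-squares fit of the per-size mean R-squared on size, reported as
#' `slope_per_10` — the gain in R-squared per 10 additional samples.
#'
#' @param x Feature matrix or `abundance_table`.
#' @param y Outcome vector.
#' @param sizes Strictly increasing subset sizes (default 40 to 110 by 10).
#' @param reps Subsets per size (default 20).
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `"learning_curve"`: `summary` (data frame with
#'   `size`, `mean_r2`, `sd_r2`), `r2` (reps x sizes matrix), `slope_per_10`,
#'   `slope_r_squared`.
#' @export
learning_curve <- function(x, y, sizes = seq(40, 110, by = 10), reps = 20,
                           config = model_config(), seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) stop("`sizes` must be strictly increasing", call. = FALSE)
  if (any(sizes > n)) {
    stop(sprintf("subset size %d exceeds sample count %d", max(sizes), n), call. = FALSE)
  }
  if (any(sizes < 3)) stop("subset sizes must be at least 3", call. = FALSE)
  stopifnot(reps >= 1)
  subsets <- with_seed(seed, {
    lapply(sizes, function(s) lapply(seq_len(reps), function(r) sample.int(n, s)))
  })
  seeds <- matrix(child_seeds(seed + 13L, length(sizes) * reps), nrow = reps)
  r2 <- matrix(NA_real_, nrow = reps, ncol = length(sizes),
               dimnames = list(NULL, sizes))
  for (si in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      idx <- subsets[[si]][[r]]
      preds <- loo_predictions(x[idx, , drop = FALSE], y[idx], config, seeds[r, si])
      r2[r, si] <- evaluate_r2(y[idx], preds)
    }
  }
  smry <- data.frame(size = sizes, mean_r2 = colMeans(r2),
                     sd_r2 = apply(r2, 2, sd))
  slope_fit <- lm(mean_r2 ~ size, data = smry)
  res <- list(summary = smry, r2 = r2,
              slope_per_10 = unname(coef(slope_fit)[2]) * 10,
              slope_r_squared = summary(slope_fit)$r.squared,
              reps = reps, config = config)
  class(res) <- "learning_curve"
  res
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve (%d reps per size)\n", x$reps))
  print.data.frame(x$summary, row.names = FALSE)
  cat(sprintf("slope: %+.4f R^2 per 10 samples (trend R^2 = %.2f)\n",
              x$slope_per_10, x$slope_r_squared))
  invisible(x)
}

#' @export
plot.learning_curve <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$size, s$mean_r2, type = "b", pch = 16,
                 ylim = range(c(s$mean_r2 - s$sd_r2, s$mean_r2 + s$sd_r2)),
                 xlab = "number of samples", ylab = "mean LOO R^2", ...)
  graphics::arrows(s$size, s$mean_r2 - s$sd_r2, s$size, s$mean_r2 + s$sd_r2,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Rank features by their importance in predicting the outcome
#'
#' Fits the configured regressor on all samples and extracts per-feature
#' importances (impurity importance for the forest engines, gain for
#' gradient boosting, absolute coefficients for the lasso), normalised to sum
#' to 1 and sorted in decreasing order with ties broken by feature id.
#'
#' @param x Feature matrix or `abundance_table`.
#' @param y Outcome vector.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `feature` and `importance` (summing to 1).
#' @export
rank_features <- function(x, y, config = model_config(), seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  cfg <- config
  if (cfg$engine == "ranger") {
    fit <- ranger::ranger(x = x, y = y, num.trees = cfg$n_trees,
                          mtry = max(1L, floor(ncol(x) * cfg$mtry_fraction)),
                          importance = "impurity", num.threads = 1,
                          seed = as.integer(seed))
    imp <- fit$variable.importance
  } else if (cfg$engine == "randomForest") {
    fit <- fit_regressor(x, y, cfg, seed)
    imp <- randomForest::importance(fit, type = 2)[, 1]
  } else if (cfg$engine == "xgboost") {
    fit <- fit_regressor(x, y, cfg, seed)
    tab <- xgboost::xgb.importance(model = fit)
    imp <- stats::setNames(rep(0, ncol(x)), colnames(x))
    imp[tab$Feature] <- tab$Gain
  } else {
    fit <- fit_regressor(x, y, cfg, seed)
    cf <- as.numeric(coef(fit, s = "lambda.min"))[-1]
    imp <- stats::setNames(abs(cf), colnames(x))
  }
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
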