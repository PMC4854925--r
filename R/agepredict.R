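#' Cross-validated age prediction by linear support-vector regression
#'
#' For each fold, features are standardized with training-fold statistics
#' only (zero-variance features are zeroed out, so all-constant features
#' never influence predictions), the target age is standardized the same way,
#' a linear-kernel epsilon-insensitive SVR is trained on the training
#' partition, and held-out samples are predicted. Metrics are computed over
#' the pooled out-of-fold predictions.
#'
#' @param features probes/genes x samples matrix (a [methyl_matrix] or plain
#'   numeric matrix); samples in columns.
#' @param ages numeric vector (optionally named by sample), or a sample sheet.
#' @param scheme `"loo"` or `"kfold"`.
#' @param k number of folds for `scheme = "kfold"`.
#' @param cost,epsilon SVR hyperparameters (epsilon applies to the
#'   standardized target); defaults `C = 1`, `epsilon = 0.1`.
#' @param seed seed for the (age-tertile-stratified) k-fold partition.
#' @param folds optional integer vector of fold assignments, overriding
#'   `scheme`; useful for leakage checks with a fixed partition.
#' @return object of class `age_prediction`: `predictions` (data frame with
#'   `sample_id`, `age`, `predicted_age`, `fold`), `metrics` (Pearson and
#'   Spearman correlation, MAE in years, R-squared, slope of predicted on
#'   chronological age) and `n_models`.
#' @export
cv_age_prediction <- function(features, ages, scheme = c("loo", "kfold"),
                              k = 10, cost = 1, epsilon = 0.1, seed = 1,
                              folds = NULL) {
  scheme <- match.arg(scheme)
  x <- t(as_feature_matrix(features))
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples")
  y <- ages_from(ages, rownames(x))
  if (stats::sd(y) == 0) stop("ages are constant; nothing to predict")

  if (is.null(folds)) {
    folds <- if (scheme == "loo") seq_len(n) else {
      if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
      stratified_folds(y, k, seed)
    }
  } else {
    if (length(folds) != n) stop("folds must assign every sample")
    folds <- as.integer(folds)
  }

  pred <- rep(NA_real_, n)
  n_models <- 0L
  for (f in sort(unique(folds))) {
    test <- folds == f
    model <- svr_train(x[!test, , drop = FALSE], y[!test], cost, epsilon)
    pred[test] <- svr_predict(model, x[test, , drop = FALSE])
    n_models <- n_models + 1L
  }

  structure(list(
    predictions = data.frame(sample_id = rownames(x), age = y,
                             predicted_age = pred, fold = folds,
                             stringsAsFactors = FALSE),
    metrics = prediction_metrics(y, pred),
    n_models = n_models, scheme = scheme,
    params = list(cost = cost, epsilon = epsilon)),
    class = "age_prediction")
}

#' @export
print.age_prediction <- function(x, ...) {
  m <- x$metrics
  cat("<age_prediction> ", nrow(x$predictions), " samples, scheme=", x$scheme,
      " (", x$n_models, " models)\n", sep = "")
  cat(sprintf("  Pearson r = %.3f, Spearman rho = %.3f, MAE = %.2f years\n",
              m$pearson, m$spearman, m$mae))
  cat(sprintf("  R^2 = %.3f, slope(predicted ~ age) = %.3f\n", m$r_squared, m$slope))
  invisible(x)
}

prediction_metrics <- function(age, pred) {
  list(pearson = stats::cor(age, pred),
       spearman = stats::cor(age, pred, method = "spearman"),
       mae = mean(abs(age - pred)),
       r_squared = stats::cor(age, pred)^2,
       slope = unname(stats::coef(stats::lm(pred ~ age))[2]))
}

as_feature_matrix <- function(features) {
  if (inherits(features, "methyl_matrix")) return(unclass(features))
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("features must be a numeric matrix (features x samples)")
  }
  if (anyNA(features)) stop("missing values in feature matrix")
  features
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  tert <- cut(rank(y, ties.method = "first"), breaks = 3, labels = FALSE)
  folds <- integer(length(y))
  for (t in unique(tert)) {
    idx <- which(tert == t)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

svr_train <- function(x_train, y_train, cost, epsilon) {
  center <- colMeans(x_train)
  scale <- apply(x_train, 2, stats::sd)
  scale[scale == 0] <- Inf  # zero-variance features contribute nothing
  xs <- sweep(sweep(x_train, 2, center), 2, scale, `/`)
  y_center <- mean(y_train)
  y_scale <- stats::sd(y_train)
  if (y_scale == 0) y_scale <- 1
  ys <- (y_train - y_center) / y_scale
  fit <- e1071::svm(x = xs, y = ys, type = "eps-regression",
                    kernel = "linear", cost = cost, epsilon = epsilon,
                    scale = FALSE)
  # collapse to an explicit linear model: w = t(coefs) %*% SV
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  list(w = w, b = b, center = center, scale = scale,
       y_center = y_center, y_scale = y_scale,
       feature_ids = colnames(x_train))
}

svr_predict <- function(model, x_new) {
  xs <- sweep(sweep(x_new, 2, model$center), 2, model$scale, `/`)
  as.numeric(xs %*% model$w + model$b) * model$y_scale + model$y_center
}

#' Train an age predictor on a full cohort
#'
#' Same standardization and linear SVR as [cv_age_prediction()], trained once
#' on all samples; the result can be applied to an external cohort with
#' [predict_age()] and serialized with [write_age_model()].
#'
#' @inheritParams cv_age_prediction
#' @return object of class `age_model`.
#' @export
train_age_model <- function(features, ages, cost = 1, epsilon = 0.1) {
  x <- t(as_feature_matrix(features))
  y <- ages_from(ages, rownames(x))
  model <- svr_train(x, y, cost, epsilon)
  structure(model, class = "age_model")
}

#' Predict ages with a trained model
#' @param model an `age_model`.
#' @param features features x samples matrix with the training features.
#' @return named numeric vector of predicted ages.
#' @export
predict_age <- function(model, features) {
  x <- t(as_feature_matrix(features))
  miss <- setdiff(model$feature_ids, colnames(x))
  if (length(miss)) stop("features missing from new data: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  x <- x[, model$feature_ids, drop = FALSE]
  stats::setNames(svr_predict(model, x), rownames(x))
}

#' Serialize an age model to JSON
#' @param model an `age_model`.
#' @param path output path.
#' @export
write_age_model <- function(model, path) {
  jsonlite::write_json(list(
    feature_ids = model$feature_ids, weights = model$w, intercept = model$b,
    center = model$center, scale = model$scale,
    y_center = model$y_center, y_scale = model$y_scale),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized age model
#' @param path JSON path written by [write_age_model()].
#' @return an `age_model`.
#' @export
read_age_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = j$weights, b = j$intercept, center = j$center,
                 scale = j$scale, y_center = j$y_center, y_scale = j$y_scale,
                 feature_ids = j$feature_ids),
            class = "age_model")
}

#' Matched-n subsampling comparison of methylation vs expression predictors
#'
#' Repeatedly draws `n_sub` methylation samples without replacement, runs
#' [cv_age_prediction()] on the subset, and compares against a single run on
#' the full expression matrix, mirroring a matched-sample-size comparison of
#' the two platforms.
#'
#' @param meth methylation features x samples matrix.
#' @param expr expression genes x samples matrix.
#' @param ages sample sheet (or named age vector) covering both matrices.
#' @param n_sub subsample size (<= methylation samples).
#' @param reps number of subsampling repetitions (>= 1).
#' @param scheme CV scheme passed through.
#' @param seed master seed; each repetition gets a derived seed.
#' @param ... further arguments to [cv_age_prediction()].
#' @return list with `methylation` (per-rep metric data frame), `expression`
#'   (metrics of the single expression run) and `summary` (medians of the
#'   methylation metrics).
#' @export
subsample_comparison <- function(meth, expr, ages, n_sub, reps = 10,
                                 scheme = "loo", seed = 1, ...) {
  if (reps < 1) stop("reps must be >= 1")
  meth <- as_feature_matrix(if (inherits(meth, "methyl_matrix")) unclass(meth) else meth)
  if (n_sub > ncol(meth)) stop("n_sub exceeds available methylation samples")

  expr_fit <- cv_age_prediction(expr, ages, scheme = scheme,
                                seed = child_seed(seed, 0), ...)

  per_rep <- do.call(rbind, lapply(seq_len(reps), function(r) {
    set.seed(child_seed(seed, r))
    cols <- sort(sample(ncol(meth), n_sub))
    fit <- cv_age_prediction(meth[, cols, drop = FALSE], ages,
                             scheme = scheme, seed = child_seed(seed, r), ...)
    data.frame(rep = r, n = n_sub, pearson = fit$metrics$pearson,
               spearman = fit$metrics$spearman, mae = fit$metrics$mae)
  }))

  list(methylation = per_rep,
       expression = data.frame(n = ncol(as_feature_matrix(expr)),
                               pearson = expr_fit$metrics$pearson,
                               spearman = expr_fit$metrics$spearman,
                               mae = expr_fit$metrics$mae),
       summary = data.frame(median_pearson = stats::median(per_rep$pearson),
                            median_mae = stats::median(per_rep$mae)))
}
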