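#' Regression model specification
#'
#' Declares which learner maps selected-band reflectance to SPAD and its
#' hyperparameters. Four methods are supported: PLSR (latent-variable
#' linear regression, the chemometrics baseline) and three tree ensembles
#' (XGBoost, random forest regression, gradient-boosted decision trees).
#'
#' @param method one of `"plsr"`, `"xgboost"`, `"rfr"`, `"gbdt"`.
#' @param n_components PLSR latent components; `NULL` (default) chooses by
#'   inner 5-fold CV up to 10.
#' @param n_trees ensemble size (default 500).
#' @param depth tree depth (default 3).
#' @param learning_rate shrinkage for the boosting methods (default 0.1).
#' @param seed integer seed controlling any fitting randomness.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(method = c("plsr", "xgboost", "rfr", "gbdt"),
                       n_components = NULL, n_trees = 500L, depth = 3L,
                       learning_rate = 0.1, seed = 1L) {
  method <- match.arg(method)
  if (!is.null(n_components) && n_components < 1)
    stop("n_components must be >= 1")
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (depth < 1) stop("depth must be >= 1")
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must be in (0, 1]")
  structure(list(method = method, n_components = n_components,
                 n_trees = as.integer(n_trees), depth = as.integer(depth),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit a SPAD regression model on selected bands
#'
#' Restricts the dataset to the selected bands and fits the learner named
#' in the spec. The fitted object records its band subset and wavelengths,
#' so pixel-wise prediction can assemble matching spectra. Fits are
#' deterministic under the spec seed (tree learners run single threaded).
#'
#' @param ds a [spectral_dataset()].
#' @param spec a [model_spec()].
#' @param bands 1-based band indices to use, or a [selection_result()];
#'   default: all bands.
#' @return An object of class `spad_model`.
#' @export
fit_model <- function(ds, spec, bands = NULL) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(spec, "model_spec"))
  if (inherits(bands, "selection_result")) bands <- bands$indices
  if (is.null(bands)) bands <- seq_len(ncol(ds$X))
  bands <- as.integer(bands)
  if (!length(bands)) stop("selected band set is empty")
  if (any(bands < 1) || any(bands > ncol(ds$X)))
    stop("band indices out of range")
  X <- ds$X[, bands, drop = FALSE]
  y <- ds$y
  fit <- fit_learner(X, y, spec)
  structure(list(method = spec$method, spec = spec, bands = bands,
                 wavelengths = ds$wavelengths[bands], fit = fit),
            class = "spad_model")
}

fit_learner <- function(X, y, spec) {
  switch(spec$method,
    plsr = {
      if (nrow(X) <= 2)
        stop("PLSR needs more training samples than latent components")
      fit_pls(X, y, ncomp = spec$n_components, max_ncomp = 10,
              inner_folds = 5, seed = spec$seed)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(max_depth = spec$depth, eta = spec$learning_rate,
                      objective = "reg:squarederror", nthread = 1,
                      seed = spec$seed),
        data = dtrain, nrounds = spec$n_trees, verbose = 0)
    },
    rfr = {
      set.seed(spec$seed)
      randomForest::randomForest(x = X, y = y, ntree = spec$n_trees)
    },
    gbdt = fit_gbdt(X, y, spec)
  )
}

# Least-squares gradient boosting over rpart regression trees: start from
# the mean, repeatedly fit a depth-limited tree to the residuals and add a
# shrunken copy. Deterministic: rpart has no sampling.
fit_gbdt <- function(X, y, spec) {
  df <- as.data.frame(X)
  names(df) <- paste0("b", seq_len(ncol(X)))
  f0 <- mean(y)
  pred <- rep(f0, length(y))
  trees <- vector("list", spec$n_trees)
  ctrl <- rpart::rpart.control(maxdepth = spec$depth, cp = 0,
                               minsplit = 10, minbucket = 5, xval = 0)
  for (m in seq_len(spec$n_trees)) {
    df$..r <- y - pred
    tr <- rpart::rpart(..r ~ ., data = df, method = "anova", control = ctrl)
    step <- predict(tr, df)
    if (all(step == step[1]) && m > 1) {  # residuals exhausted
      trees <- trees[seq_len(m - 1)]
      break
    }
    pred <- pred + spec$learning_rate * step
    trees[[m]] <- tr
  }
  structure(list(f0 = f0, trees = trees,
                 learning_rate = spec$learning_rate),
            class = "gbdt_model")
}

#' @export
predict.gbdt_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  names(df) <- paste0("b", seq_len(ncol(df)))
  pred <- rep(object$f0, nrow(df))
  for (tr in object$trees)
    pred <- pred + object$learning_rate * predict(tr, df)
  pred
}

#' Predict SPAD from selected-band spectra
#'
#' @param object a [fit_model()] result.
#' @param newdata matrix whose columns are the model's selected bands (in
#'   the model's band order), or a [spectral_dataset()] on the same grid
#'   (restricted internally).
#' @param ... unused.
#' @return Numeric vector of predicted SPAD values.
#' @export
predict.spad_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectral_dataset"))
    newdata <- newdata$X[, object$bands, drop = FALSE]
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$bands))
    stop("newdata must have one column per selected band (",
         length(object$bands), ")")
  switch(object$method,
    plsr = predict(object$fit, newdata),
    xgboost = predict(object$fit,
                      xgboost::xgb.DMatrix(newdata, nthread = 1)),
    rfr = as.numeric(predict(object$fit, newdata)),
    gbdt = predict(object$fit, newdata)
  )
}

#' Regression accuracy metrics
#'
#' The three cross-validation metrics: the determination coefficient as the
#' squared Pearson correlation between measured and predicted values (note:
#' this is not `1 - SSres/SStot`; the two differ for biased predictors),
#' the root mean square error, and the mean absolute error.
#'
#' @param y measured values.
#' @param yhat predicted values, same length.
#' @return Named list with `R2` (NA when y or yhat is constant), `RMSE`
#'   and `MAE`.
#' @export
metrics <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0)
    stop("y and yhat must have equal nonzero length")
  r2 <- if (sd(y) == 0 || sd(yhat) == 0) NA_real_ else cor(y, yhat)^2
  list(R2 = r2,
       RMSE = sqrt(mean((y - yhat)^2)),
       MAE = mean(abs(y - yhat)))
}

#' k-fold cross-validated model evaluation
#'
#' Randomly partitions the samples into k near-equal folds (stratified by
#' leaf-position label when available), fits the model on each training
#' split, predicts the held-out fold, and reports per-fold and aggregate
#' metrics. The reported aggregate is the unweighted mean of the per-fold
#' metrics; a pooled computation over all out-of-fold predictions is also
#' stored (the two differ slightly for unbalanced folds).
#'
#' @param ds a [spectral_dataset()].
#' @param bands band indices or a [selection_result()]; default all bands.
#' @param spec a [model_spec()].
#' @param k number of folds (default 10). Every fold must hold at least 2
#'   samples, since a per-fold correlation needs them; `k = n` is rejected.
#' @param seed seed for the fold assignment.
#' @return Object of class `cv_report`: `k`, `per_fold` (data frame),
#'   `aggregate` (mean-of-folds `R2`, `RMSE`, `MAE`), `pooled`, and
#'   `predictions` (id, y, yhat, fold).
#' @export
cross_validate <- function(ds, bands = NULL, spec = model_spec(), k = 10,
                           seed = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- nrow(ds$X)
  if (n < k) stop("need at least k samples")
  strata <- if (all(is.na(ds$position_labels))) NULL else ds$position_labels
  folds <- make_folds(n, k, seed = seed, strata = strata)
  if (min(table(folds)) < 2)
    stop("every fold needs at least 2 samples; lower k")
  yhat <- rep(NA_real_, n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    ds_train <- spectral_dataset(ds$X[train, , drop = FALSE], ds$y[train],
                                 ds$wavelengths,
                                 sample_ids = ds$sample_ids[train],
                                 position_labels = ds$position_labels[train])
    m <- fit_model(ds_train, spec, bands = bands)
    pred <- predict(m, ds$X[test, m$bands, drop = FALSE])
    yhat[test] <- pred
    mt <- metrics(ds$y[test], pred)
    per_fold[[f]] <- data.frame(fold = f, R2 = mt$R2, RMSE = mt$RMSE,
                                MAE = mt$MAE)
  }
  per_fold <- do.call(rbind, per_fold)
  aggregate <- list(R2 = mean(per_fold$R2), RMSE = mean(per_fold$RMSE),
                    MAE = mean(per_fold$MAE))
  pooled <- metrics(ds$y, yhat)
  structure(list(k = k, per_fold = per_fold, aggregate = aggregate,
                 pooled = pooled,
                 predictions = data.frame(id = ds$sample_ids, y = ds$y,
                                          yhat = yhat, fold = folds),
                 method = spec$method),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report:%s> %d-fold CV\n", x$method, x$k))
  cat(sprintf("  Rcv2 = %.3f, RMSEcv = %.3f, MAEcv = %.3f (mean of folds)\n",
              x$aggregate$R2, x$aggregate$RMSE, x$aggregate$MAE))
  cat(sprintf("  pooled: R2 = %.3f, RMSE = %.3f, MAE = %.3f\n",
              x$pooled$R2, x$pooled$RMSE, x$pooled$MAE))
  invisible(x)
}

#' Write a CV report (and its out-of-fold predictions) to CSV
#'
#' @param report a [cross_validate()] result.
#' @param path CSV path for the per-fold and aggregate metrics.
#' @param predictions_path optional CSV path for out-of-fold predictions.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(report, path, predictions_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  df <- rbind(report$per_fold,
              data.frame(fold = NA, R2 = report$aggregate$R2,
                         RMSE = report$aggregate$RMSE,
                         MAE = report$aggregate$MAE))
  write.csv(df, path, row.names = FALSE)
  if (!is.null(predictions_path))
    write.csv(report$predictions, predictions_path, row.names = FALSE)
  invisible(path)
}
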