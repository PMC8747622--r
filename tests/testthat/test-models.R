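test_that("metrics handle exact and offset predictions", {
  m <- metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$RMSE, 0)
  expect_equal(m$MAE, 0)
  expect_equal(m$R2, 1)
  m2 <- metrics(c(0, 0), c(1, 1))
  expect_equal(m2$RMSE, 1)
  expect_equal(m2$MAE, 1)
  expect_true(is.na(m2$R2))  # constant vectors: correlation undefined
  expect_error(metrics(1:3, 1:4), "equal")
})

test_that("metrics agree with an independently coded implementation", {
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(100, 55, 7)
    yhat <- y + rnorm(100, sd = 2)
    m <- metrics(y, yhat)
    # textbook forms, written out directly
    r2_oracle <- (sum((y - mean(y)) * (yhat - mean(yhat))) /
                    sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2)))^2
    rmse_oracle <- sqrt(sum((y - yhat)^2) / 100)
    mae_oracle <- sum(abs(y - yhat)) / 100
    expect_equal(m$R2, r2_oracle, tolerance = 1e-12)
    expect_equal(m$RMSE, rmse_oracle, tolerance = 1e-12)
    expect_equal(m$MAE, mae_oracle, tolerance = 1e-12)
  }
})

test_that("PLSR with one component fits an exactly linear single-band relation", {
  set.seed(5)
  x <- runif(40, 0.1, 0.6)
  y <- 20 + 60 * x
  ds <- spectral_dataset(cbind(x, runif(40)), y, c(550, 800))
  m <- fit_model(ds, model_spec("plsr", n_components = 1), bands = 1L)
  resid <- y - predict(m, cbind(x))
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("the compiled PLS kernel matches an independent NIPALS implementation and mixOmics", {
  set.seed(6)
  X <- matrix(rnorm(60 * 12), 60)
  y <- drop(X[, 1:3] %*% c(2, -1, 0.5)) + rnorm(60, sd = 0.3)
  for (nc in c(1, 3, 5)) {
    f <- fit_pls(X, y, ncomp = nc)
    o <- oracle_pls1(X, y, nc)
    expect_equal(f$coef, o$coef, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
  }
  colnames(X) <- paste0("b", 1:12)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  pred_mo <- predict(mo, X)$predict[, 1, 3]
  f3 <- fit_pls(X, y, ncomp = 3)
  expect_equal(unname(pred_mo), drop(X %*% f3$coef) + f3$intercept,
               tolerance = 1e-8)
})

test_that("every learner is deterministic under its seed", {
  ds <- tiny_dataset(n = 60, p = 15, seed = 7)
  for (method in c("plsr", "xgboost", "rfr", "gbdt")) {
    spec <- model_spec(method, n_trees = 40, seed = 11)
    m1 <- fit_model(ds, spec)
    m2 <- fit_model(ds, spec)
    expect_equal(predict(m1, ds$X), predict(m2, ds$X), tolerance = 1e-12,
                 info = method)
  }
})

test_that("MAE never exceeds RMSE in any CV report", {
  ds <- tiny_dataset(n = 60, p = 15, noise_sd = 0.01, seed = 8)
  rep <- cross_validate(ds, spec = model_spec("plsr"), k = 5, seed = 8)
  expect_true(all(rep$per_fold$MAE <= rep$per_fold$RMSE + 1e-12))
  expect_lte(rep$aggregate$MAE, rep$aggregate$RMSE)
  expect_lte(rep$pooled$MAE, rep$pooled$RMSE)
})

test_that("noiseless linear data cross-validates to R2 of one", {
  set.seed(9)
  X <- matrix(runif(60 * 5, 0.1, 0.6), 60)
  y <- 10 + drop(X %*% c(30, -20, 10, 5, -5))
  ds <- spectral_dataset(X, y, seq(500, 900, length.out = 5))
  rep <- cross_validate(ds, spec = model_spec("plsr", n_components = 5),
                        k = 5, seed = 9)
  expect_equal(rep$aggregate$R2, 1, tolerance = 1e-9)
  expect_lt(rep$aggregate$RMSE, 1e-6)
})

test_that("shuffled-label null data gives near-zero cross-validated R2", {
  r2 <- vapply(1:10, function(s) {
    ds <- generate_dataset(sim_config(n_samples = 300, n_bands = 20,
                                      noise_sd = 0.01, seed = 700 + s))
    set.seed(800 + s)
    ds_null <- spectral_dataset(ds$X, sample(ds$y), ds$wavelengths,
                                position_labels = ds$position_labels)
    cross_validate(ds_null, spec = model_spec("plsr"), k = 5,
                   seed = 900 + s)$aggregate$R2
  }, numeric(1))
  expect_lt(mean(r2), 0.15)
})

test_that("degenerate fold requests are rejected", {
  ds <- tiny_dataset(n = 20, p = 6, seed = 10)
  expect_error(cross_validate(ds, spec = model_spec("plsr"), k = 20),
               "at least 2 samples")
  expect_error(cross_validate(ds, spec = model_spec("plsr"), k = 25),
               "at least k samples")
  expect_error(fit_model(ds, model_spec("plsr"), bands = integer(0)), "empty")
})

test_that("tree ensembles beat PLSR on a quadratic band-SPAD link", {
  set.seed(12)
  n <- 300
  x <- runif(n, -1, 1)
  X <- cbind(x, matrix(runif(n * 4, -1, 1), n))
  y <- 55 + 10 * x^2 + rnorm(n, sd = 0.5)  # purely nonlinear in band 1
  ds <- spectral_dataset(X, y, seq(500, 900, length.out = 5))
  rep_pls <- cross_validate(ds, spec = model_spec("plsr"), k = 5, seed = 12)
  rep_xgb <- cross_validate(ds, spec = model_spec("xgboost", n_trees = 300),
                            k = 5, seed = 12)
  expect_lt(rep_xgb$aggregate$RMSE, rep_pls$aggregate$RMSE)
})

test_that("CV reports write to CSV with aggregate row and predictions", {
  ds <- tiny_dataset(n = 30, p = 8, seed = 13)
  rep <- cross_validate(ds, spec = model_spec("plsr"), k = 5, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  pred_path <- withr::local_tempfile(fileext = ".csv")
  write_cv_csv(rep, path, pred_path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 6)  # 5 folds + aggregate
  expect_equal(tab$RMSE[6], rep$aggregate$RMSE)
  preds <- read.csv(pred_path)
  expect_equal(nrow(preds), 30)
  expect_false(anyNA(preds$yhat))
})
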