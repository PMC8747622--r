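#' Seeded k-fold assignment
#'
#' Random partition of `n` samples into `k` near-equal folds, optionally
#' stratified so each fold sees every stratum (leaf tier) in proportion.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param strata optional length-n grouping vector for stratified folds.
#' @return Integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(n, k, seed = NULL, strata = NULL) {
  if (k < 2 || k > n) stop("k must be in [2, n]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(strata)) strata <- rep(1L, n)
  # shuffle within stratum, then deal fold labels round-robin across the
  # concatenated order so folds stay balanced per stratum AND overall
  ord <- unlist(lapply(unique(strata), function(g) {
    idx <- which(strata == g)
    idx[sample.int(length(idx))]
  }), use.names = FALSE)
  ids <- integer(n)
  ids[ord] <- rep_len(seq_len(k), n)
  ids
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares with a single response. If `ncomp` is
#' `NULL`, the component count is chosen by inner cross-validation: the
#' per-component RMSECV path is computed in one CV pass (NIPALS models are
#' nested) and the minimum taken, capped at `max_ncomp`.
#'
#' @param X n x p predictor matrix.
#' @param y length-n response.
#' @param ncomp fixed number of latent components, or `NULL` to choose by
#'   inner CV.
#' @param max_ncomp cap on the component count (default 10).
#' @param inner_folds folds of the inner CV (default 5).
#' @param seed seed for the inner fold assignment.
#' @return Object of class `pls_model` with `coef` (length-p), `intercept`,
#'   `ncomp` and the inner RMSECV path (if computed).
#' @export
fit_pls <- function(X, y, ncomp = NULL, max_ncomp = 10, inner_folds = 5,
                    seed = 1L) {
  X <- as.matrix(X)
  cap <- max(1L, min(max_ncomp, ncol(X), nrow(X) - 2L))
  path <- NULL
  if (is.null(ncomp)) {
    folds <- make_folds(nrow(X), min(inner_folds, nrow(X)), seed = seed)
    path <- as.numeric(cpp_cv_rmse_path(X, y, cap, as.integer(folds)))
    ncomp <- which.min(path)
  }
  ncomp <- max(1L, min(as.integer(ncomp), cap))
  f <- cpp_pls_fit(X, y, ncomp)
  structure(list(coef = as.numeric(f$coef[, ncomp]),
                 intercept = as.numeric(f$intercept[ncomp]),
                 ncomp = ncomp, rmsecv_path = path),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coef) + object$intercept
}

#' Cross-validated RMSE of a PLS model on a band subset
#'
#' Pooled RMSECV (square root of the mean squared out-of-fold error over
#' all samples) of a PLS model restricted to the given bands, at the best
#' component count up to `max_ncomp`.
#'
#' @param X n x p predictor matrix.
#' @param y length-n response.
#' @param bands 1-based column indices (default: all).
#' @param max_ncomp component cap.
#' @param fold_ids integer fold labels from [make_folds()].
#' @return The minimal RMSECV over component counts.
#' @export
pls_rmsecv <- function(X, y, bands = seq_len(ncol(X)), max_ncomp = 10,
                       fold_ids) {
  Xs <- as.matrix(X)[, bands, drop = FALSE]
  cap <- max(1L, min(max_ncomp, ncol(Xs), nrow(Xs) - 2L))
  min(as.numeric(cpp_cv_rmse_path(Xs, y, cap, as.integer(fold_ids))))
}
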