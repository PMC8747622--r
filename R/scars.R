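#' sCARS configuration
#'
#' Settings for stability competitive adaptive reweighted sampling: the
#' number of Monte-Carlo runs, the fraction of samples drawn per run, the
#' PLS component cap, the CV folds used to score each run's retained
#' subset, and the band-weighting rule.
#'
#' @param n_runs Monte-Carlo sampling runs (default 500).
#' @param sample_ratio fraction of samples drawn (without replacement) per
#'   run (default 0.8).
#' @param max_pls_components cap on PLS latent components (default 10);
#'   the count used in each fit is chosen by inner 5-fold CV up to the cap.
#' @param cv_folds folds for the per-run RMSECV scoring (default 10).
#' @param n_bootstrap within-run bootstrap refits used for the stability
#'   weight (default 20).
#' @param weight one of `"stability"` (|mean coefficient| / SD over the
#'   bootstrap refits; the sCARS weighting) or `"coef"` (absolute
#'   coefficient of a single fit; classic CARS).
#' @param seed integer seed.
#' @return An object of class `scars_config`.
#' @export
scars_config <- function(n_runs = 500L, sample_ratio = 0.8,
                         max_pls_components = 10L, cv_folds = 10L,
                         n_bootstrap = 20L,
                         weight = c("stability", "coef"), seed = 1L) {
  weight <- match.arg(weight)
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (sample_ratio <= 0 || sample_ratio >= 1)
    stop("sample_ratio must be in (0, 1)")
  if (n_bootstrap < 2) stop("n_bootstrap must be >= 2")
  structure(list(n_runs = as.integer(n_runs), sample_ratio = sample_ratio,
                 max_pls_components = as.integer(max_pls_components),
                 cv_folds = as.integer(cv_folds),
                 n_bootstrap = as.integer(n_bootstrap),
                 weight = weight, seed = as.integer(seed)),
            class = "scars_config")
}

#' Exponential decrease function ratio
#'
#' Fraction of the full band set enforced at Monte-Carlo run `i` of `N`:
#' `r_i = a * exp(-k * i)` with `a`, `k` fixed by the boundary conditions
#' `r_1 = 1` (all `p` bands kept at the first run) and `r_N = 2/p` (two
#' bands kept at the last).
#'
#' @param i run index (1-based), possibly a vector.
#' @param n_runs total number of runs `N`.
#' @param n_bands number of bands `p` (must be >= 2).
#' @return The retention fraction(s) `r_i`.
#' @export
edf_ratio <- function(i, n_runs, n_bands) {
  if (n_bands < 2) stop("n_bands must be >= 2")
  if (any(i < 1) || any(i > n_runs)) stop("run index out of [1, n_runs]")
  k <- log(n_bands / 2) / (n_runs - 1)
  a <- exp(k)
  a * exp(-k * i)
}

#' Run sCARS wavelength selection
#'
#' Competitive adaptive reweighted sampling with stability weighting. Each
#' Monte-Carlo run draws a fixed fraction of samples, fits PLS on the
#' currently retained bands, and weighs each band by the stability of its
#' regression coefficient (mean magnitude / SD over within-run bootstrap
#' refits). Bands are then culled in two steps: enforced selection keeps
#' the top `ceil(r_i * p)` bands by weight (exponential decrease schedule),
#' and adaptive reweighted sampling draws that many bands with replacement,
#' with probability proportional to weight, keeping the distinct draws
#' (floored at 2 bands, the PLS minimum). Every run's retained subset is
#' scored by k-fold RMSECV on the full sample set; the selection is the
#' subset of the run with the smallest RMSECV.
#'
#' Weight ties are broken toward the lower band index. Runs whose retained
#' subset has zero variance are recorded as failed and excluded from the
#' minimum.
#'
#' @param ds a [spectral_dataset()].
#' @param cfg a [scars_config()].
#' @return A [selection_result()] (method `"scars"`) whose `diagnostics`
#'   hold the trace: `retained_counts`, `rmsecv_path`, `best_run`,
#'   `subsets` and per-run mean coefficients (`coef_paths`).
#' @export
run_scars <- function(ds, cfg = scars_config()) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(cfg, "scars_config"))
  X <- ds$X
  y <- ds$y
  n <- nrow(X)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 bands")
  if (n < cfg$cv_folds) stop("need at least cv_folds samples")
  set.seed(cfg$seed)
  score_folds <- make_folds(n, cfg$cv_folds, seed = NULL)

  retained <- seq_len(p)
  n_runs <- cfg$n_runs
  retained_counts <- integer(n_runs)
  rmsecv_path <- rep(NA_real_, n_runs)
  subsets <- vector("list", n_runs)
  coef_paths <- vector("list", n_runs)
  n_sub <- max(cfg$cv_folds, round(cfg$sample_ratio * n))

  for (i in seq_len(n_runs)) {
    sub <- sample.int(n, n_sub)
    Xs <- X[sub, retained, drop = FALSE]
    ys <- y[sub]
    if (all(apply(Xs, 2, sd) == 0)) {
      retained_counts[i] <- length(retained)
      subsets[[i]] <- retained
      next  # failed run: zero-variance subset
    }
    # component count by inner 5-fold CV on this run's subsample
    cap <- max(1L, min(cfg$max_pls_components, length(retained), n_sub - 2L))
    inner <- make_folds(n_sub, min(5L, n_sub), seed = NULL)
    ncomp <- which.min(cpp_cv_rmse_path(Xs, ys, cap, as.integer(inner)))

    if (cfg$weight == "stability") {
      B <- cfg$n_bootstrap
      coefs <- matrix(0, length(retained), B)
      for (b in seq_len(B)) {
        bs <- sample.int(n_sub, n_sub, replace = TRUE)
        fb <- cpp_pls_fit(Xs[bs, , drop = FALSE], ys[bs], ncomp)
        coefs[, b] <- fb$coef[, ncomp]
      }
      cmean <- rowMeans(coefs)
      csd <- apply(coefs, 1, sd)
      w <- abs(cmean) / pmax(csd, 1e-12)
      coef_run <- cmean
    } else {
      f1 <- cpp_pls_fit(Xs, ys, ncomp)
      coef_run <- as.numeric(f1$coef[, ncomp])
      w <- abs(coef_run)
    }
    if (all(w == 0)) w <- rep(1, length(w))

    m <- max(2L, min(ceiling(edf_ratio(i, n_runs, p) * p), length(retained)))
    # enforced selection: top m by weight, ties toward the lower band index
    ord <- order(-w, retained)
    enforced_local <- sort(ord[seq_len(m)])
    # adaptive reweighted sampling: m weighted draws with replacement
    probs <- w[enforced_local]
    if (sum(probs) == 0) probs <- rep(1, length(probs))
    draws <- unique(sample(enforced_local, m, replace = TRUE,
                           prob = probs / sum(probs)))
    if (length(draws) < 2) {
      extra <- setdiff(enforced_local[order(-w[enforced_local])], draws)
      draws <- c(draws, extra[seq_len(2 - length(draws))])
    }
    new_retained <- sort(retained[draws])
    names(coef_run) <- as.character(retained)
    retained <- new_retained

    retained_counts[i] <- length(retained)
    subsets[[i]] <- retained
    coef_paths[[i]] <- coef_run
    rmsecv_path[i] <- pls_rmsecv(X, y, retained, cfg$max_pls_components,
                                 score_folds)
  }

  if (all(is.na(rmsecv_path))) stop("all sCARS runs failed")
  best_run <- which.min(rmsecv_path)
  sel <- subsets[[best_run]]
  selection_result("scars", sel, ds$wavelengths[sel], n_bands_total = p,
                   diagnostics = list(retained_counts = retained_counts,
                                      rmsecv_path = rmsecv_path,
                                      best_run = best_run,
                                      subsets = subsets,
                                      coef_paths = coef_paths,
                                      score_folds = score_folds,
                                      config = cfg))
}

#' Write an sCARS trace to CSV
#'
#' One row per Monte-Carlo run: run index, retained band count, RMSECV.
#'
#' @param sel the [selection_result()] returned by [run_scars()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scars_trace_csv <- function(sel, path) {
  d <- sel$diagnostics
  write.csv(data.frame(run = seq_along(d$retained_counts),
                       retained = d$retained_counts,
                       rmsecv = d$rmsecv_path),
            path, row.names = FALSE)
  invisible(path)
}
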