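#' IRIV configuration
#'
#' Settings for iteratively retaining informative variables: the size of
#' the random binary inclusion design, the inclusion probability, the CV
#' folds of the inner PLS models, the PLS component cap, the Mann-Whitney
#' significance threshold, and a safety cap on rounds.
#'
#' @param n_rows rows of the binary inclusion matrix (default 500).
#' @param inclusion_prob probability a variable enters a design row
#'   (default 0.5).
#' @param cv_folds folds of the inner RMSECV (default 5).
#' @param max_pls_components PLS component cap; the count used is
#'   `min(max_pls_components, n_variables, n_train - 1)` per fit
#'   (default 5).
#' @param alpha Mann-Whitney significance threshold (default 0.05).
#' @param max_rounds safety cap on elimination rounds (default 50).
#' @param seed integer seed.
#' @return An object of class `iriv_config`.
#' @export
iriv_config <- function(n_rows = 500L, inclusion_prob = 0.5, cv_folds = 5L,
                        max_pls_components = 5L, alpha = 0.05,
                        max_rounds = 50L, seed = 1L) {
  if (n_rows < 10) stop("n_rows must be >= 10")
  if (inclusion_prob <= 0 || inclusion_prob >= 1)
    stop("inclusion_prob must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_rows = as.integer(n_rows),
                 inclusion_prob = inclusion_prob,
                 cv_folds = as.integer(cv_folds),
                 max_pls_components = as.integer(max_pls_components),
                 alpha = alpha, max_rounds = as.integer(max_rounds),
                 seed = as.integer(seed)),
            class = "iriv_config")
}

#' Random binary inclusion design
#'
#' `n_rows` x `p_active` matrix of independent Bernoulli(inclusion_prob)
#' entries; rows with fewer than 2 ones are redrawn (a PLS model needs at
#' least two predictors to say anything about variable interplay).
#' Reproducible under the seed.
#'
#' @param p_active number of active variables (columns).
#' @param cfg an [iriv_config()].
#' @param seed seed override (default: the config seed).
#' @return Integer 0/1 matrix.
#' @export
build_inclusion_matrix <- function(p_active, cfg, seed = cfg$seed) {
  if (p_active < 2) stop("p_active must be >= 2")
  set.seed(seed)
  A <- matrix(rbinom(cfg$n_rows * p_active, 1L, cfg$inclusion_prob),
              nrow = cfg$n_rows)
  bad <- which(rowSums(A) < 2)
  while (length(bad)) {
    A[bad, ] <- rbinom(length(bad) * p_active, 1L, cfg$inclusion_prob)
    bad <- which(rowSums(A) < 2)
  }
  A
}

#' Classify variables from (DMEAN, p) pairs
#'
#' The four-way rule: negative DMEAN with significant p is strongly
#' informative; negative DMEAN, non-significant p is weakly informative;
#' positive DMEAN splits the same way into interfering (significant) and
#' uninformative. Boundary cases (`DMEAN == 0` or `p == alpha` exactly)
#' fall to the weaker class on their side: weak when `DMEAN < 0`,
#' uninformative otherwise.
#'
#' @param dmean numeric vector of DMEAN values.
#' @param pvalue numeric vector of Mann-Whitney p-values.
#' @param alpha significance threshold (default 0.05).
#' @return Character vector over
#'   `c("strong", "weak", "uninformative", "interfering")`.
#' @export
classify_iriv <- function(dmean, pvalue, alpha = 0.05) {
  out <- character(length(dmean))
  neg <- dmean < 0
  sig <- pvalue < alpha
  out[neg & sig] <- "strong"
  out[neg & !sig] <- "weak"
  out[!neg & sig] <- "interfering"
  out[!neg & !sig] <- "uninformative"
  out[dmean == 0] <- "uninformative"
  out
}

#' One IRIV round
#'
#' Builds the binary inclusion design over the active variables, computes
#' every row's 5-fold RMSECV with the design as given (`RMSECV0`) and with
#' each variable's inclusion flipped (`RMSECVi`), forms the ratio
#' `phi = RMSECV0 / RMSECVi` separately over rows where the variable was
#' originally included (`phi0`) and excluded (`phii`), takes
#' `DMEAN_i = mean(phi0) - mean(phii)`, tests `phi0` against `phii` with a
#' two-sided Mann-Whitney U test (normal approximation, tie corrected),
#' and classifies each variable with [classify_iriv()]. An informative
#' variable inflates RMSECV when removed, so its `phi0` ratios sit below
#' its `phii` ratios and DMEAN comes out negative.
#'
#' If some variable is included (or excluded) in zero design rows the
#' classification is impossible; the design is rebuilt with an offset seed
#' (with a message) up to 10 times.
#'
#' @param X n x p reflectance matrix (full grid).
#' @param y length-n response.
#' @param variables active variable indices (columns of `X`), at least 2.
#' @param cfg an [iriv_config()].
#' @param seed seed for this round's design and folds.
#' @return List of class `iriv_round`: `variables`, `A`, `rmsecv0`,
#'   `dmean`, `pvalue`, `category`.
#' @export
iriv_round <- function(X, y, variables, cfg, seed = cfg$seed) {
  if (length(variables) < 2) stop("need at least 2 active variables")
  n <- nrow(X)
  if (n < cfg$cv_folds) stop("need at least cv_folds samples")
  p_active <- length(variables)

  A <- build_inclusion_matrix(p_active, cfg, seed = seed)
  tries <- 0
  while (any(colSums(A) == 0 | colSums(A) == nrow(A)) && tries < 10) {
    tries <- tries + 1
    message("inclusion design left a variable constant; rebuilding (try ",
            tries, ")")
    A <- build_inclusion_matrix(p_active, cfg, seed = seed + 1000L * tries)
  }
  if (any(colSums(A) == 0 | colSums(A) == nrow(A)))
    stop("could not build a usable inclusion design")

  folds <- make_folds(n, cfg$cv_folds, seed = seed)
  res <- cpp_iriv_rmsecv(X[, variables, drop = FALSE], y, A,
                         cfg$max_pls_components, as.integer(folds))
  rmsecv0 <- res[, 1]
  dmean <- numeric(p_active)
  pvalue <- numeric(p_active)
  for (i in seq_len(p_active)) {
    ratio <- rmsecv0 / res[, i + 1]
    phi0 <- ratio[A[, i] == 1]
    phii <- ratio[A[, i] == 0]
    dmean[i] <- mean(phi0) - mean(phii)
    pvalue[i] <- suppressWarnings(
      wilcox.test(phi0, phii, exact = FALSE)$p.value)
  }
  structure(list(variables = variables, A = A, rmsecv0 = rmsecv0,
                 dmean = dmean, pvalue = pvalue,
                 category = classify_iriv(dmean, pvalue, cfg$alpha)),
            class = "iriv_round")
}

#' Run IRIV wavelength selection
#'
#' Iterates [iriv_round()] over the active variable set, retaining only
#' strongly and weakly informative variables (negative DMEAN) each round,
#' until a round eliminates nothing, fewer than 3 variables remain, or
#' `max_rounds` is hit; the survivors then go through
#' [backward_eliminate()].
#'
#' @param ds a [spectral_dataset()].
#' @param cfg an [iriv_config()].
#' @return A [selection_result()] (method `"iriv"`) whose diagnostics hold
#'   the per-round history (`rounds`), the retained counts per round
#'   (`retained_after_rounds`) and the pre-backward-elimination survivor
#'   set.
#' @export
run_iriv <- function(ds, cfg = iriv_config()) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(cfg, "iriv_config"))
  X <- ds$X
  y <- ds$y
  variables <- seq_len(ncol(X))
  rounds <- list()
  retained_after <- integer(0)
  for (r in seq_len(cfg$max_rounds)) {
    rd <- iriv_round(X, y, variables, cfg, seed = cfg$seed + r)
    rounds[[r]] <- rd
    keep <- rd$variables[rd$category %in% c("strong", "weak")]
    if (length(keep) == 0)
      stop("all variables eliminated in round ", r)
    retained_after <- c(retained_after, length(keep))
    no_change <- length(keep) == length(variables)
    variables <- keep
    if (no_change || length(variables) < 3) break
  }
  survivors <- variables
  folds <- make_folds(nrow(X), cfg$cv_folds, seed = cfg$seed)
  final <- backward_eliminate(X, y, survivors, cfg, fold_ids = folds)
  selection_result("iriv", final, ds$wavelengths[final],
                   n_bands_total = ncol(X),
                   diagnostics = list(rounds = rounds,
                                      retained_after_rounds = retained_after,
                                      survivors = survivors,
                                      config = cfg))
}

#' Backward elimination of retained variables
#'
#' Greedy final pruning: with `t` variables, compute the 5-fold RMSECV of
#' the full set (`theta_t`) and of every leave-one-variable-out subset
#' (`theta_{-i}`); while `min(theta_{-i}) <= theta_t`, drop the variable
#' whose removal gives the minimum (ties toward the lower index) and
#' repeat. Stops when removing any variable would worsen the RMSECV, or a
#' single variable remains.
#'
#' @param X n x p reflectance matrix (full grid).
#' @param y length-n response.
#' @param variables indices of the retained variables.
#' @param cfg an [iriv_config()] (component cap, folds).
#' @param fold_ids optional fold labels; default: seeded 5-fold from the
#'   config seed.
#' @return Integer vector of surviving variable indices. The greedy path
#'   (per-step `theta_t`, candidate `theta_{-i}` and the variable dropped)
#'   is attached as attribute `"path"`.
#' @export
backward_eliminate <- function(X, y, variables, cfg = iriv_config(),
                               fold_ids = NULL) {
  if (length(variables) < 1) stop("need at least 1 variable")
  if (is.null(fold_ids))
    fold_ids <- make_folds(nrow(X), cfg$cv_folds, seed = cfg$seed)
  fold_ids <- as.integer(fold_ids)
  vars <- as.integer(variables)
  path <- list()
  step <- 0
  while (length(vars) > 1) {
    theta_t <- cpp_rmsecv_subset(X, y, vars - 1L, cfg$max_pls_components,
                                 fold_ids)
    theta_minus <- vapply(seq_along(vars), function(i)
      cpp_rmsecv_subset(X, y, vars[-i] - 1L, cfg$max_pls_components,
                        fold_ids), numeric(1))
    step <- step + 1
    if (min(theta_minus) > theta_t) {
      path[[step]] <- list(theta_t = theta_t, theta_minus = theta_minus,
                           dropped = NA_integer_)
      break
    }
    drop_i <- which.min(theta_minus)
    path[[step]] <- list(theta_t = theta_t, theta_minus = theta_minus,
                         dropped = vars[drop_i])
    vars <- vars[-drop_i]
  }
  attr(vars, "path") <- path
  vars
}

#' Write an IRIV round history to CSV
#'
#' One row per (round, variable): round index, variable index, wavelength,
#' DMEAN, p-value, category.
#'
#' @param sel the [selection_result()] returned by [run_iriv()].
#' @param wavelengths the full wavelength grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_iriv_history_csv <- function(sel, wavelengths, path) {
  d <- sel$diagnostics
  rows <- do.call(rbind, lapply(seq_along(d$rounds), function(r) {
    rd <- d$rounds[[r]]
    data.frame(round = r, variable = rd$variables,
               wavelength = wavelengths[rd$variables],
               dmean = rd$dmean, pvalue = rd$pvalue,
               category = rd$category)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
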