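# Independent oracles, coded straight from the textbook definitions and
# kept free of the package's compiled code paths.

# PLS1 via the NIPALS recursion, plain R. Returns the coefficient vector
# and intercept of the ncomp-component model.
oracle_pls1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X)
  ym <- mean(y)
  E <- sweep(X, 2, xm)
  f <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  used <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    if (sqrt(sum(w^2)) < 1e-12) break
    w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
    used <- a
  }
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  beta <- drop(W %*% solve(crossprod(P, W), q[seq_len(used)]))
  list(coef = beta, intercept = ym - sum(xm * beta))
}

# Pooled RMSECV of a column subset at a fixed component count, matching
# the contract of the compiled kernel but recomputed independently.
oracle_rmsecv <- function(X, y, cols, ncomp, fold_ids) {
  n <- length(y)
  sse <- 0
  for (f in sort(unique(fold_ids))) {
    test <- which(fold_ids == f)
    train <- which(fold_ids != f)
    if (length(cols) == 0) {
      sse <- sse + sum((y[test] - mean(y[train]))^2)
      next
    }
    Xtr <- X[train, cols, drop = FALSE]
    nc <- max(1, min(ncomp, length(cols), length(train) - 1))
    fit <- oracle_pls1(Xtr, y[train], nc)
    pred <- drop(X[test, cols, drop = FALSE] %*% fit$coef) + fit$intercept
    sse <- sse + sum((y[test] - pred)^2)
  }
  sqrt(sse / n)
}

# Small default dataset shared by several tests.
tiny_dataset <- function(n = 60, p = 30, noise_sd = 0.003, seed = 42,
                         corr = 0) {
  generate_dataset(sim_config(n_samples = n, n_bands = p,
                              noise_sd = noise_sd,
                              spectral_corr_length = corr, seed = seed))
}
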