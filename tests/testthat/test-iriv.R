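test_that("inclusion designs have balanced columns, >= 2 ones per row, and are seeded", {
  cfg <- iriv_config(n_rows = 500, seed = 42)
  A <- build_inclusion_matrix(50, cfg)
  expect_equal(dim(A), c(500L, 50L))
  expect_true(all(A %in% c(0L, 1L)))
  expect_true(all(rowSums(A) >= 2))
  # binomial concentration: column means within 3 * sqrt(0.25/500) of 0.5
  expect_true(all(abs(colMeans(A) - 0.5) < 3 * sqrt(0.25 / 500)))
  expect_identical(A, build_inclusion_matrix(50, cfg))
  expect_false(identical(A, build_inclusion_matrix(50, cfg, seed = 43)))
})

test_that("the four (DMEAN, p) rule combinations map to the right categories", {
  expect_equal(classify_iriv(-1, 0.01), "strong")
  expect_equal(classify_iriv(-1, 0.50), "weak")
  expect_equal(classify_iriv(1, 0.50), "uninformative")
  expect_equal(classify_iriv(1, 0.01), "interfering")
  # boundaries fall to the weaker class of their side
  expect_equal(classify_iriv(-1, 0.05), "weak")
  expect_equal(classify_iriv(1, 0.05), "uninformative")
  expect_equal(classify_iriv(0, 0.01), "uninformative")
  # exact partition over a grid
  grid <- expand.grid(d = c(-2, -0.1, 0, 0.1, 2), p = c(0.001, 0.049, 0.05, 0.6, 1))
  cats <- classify_iriv(grid$d, grid$p)
  expect_true(all(cats %in% c("strong", "weak", "uninformative", "interfering")))
  expect_true(all(nchar(cats) > 0))
})

test_that("an informative variable whose removal inflates RMSECV gets negative DMEAN", {
  set.seed(7)
  n <- 80
  x1 <- rnorm(n)
  X <- cbind(x1, rnorm(n), rnorm(n))
  y <- 50 + 8 * x1 + rnorm(n, sd = 0.1)
  rd <- iriv_round(X, y, 1:3, iriv_config(n_rows = 200, seed = 11), seed = 11)
  expect_lt(rd$dmean[1], 0)
  expect_lt(rd$pvalue[1], 0.05)
  expect_equal(rd$category[1], "strong")
})

test_that("a pure-noise variable appended to a linear system is flagged non-informative", {
  bad <- 0
  for (r in 1:10) {
    set.seed(500 + r)
    n <- 100  # large enough that spurious noise-response correlation is negligible
    Xs <- matrix(rnorm(3 * n), n)
    y <- 40 + 3 * Xs[, 1] - 2 * Xs[, 2] + 1.5 * Xs[, 3] + rnorm(n, sd = 1)
    X <- cbind(Xs, noise = rnorm(n))
    rd <- iriv_round(X, y, 1:4, iriv_config(n_rows = 300, seed = 600 + r),
                     seed = 600 + r)
    if (!rd$category[4] %in% c("uninformative", "interfering"))
      bad <- bad + 1
  }
  expect_lte(bad, 1)
})

test_that("retained counts never increase across rounds and null data terminates", {
  ds <- tiny_dataset(n = 50, p = 20, seed = 71)
  cfg <- iriv_config(n_rows = 100, max_rounds = 10, seed = 71)
  sel <- run_iriv(ds, cfg)
  counts <- sel$diagnostics$retained_after_rounds
  expect_true(all(diff(counts) <= 0))
  expect_lte(length(sel$diagnostics$rounds), cfg$max_rounds)
  expect_true(all(sel$indices %in% sel$diagnostics$survivors))

  # y unrelated to X: the algorithm must still terminate with a small set
  set.seed(72)
  null_ds <- spectral_dataset(matrix(runif(50 * 20), 50), rnorm(50, 55, 5),
                              seq(400, 900, length.out = 20))
  null_sel <- run_iriv(null_ds, iriv_config(n_rows = 100, max_rounds = 10,
                                            seed = 72))
  expect_lte(length(null_sel$indices), 20)
  expect_lte(length(null_sel$diagnostics$rounds), 10)
})

test_that("IRIV recovers planted bands on a mid-sized problem", {
  planted <- c(8, 20, 32, 44, 56)
  cfg <- sim_config(n_samples = 100, n_bands = 64,
                    informative_bands = planted,
                    effect_sizes = c(-0.02, -0.02, 0.02, 0.02, 0.02),
                    noise_sd = 0.001, spectral_corr_length = 0, seed = 81)
  ds <- generate_dataset(cfg)
  sel <- run_iriv(ds, iriv_config(n_rows = 200, seed = 81))
  expect_gte(sum(planted %in% sel$indices), 4)
  expect_lte(sum(!sel$indices %in% planted), 3)
})

test_that("backward elimination contracts hold on edge cases", {
  ds <- tiny_dataset(n = 40, p = 10, seed = 91)
  cfg <- iriv_config(seed = 91)
  # single variable: the loop cannot run
  out <- backward_eliminate(ds$X, ds$y, 7L, cfg)
  expect_equal(as.integer(out), 7L)
  # an exactly duplicated variable: one copy goes
  X <- cbind(ds$X[, 1:4], dup = ds$X[, 4])
  y <- ds$y
  kept <- backward_eliminate(X, y, 1:5, cfg)
  expect_false(all(c(4L, 5L) %in% kept))
})

test_that("the greedy elimination path matches brute-force recomputation on p = 6", {
  set.seed(101)
  n <- 50
  X <- matrix(rnorm(6 * n), n)
  y <- 30 + 2 * X[, 1] + 2 * X[, 2] + rnorm(n, sd = 0.5)
  cfg <- iriv_config(max_pls_components = 3, seed = 13)
  folds <- make_folds(n, 5, seed = 13)
  kept <- backward_eliminate(X, y, 1:6, cfg, fold_ids = folds)
  path <- attr(kept, "path")
  vars <- 1:6
  for (st in path) {
    # oracle recomputation of theta_t and every leave-one-out theta
    theta_t <- oracle_rmsecv(X, y, vars, 3, folds)
    theta_minus <- vapply(seq_along(vars), function(i)
      oracle_rmsecv(X, y, vars[-i], 3, folds), numeric(1))
    expect_equal(st$theta_t, theta_t, tolerance = 1e-10)
    expect_equal(st$theta_minus, theta_minus, tolerance = 1e-10)
    if (is.na(st$dropped)) {
      expect_gt(min(theta_minus), theta_t)
      break
    }
    expect_equal(st$dropped, vars[which.min(theta_minus)])
    vars <- vars[-which.min(theta_minus)]
  }
  expect_equal(as.integer(kept), vars)
})

test_that("iriv_round rejects degenerate inputs by name", {
  ds <- tiny_dataset(n = 20, p = 6, seed = 111)
  expect_error(iriv_round(ds$X, ds$y, 3L, iriv_config(seed = 1)), "2 active")
  expect_error(iriv_config(n_rows = 5), "n_rows")
  expect_error(iriv_config(inclusion_prob = 1.2), "inclusion_prob")
})
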