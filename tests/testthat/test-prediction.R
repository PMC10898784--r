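test_that("behavioral PCA normalizes, fixes signs, and is duplication-invariant", {
  set.seed(47)
  latent <- rnorm(12)
  tab <- make_behavior(latent, lambda = rep(1, 11), noise = 0.2, seed = 5)
  bp <- behavioral_pca(tab)
  expect_lt(abs(sum(bp$variance_explained) - 1), 1e-12)
  expect_true(all(bp$coefficients[, 1] > 0))
  expect_gt(abs(cor(bp$b, latent)), 0.95)
  # duplicating every subject leaves the coefficients unchanged
  bp2 <- behavioral_pca(rbind(tab, tab))
  expect_equal(abs(bp2$coefficients[, 1]), abs(bp$coefficients[, 1]),
               tolerance = 1e-8)
  tab$UN <- 1
  expect_error(behavioral_pca(tab), "constant behavioral column")
})

test_that("edge selection ranks deterministically and seeds reproducibly", {
  idx <- build_edge_index(4)   # 6 edges
  icc <- c(0.9, 0.5, 0.9, 0.1, 0.7, 0.3)
  sel <- select_edges("icc_ranked", 3, idx, icc = icc)
  expect_equal(sel$edges, c(1L, 3L, 5L))   # tie at the top -> lower id first
  # tie exactly at rank n: lower edge id included
  icc_tie <- c(0.9, 0.7, 0.5, 0.5, 0.2, 0.3)
  expect_equal(select_edges("icc_ranked", 3, idx, icc = icc_tie)$edges,
               c(1L, 2L, 3L))
  r1 <- select_edges("random", 3, idx, seed = 99)
  r2 <- select_edges("random", 3, idx, seed = 99)
  expect_identical(r1$edges, r2$edges)
  expect_error(select_edges("icc_ranked", 7, idx, icc = icc), "\\[3, 6\\]")
})

test_that("spin permutations are seeded hemisphere-preserving bijections", {
  parc <- make_parcellation(small_config())
  expect_equal(spin_permutation(parc, rotation = diag(3)),
               seq_len(n_regions(parc)))
  perms <- lapply(1:20, function(s) spin_permutation(parc, seed = s))
  for (p in perms) {
    expect_equal(sort(p), seq_len(n_regions(parc)))
    expect_equal(parc$hemisphere[p], parc$hemisphere)
  }
  expect_identical(spin_permutation(parc, seed = 7),
                   spin_permutation(parc, seed = 7))
  distinct <- sum(!vapply(2:20, function(k) {
    identical(perms[[k]], perms[[1]])
  }, logical(1)))
  expect_gte(distinct, 18)
})

test_that("edge PCA matches a covariance eigen-oracle and reconstructs exactly", {
  set.seed(53)
  s <- 10; n <- 40
  x <- matrix(rnorm(s * n), s, n)
  pca <- edge_pca(x, NULL, k = 5)
  # full reconstruction from all components
  rec <- pca$scores_all %*% t(pca$loadings_all)
  xc <- sweep(x, 2, colMeans(x))
  expect_lt(max(abs(rec - xc)), 1e-10)
  # ordering of explained variance
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  # eigen-oracle on the edge covariance, up to sign
  ev <- eigen(cov(x), symmetric = TRUE)
  for (c in 1:5) {
    v_o <- ev$vectors[, c]
    expect_lt(min(max(abs(pca$loadings_all[, c] - v_o)),
                  max(abs(pca$loadings_all[, c] + v_o))), 1e-8)
  }
  # scores against oracle projections (scaled by sqrt(s-1) convention-free)
  sc_o <- xc %*% ev$vectors[, 1]
  expect_lt(min(max(abs(pca$scores_all[, 1] - sc_o)),
                max(abs(pca$scores_all[, 1] + sc_o))), 1e-8)
  # sign convention: the largest-|loading| entry of each component is positive
  for (c in 1:5) {
    expect_gt(pca$loadings_all[which.max(abs(pca$loadings_all[, c])), c], 0)
  }
  expect_error(edge_pca(x, NULL, k = 10), "exceeds")
})

test_that("linear model fits match a normal-equations OLS oracle", {
  set.seed(59)
  s <- 15
  x <- matrix(rnorm(s * 3), s, 3)
  b <- 0.5 * x[, 2] + rnorm(s, sd = 0.5)
  fit <- fit_linear_model(b, x)
  xd <- cbind(1, x)
  beta <- solve(crossprod(xd), crossprod(xd, b))
  res <- b - xd %*% beta
  r2 <- 1 - sum(res^2) / sum((b - mean(b))^2)
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-10)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  f_stat <- (r2 / 3) / ((1 - r2) / (s - 4))
  expect_equal(fit$p, pf(f_stat, 3, s - 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # exact linear response
  fit1 <- suppressWarnings(
    fit_linear_model(2 * x[, 1] - 1, x[, 1, drop = FALSE]))
  expect_equal(fit1$r_squared, 1, tolerance = 1e-12)
  # response orthogonal to the predictor
  y0 <- residuals(lm(rnorm(s) ~ x[, 1]))
  expect_lt(fit_linear_model(y0, x[, 1, drop = FALSE])$r_squared, 1e-12)
})

test_that("s - 1 predictors overfit to R-squared 1 on a generic design", {
  set.seed(61)
  s <- 8
  x <- matrix(rnorm(s * 30), s, 30)
  pca <- edge_pca(x, NULL, k = s - 1)
  b <- rnorm(s)
  fit <- fit_linear_model(b, pca$scores_all[, seq_len(s - 1)])
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("prediction sweep converges at the full edge set and is deterministic", {
  set.seed(67)
  n_reg <- 12
  idx <- build_edge_index(n_reg)             # 66 edges
  s <- 9
  ev <- matrix(rnorm(s * n_edges(idx), sd = 0.3), s, n_edges(idx))
  icc <- runif(n_edges(idx))
  b <- rnorm(s)
  sw <- prediction_sweep(ev, icc, b, idx, n_grid = n_edges(idx), k = 3,
                         ensemble_size = 5, seed = 11)
  f <- sw$fits
  r2 <- f$r_squared[f$model %in% c("icc_ranked", "random")]
  expect_lt(diff(range(r2)), 1e-10)          # same full edge set everywhere
  sw2 <- prediction_sweep(ev, icc, b, idx, n_grid = n_edges(idx), k = 3,
                          ensemble_size = 5, seed = 11)
  expect_identical(sw$fits, sw2$fits)
  # single-predictor variants are present for each grid point
  expect_true(all(c("single_PC1", "single_PC2", "single_PC3") %in% f$model))
})

test_that("spin surrogates read edges through the permutation and keep the grid", {
  set.seed(71)
  cfg <- small_config()
  parc <- make_parcellation(cfg)
  idx <- build_edge_index(parc)
  s <- 8
  ev <- matrix(rnorm(s * n_edges(idx), sd = 0.3), s, n_edges(idx))
  icc <- runif(n_edges(idx))
  b <- rnorm(s)
  sw <- prediction_sweep(ev, icc, b, idx, n_grid = c(20L, 40L), k = 3,
                         ensembles = c("random", "spin"), ensemble_size = 4,
                         seed = 13, parc = parc)
  f <- sw$fits
  expect_equal(sum(f$model == "spin"), 8)
  expect_true(all(f$r_squared >= 0 & f$r_squared <= 1 + 1e-12))
})

test_that("ensemble comparison handles degenerate and constructed cases", {
  fits <- data.frame(
    n = rep(100L, 6),
    model = c("icc_ranked", rep("random", 5)),
    replicate = c(0L, 1:5),
    r_squared = c(0.5, rep(0.5, 5)),
    p = 0.1)
  sw <- structure(list(fits = fits, n_grid = 100L), class = "prediction_sweep")
  res <- ensemble_comparison(sw)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # ensemble far below the reference with small SD
  fits$r_squared <- c(0.9, 0.10, 0.11, 0.09, 0.10, 0.105)
  sw$fits <- fits
  res <- ensemble_comparison(sw)
  ens <- fits$r_squared[-1]
  t_hand <- (mean(ens) - 0.9) / (sd(ens) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_lt(res$p_adj, 0.05)
  expect_true(all(res$p_adj >= res$p))
})
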