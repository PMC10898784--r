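# Build pairs whose edge (1,2) takes prescribed half values per subject.
pairs_from_edge_values <- function(h1, h2) {
  lapply(seq_along(h1), function(k) {
    m1 <- diag(3); m1[1, 2] <- m1[2, 1] <- h1[k]
    m2 <- diag(3); m2[1, 2] <- m2[2, 1] <- h2[k]
    fake_pair(m1, m2, paste0("s", k))
  })
}

# Independent oracle: classical one-way random-effects ANOVA via stats::aov.
icc11_oracle <- function(values) {   # values: s x 2 (subjects x measurements)
  long <- data.frame(y = as.vector(t(values)),
                     g = factor(rep(seq_len(nrow(values)), each = 2)))
  tab <- summary(stats::aov(y ~ g, data = long))[[1]]
  msb <- tab["g", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

test_that("edgewise ICC reproduces the hand-computed one-way ANOVA case", {
  pairs <- pairs_from_edge_values(h1 = c(1, 5), h2 = c(3, 7))
  suppressWarnings(res <- edgewise_icc(pairs, build_edge_index(3)))
  expect_equal(res$msr[1], 16)
  expect_equal(res$msw[1], 2)
  expect_equal(res$icc[1], 7 / 9)
})

test_that("edgewise ICC hits the +1 and -1 boundary cases", {
  # identical halves per subject, differing means -> ICC 1
  pairs <- pairs_from_edge_values(h1 = c(0.1, 0.5, 0.9), h2 = c(0.1, 0.5, 0.9))
  suppressWarnings(res <- edgewise_icc(pairs, build_edge_index(3)))
  expect_equal(res$icc[1], 1)
  # identical means across subjects, nonzero within-variance -> ICC -1
  pairs <- pairs_from_edge_values(h1 = c(0.2, 0.2, 0.2), h2 = c(0.6, 0.6, 0.6))
  suppressWarnings(res <- edgewise_icc(pairs, build_edge_index(3)))
  expect_equal(res$icc[1], -1)
})

test_that("degenerate edges get ICC 0 with a warning", {
  pairs <- pairs_from_edge_values(h1 = c(0.4, 0.4), h2 = c(0.4, 0.4))
  expect_warning(res <- edgewise_icc(pairs, build_edge_index(3)),
                 "degenerate")
  expect_equal(res$icc[1], 0)
  expect_true(res$degenerate[1])
})

test_that("edgewise ICC agrees with the ANOVA ICC(1,1) oracle on random data", {
  set.seed(17)
  for (rep in 1:200) {
    s <- sample(3:20, 1)
    h1 <- rnorm(s); h2 <- rnorm(s)
    pairs <- pairs_from_edge_values(h1, h2)
    suppressWarnings(res <- edgewise_icc(pairs, build_edge_index(3)))
    expect_lt(abs(res$icc[1] - icc11_oracle(cbind(h1, h2))), 1e-10)
  }
})

test_that("ICC is invariant to half swaps, common shifts and positive scaling", {
  set.seed(19)
  s <- 8
  h1 <- rnorm(s); h2 <- rnorm(s)
  base <- suppressWarnings(
    edgewise_icc(pairs_from_edge_values(h1, h2), build_edge_index(3)))$icc[1]
  # swap halves of subjects 2 and 5
  h1s <- h1; h2s <- h2
  h1s[c(2, 5)] <- h2[c(2, 5)]; h2s[c(2, 5)] <- h1[c(2, 5)]
  swapped <- suppressWarnings(
    edgewise_icc(pairs_from_edge_values(h1s, h2s), build_edge_index(3)))$icc[1]
  expect_equal(swapped, base, tolerance = 1e-12)
  shifted <- suppressWarnings(
    edgewise_icc(pairs_from_edge_values(h1 + 5, h2 + 5),
                 build_edge_index(3)))$icc[1]
  expect_equal(shifted, base, tolerance = 1e-10)
  scaled <- suppressWarnings(
    edgewise_icc(pairs_from_edge_values(3 * h1, 3 * h2),
                 build_edge_index(3)))$icc[1]
  expect_equal(scaled, base, tolerance = 1e-10)
})

test_that("ICC strength satisfies the handshake identity and a brute-force loop", {
  set.seed(23)
  idx <- build_edge_index(12)
  v <- runif(n_edges(idx), -1, 1)
  strength <- icc_strength(v, idx)
  expect_equal(sum(strength), 2 * sum(v), tolerance = 1e-12)
  oracle <- numeric(12)
  for (e in seq_len(n_edges(idx))) {
    oracle[idx$i[e]] <- oracle[idx$i[e]] + v[e]
    oracle[idx$j[e]] <- oracle[idx$j[e]] + v[e]
  }
  expect_equal(strength, oracle, tolerance = 1e-12)
  expect_equal(icc_strength(rep(0.5, n_edges(idx)), idx), rep(0.5 * 11, 12))
})

test_that("thresholded ICC matrix binarizes strictly above the threshold", {
  idx <- build_edge_index(3)
  m <- threshold_icc_matrix(c(0.61, 0.59, 0.6), idx, thr = 0.6)
  expect_equal(sum(m), 2)         # one edge, both triangles
  expect_equal(m[1, 2], 1)
  expect_equal(diag(m), rep(0, 3))
  expect_equal(sum(threshold_icc_matrix(c(0.3, 0.9, 1), idx, thr = 1)), 0)
})

test_that("RSN-pair ICC contrasts detect planted shifts and stay null under equality", {
  parc <- make_parcellation(small_config())
  idx <- build_edge_index(parc)
  labels <- edge_rsn_labels(idx, parc)
  set.seed(29)
  icc_a <- list(icc = runif(n_edges(idx), 0, 0.8))
  icc_b <- list(icc = icc_a$icc)
  eq <- rsn_icc_contrast(icc_a, icc_b, labels)
  expect_equal(eq$delta_mean, rep(0, nrow(eq)))
  expect_equal(eq$t, rep(0, nrow(eq)))
  # constant +delta on one RSN pair
  icc_c <- list(icc = icc_a$icc + 0.15 * (labels == "DMN-DMN"))
  sh <- rsn_icc_contrast(icc_c, icc_b, labels)
  expect_equal(sh$delta_mean[sh$rsn_pair == "DMN-DMN"], 0.15)
  expect_true(all(sh$p_adj >= sh$p))
})

test_that("RSN strength contrasts localize a planted regional shift", {
  parc <- make_parcellation(small_config())
  set.seed(31)
  str_b <- runif(28)
  eq <- rsn_strength_contrast(str_b, str_b, parc)
  expect_equal(eq$t, rep(0, 7))
  str_a <- str_b + 2 * (parc$rsn == "DMN")
  sh <- rsn_strength_contrast(str_a, str_b, parc)
  expect_equal(sh$delta_mean[sh$rsn == "DMN"], 2)
  expect_equal(sh$delta_mean[sh$rsn == "Vis"], 0)
})

test_that("z-scored maps are standardized and affine-invariant", {
  set.seed(37)
  x <- rnorm(50)
  z <- zscore_map(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore_map(3 * x + 7), z, tolerance = 1e-10)
  expect_equal(zscore_map(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore_map(rep(1, 5)), "zero variance")
})
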