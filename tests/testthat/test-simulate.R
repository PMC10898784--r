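test_that("synthetic parcellation echoes its config deterministically", {
  cfg <- sim_config()
  parc <- make_parcellation(cfg)
  expect_equal(n_regions(parc), 200)
  expect_equal(length(unique(parc$rsn)), 7)
  expect_equal(sum(parc$hemisphere == "L"), 100)
  expect_equal(sum(parc$hemisphere == "R"), 100)
  coords <- as.matrix(parc[, c("x", "y", "z")])
  expect_lt(max(abs(sqrt(rowSums(coords^2)) - 1)), 1e-9)
  expect_identical(make_parcellation(cfg), parc)
  expect_equal(as.vector(table(parc$rsn)[names(cfg$rsn_counts)]),
               unname(cfg$rsn_counts))
})

test_that("subject covariance reduces to the block base when alpha = beta = 0", {
  cfg <- small_config(alpha = c(psilocybin = 0, placebo = 0), beta = 0)
  parc <- make_parcellation(cfg)
  sigma <- make_subject_covariance(cfg, parc, "psilocybin", b_true = 1.3,
                                   seed = 5)
  same <- outer(parc$rsn, parc$rsn, `==`)
  base <- ifelse(same, cfg$rho_within, cfg$rho_between)
  diag(base) <- 1
  expect_lt(max(abs(sigma - base)), 1e-10)
})

test_that("subject covariances are valid correlation matrices with floored spectra", {
  cfg <- sim_config()
  parc <- make_parcellation(cfg)
  for (cond in c("psilocybin", "placebo")) {
    sigma <- make_subject_covariance(cfg, parc, cond, b_true = 1.5, seed = 9)
    expect_equal(diag(sigma), rep(1, 200))
    expect_lt(max(abs(sigma - t(sigma))), 1e-12)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("positive b lowers mean within-DMN connectivity for the same draw", {
  cfg <- sim_config()
  parc <- make_parcellation(cfg)
  dmn <- which(parc$rsn == "DMN")
  s0 <- make_subject_covariance(cfg, parc, "psilocybin", b_true = 0, seed = 21)
  s1 <- make_subject_covariance(cfg, parc, "psilocybin", b_true = 1.5,
                                seed = 21)
  off <- upper.tri(s0[dmn, dmn])
  expect_lt(mean(s1[dmn, dmn][off]), mean(s0[dmn, dmn][off]))
})

test_that("sampled time series reproduce their target covariance at large T", {
  cfg <- small_config()
  parc <- make_parcellation(cfg)
  sigma <- make_subject_covariance(cfg, parc, "placebo", seed = 2)
  x <- sample_timeseries(sigma, 50000, seed = 1)
  emp <- cor(t(x))
  expect_lt(max(abs(emp - sigma)), 0.05)
  expect_lt(mean(abs(emp - sigma)), 0.02)
  # identity covariance: off-diagonal empirical correlations near zero
  x0 <- sample_timeseries(diag(10), 20000, seed = 3)
  emp0 <- cor(t(x0))
  expect_lt(mean(abs(emp0[upper.tri(emp0)])), 0.01)
  expect_identical(sample_timeseries(sigma, 100, seed = 4),
                   sample_timeseries(sigma, 100, seed = 4))
})

test_that("behavior tables are nonnegative with a recoverable latent score", {
  set.seed(97)
  latent <- rnorm(15)
  lam <- sim_config()$behavior_lambda
  noiseless <- make_behavior(latent, lam, noise = 0, seed = 1)
  expect_true(all(noiseless >= 0))
  bp <- behavioral_pca(noiseless)
  expect_gt(abs(cor(bp$b, latent)), 1 - 1e-9)
  noisy <- make_behavior(latent, lam, noise = 0.3, seed = 1)
  expect_true(all(noisy >= 0))
})

test_that("planted pattern has the DMN-centric sign structure and unit norm", {
  cfg <- sim_config()
  parc <- make_parcellation(cfg)
  p <- planted_pattern(parc, cfg$pattern_concentration)
  expect_lt(abs(sqrt(sum(p^2)) - 1), 1e-12)
  rsn <- parc$rsn
  dmn <- rsn == "DMN"
  expect_true(all(p[dmn, dmn][upper.tri(p[dmn, dmn])] < 0))
  expect_true(all(p[dmn, rsn == "LIM"] < 0))
  expect_true(all(p[dmn, rsn == "DA"] > 0))
  expect_true(all(p[dmn, rsn == "VA"] > 0))
  expect_true(all(p[rsn == "Vis", rsn == "SM"] == 0))
  expect_identical(planted_pattern(parc, cfg$pattern_concentration), p)
})

test_that("generated cohorts have the study's composition and load end-to-end", {
  cfg <- small_config(seed = 11)
  coh <- generate_cohort(cfg)
  expect_equal(length(coh$subjects), 13)
  expect_equal(sum(coh$manifest$condition == "psilocybin"), 6)
  expect_equal(sum(coh$manifest$condition == "placebo"), 7)
  expect_equal(nrow(coh$behavior), 6)
  expect_equal(length(coh$truth$b_true), 6)

  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  parc <- load_parcellation(file.path(dir, "parcellation.tsv"))
  fcs <- load_cohort_fcs(file.path(dir, "manifest.csv"), parc)
  expect_equal(length(fcs), 13)
  expect_s3_class(fcs[[1]], "fc_pair")
  behav <- load_behavior(file.path(dir, "behavior.csv"))
  expect_equal(dim(behav), c(6, 11))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(unname(truth$b_true), unname(coh$truth$b_true),
               tolerance = 1e-9)
})

test_that("cohort generation is deterministic and motion is condition-shifted", {
  cfg <- small_config(seed = 19)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects[[3]]$data, c2$subjects[[3]]$data)
  expect_identical(c1$behavior, c2$behavior)
  expect_identical(c1$manifest, c2$manifest)
  # condition-shifted motion covariate, averaged over several small cohorts
  mot <- sapply(1:8, function(s) {
    m <- generate_cohort(small_config(seed = 100 + s))$manifest
    c(psi = mean(m$motion[m$condition == "psilocybin"]),
      pla = mean(m$motion[m$condition == "placebo"]))
  })
  expect_gt(mean(mot["psi", ] - mot["pla", ]), 0)
})

test_that("edgewise ICC of signature edges rises with scan length", {
  iccs <- sapply(c(128, 512, 2048), function(tp) {
    cfg <- sim_config(seed = 23, timepoints = tp)
    coh <- generate_cohort(cfg)
    idx <- build_edge_index(coh$parc)
    pairs <- cohort_fc_pairs(coh)
    res <- suppressWarnings(edgewise_icc(pairs$placebo, idx))
    fpn <- which(coh$parc$rsn == "FPN")
    sig_edges <- which(idx$i %in% fpn & idx$j %in% fpn)
    mean(res$icc[sig_edges])
  })
  expect_true(all(diff(iccs) > 0))
})
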