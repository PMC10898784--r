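# Shared fixtures: built in code at test time, nothing read from disk.

# Small balanced study config: 28 regions (4 per RSN), short scans.
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_regions = 28,
             rsn_counts = c(Vis = 4, SM = 4, DA = 4, VA = 4, LIM = 4,
                            FPN = 4, DMN = 4),
             s_psilocybin = 6, s_placebo = 7,
             timepoints = 64, planted_n = 30, ...)
}

# A fake split-half connectome pair built directly from two symmetric
# matrices (bypasses time series; for ICC / identifiability unit tests).
fake_pair <- function(first, second, subject_id = "s1",
                      condition = "psilocybin", full = NULL) {
  if (is.null(full)) full <- (first + second) / 2
  structure(list(first = first, second = second, full = full,
                 subject_id = subject_id, condition = condition, motion = 0),
            class = "fc_pair")
}

# Random symmetric matrix with unit diagonal (not necessarily PSD; fine for
# edge bookkeeping tests).
rand_sym <- function(n, sd = 0.2) {
  m <- matrix(stats::rnorm(n * n, sd = sd), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# Cache expensive default-scale cohorts across test files.
.fixture_env <- new.env(parent = emptyenv())

default_cohort_fixture <- function(seed = 1) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(seed = seed)
    coh <- generate_cohort(cfg)
    idx <- build_edge_index(coh$parc)
    pairs <- cohort_fc_pairs(coh)
    .fixture_env[[key]] <- list(
      cfg = cfg, cohort = coh, idx = idx, pairs = pairs,
      labels = edge_rsn_labels(idx, coh$parc),
      icc_psi = edgewise_icc(pairs$psilocybin, idx),
      icc_pla = edgewise_icc(pairs$placebo, idx),
      edge_values_psi = t(vapply(pairs$psilocybin,
                                 function(p) vectorize_edges(p$full, idx),
                                 numeric(n_edges(idx)))))
  }
  .fixture_env[[key]]
}
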