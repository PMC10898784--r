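#' Edgewise class-1 intraclass correlation of split-half connectomes
#'
#' For each edge, the two split-half values per subject are treated as
#' repeated measurements of a subject-level trait and scored with the
#' classical one-way random-effects ICC(1,1) at k = 2 measurements:
#' `ICC = (MSR - MSW) / (MSR + MSW)` with `MSR = 2 * var(mu)` (sample
#' variance, across subjects, of the per-subject across-half means `mu`) and
#' `MSW = mean(sigma)` (mean across subjects of the per-subject within-pair
#' variance `sigma = (x1 - x2)^2 / 2`). High ICC marks edges that are
#' temporally stable within a subject yet differ strongly between subjects —
#' the operational definition of connectome idiosyncrasy.
#'
#' Degenerate edges with `MSR + MSW = 0` (all values identical) get ICC 0 and
#' are flagged, so rankings stay total.
#'
#' @param pairs List of [fc_pair()] of one condition (s >= 2 subjects).
#' @param idx The [build_edge_index()].
#' @return An `icc_result` list: `icc` (per-edge vector in `[-1, 1]`), `msr`,
#'   `msw`, `mu` (s x n_edges), `sigma` (s x n_edges), `degenerate` (logical
#'   per edge), `condition`, `n_subjects`.
#' @export
edgewise_icc <- function(pairs, idx) {
  s <- length(pairs)
  assert_that(s >= 2, "need at least 2 subjects, got %d", s)
  conds <- unique(vapply(pairs, `[[`, character(1), "condition"))
  assert_that(length(conds) == 1, "all subjects must share one condition")
  h1 <- edge_matrix(pairs, idx, "first")
  h2 <- edge_matrix(pairs, idx, "second")
  mu <- (h1 + h2) / 2
  sigma <- (h1 - h2)^2 / 2
  # sample variance of mu across subjects (divisor s - 1), per edge
  mu_bar <- colMeans(mu)
  var_mu <- colSums(sweep(mu, 2L, mu_bar)^2) / (s - 1)
  msr <- 2 * var_mu
  msw <- colMeans(sigma)
  denom <- msr + msw
  degenerate <- denom == 0
  if (any(degenerate)) {
    warning(sprintf("%d degenerate edge(s) with zero total variance; ICC set to 0",
                    sum(degenerate)))
  }
  icc <- ifelse(degenerate, 0, (msr - msw) / ifelse(degenerate, 1, denom))
  structure(list(icc = unname(icc), msr = unname(msr), msw = unname(msw),
                 mu = mu, sigma = sigma, degenerate = unname(degenerate),
                 condition = conds, n_subjects = s),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s: %d edges, %d subjects, ICC range [%.3f, %.3f]\n",
              x$condition, length(x$icc), x$n_subjects,
              min(x$icc), max(x$icc)))
  invisible(x)
}

#' Regional ICC strength
#'
#' The idiosyncrasy of a region is summarized as the sum of the
#' (non-thresholded) ICC values of all edges incident to it; every edge
#' contributes to exactly its two endpoint regions, so the strengths sum to
#' twice the total edgewise ICC.
#'
#' @param icc An [edgewise_icc()] result or a plain per-edge numeric vector.
#' @param idx The [build_edge_index()].
#' @return Numeric vector of length N (regions in parcellation order).
#' @export
icc_strength <- function(icc, idx) {
  v <- if (inherits(icc, "icc_result")) icc$icc else as.numeric(icc)
  assert_that(length(v) == n_edges(idx), "ICC vector does not match edge index")
  n <- attr(idx, "n_regions")
  # accumulate each edge onto both endpoint regions
  strength <- numeric(n)
  acc <- rowsum(c(v, v), group = c(idx$i, idx$j))
  strength[as.integer(rownames(acc))] <- acc[, 1L]
  strength
}

#' Thresholded binary ICC matrix
#'
#' @param icc An [edgewise_icc()] result or per-edge vector.
#' @param idx The [build_edge_index()].
#' @param thr Threshold; entries are 1 iff ICC strictly exceeds it
#'   (default 0.6, the display threshold used for idiosyncrasy matrices).
#' @return Binary N x N matrix with zero diagonal.
#' @export
threshold_icc_matrix <- function(icc, idx, thr = 0.6) {
  v <- if (inherits(icc, "icc_result")) icc$icc else as.numeric(icc)
  unvectorize_edges(as.numeric(v > thr), idx, diag = 0)
}

#' RSN-pair contrast of edgewise ICC between conditions
#'
#' For each of the 28 unordered RSN pairs, compares the ICCs of all edges
#' connecting the two RSNs between conditions: mean paired difference
#' (`a - b`), paired t-test across the member edges, and Benjamini-Hochberg
#' adjustment over the 28 pairs.
#'
#' @param icc_a,icc_b [edgewise_icc()] results for the two conditions
#'   (e.g. psilocybin and placebo) on the same edge index.
#' @param labels Per-edge RSN-pair labels from [edge_rsn_labels()].
#' @return Data frame, one row per RSN pair: `rsn_pair`, `n_edges_pair`,
#'   `delta_mean`, `t`, `df`, `p`, `p_adj`.
#' @export
rsn_icc_contrast <- function(icc_a, icc_b, labels) {
  va <- icc_a$icc; vb <- icc_b$icc
  assert_that(length(va) == length(vb) && length(va) == length(labels),
              "both conditions and labels must cover the same edges")
  lv <- intersect(rsn_pair_levels(), unique(labels))
  rows <- lapply(lv, function(lab) {
    e <- which(labels == lab)
    assert_that(length(e) >= 2, "RSN pair %s has fewer than 2 edges", lab)
    d <- va[e] - vb[e]
    if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
      # constant paired differences: t degenerates
      tt <- list(statistic = if (abs(mean(d)) <= 1e-12) 0 else
                   sign(mean(d)) * Inf,
                 parameter = length(e) - 1,
                 p.value = if (abs(mean(d)) <= 1e-12) 1 else 0)
    } else {
      tt <- stats::t.test(va[e], vb[e], paired = TRUE)
    }
    data.frame(rsn_pair = lab, n_edges_pair = length(e), delta_mean = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-RSN contrast of regional ICC strength between conditions
#'
#' For each RSN, takes the per-region strength differences (`a - b`) of its
#' member regions, tests them against zero with a paired t-test, and applies
#' Benjamini-Hochberg over the 7 RSNs.
#'
#' @param str_a,str_b Per-region strength vectors (same parcellation order),
#'   e.g. from [icc_strength()].
#' @param parc The [parcellation()].
#' @return Data frame, one row per RSN: `rsn`, `n_regions_rsn`, `delta_mean`,
#'   `t`, `df`, `p`, `p_adj`.
#' @export
rsn_strength_contrast <- function(str_a, str_b, parc) {
  assert_that(length(str_a) == n_regions(parc) &&
              length(str_b) == n_regions(parc),
              "strength vectors must match the parcellation")
  lv <- intersect(RSN_LEVELS, unique(parc$rsn))
  rows <- lapply(lv, function(net) {
    r <- which(parc$rsn == net)
    assert_that(length(r) >= 2, "RSN %s has fewer than 2 regions", net)
    d <- str_a[r] - str_b[r]
    if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
      tt <- list(statistic = if (abs(mean(d)) <= 1e-12) 0 else
                   sign(mean(d)) * Inf,
                 parameter = length(r) - 1,
                 p.value = if (abs(mean(d)) <= 1e-12) 1 else 0)
    } else {
      tt <- stats::t.test(d, mu = 0)
    }
    data.frame(rsn = net, n_regions_rsn = length(r), delta_mean = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Z-score a regional map
#'
#' Standardizes a per-region vector to mean 0, sample SD 1 across regions
#' (used for ICC-strength maps and their condition differences).
#'
#' @param x Numeric vector (>= 2 values, nonzero variance).
#' @return Z-scored vector of the same length.
#' @export
zscore_map <- function(x) {
  assert_that(length(x) >= 2, "need at least 2 values")
  s <- stats::sd(x)
  assert_that(s > 0, "zero variance: z-scores undefined")
  (x - mean(x)) / s
}
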