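#' Regional sums of an edge-PC's coefficients
#'
#' Projects a component's edge loadings onto regions by summing, for each
#' region, the loadings of all selected edges incident to it. The result
#' maps where (anatomically) the predictive connectivity pattern loads;
#' each edge contributes to exactly its two endpoint regions, so the
#' regional sums total twice the loading sum (handshake identity).
#'
#' @param pca An [edge_pca()].
#' @param component Which component's loadings to project (default 2, the
#'   `y` predictor).
#' @param sel The [select_edges()] selection the PCA was fitted on (taken
#'   from the PCA object when omitted).
#' @param idx The [build_edge_index()].
#' @param parc The [parcellation()].
#' @return Numeric vector of length N (per-region signed coefficient sums).
#' @export
region_coefficient_map <- function(pca, component = 2, sel = NULL, idx, parc) {
  if (is.null(sel)) sel <- pca$selection
  assert_that(!is.null(sel), "no edge selection available")
  assert_that(component >= 1 && component <= ncol(pca$loadings_all),
              "component %d not fitted", component)
  w <- pca$loadings_all[, component]
  assert_that(length(w) == length(sel$edges),
              "loadings and selection disagree on edge count")
  out <- numeric(n_regions(parc))
  acc <- rowsum(c(w, w), group = c(idx$i[sel$edges], idx$j[sel$edges]))
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

#' Rank-1 reconstruction of selected edges from one component
#'
#' Rebuilds each subject's selected-edge vector from a single edge PC and
#' the subject's score on it: `xhat_i = column means + score_i * loading`.
#' Including the edgewise mean keeps the reconstruction interpretable as
#' connectivity levels rather than deviations.
#'
#' @param pca An [edge_pca()].
#' @param component Component to reconstruct from (default 2).
#' @param components Alternatively, an integer vector of components to sum
#'   over (e.g. `seq_len(k)` approaches the original data).
#' @return Subjects x n_selected matrix of reconstructed edge values.
#' @export
reconstruct_rank1 <- function(pca, component = 2, components = NULL) {
  if (is.null(components)) components <- component
  v <- pca$loadings_all[, components, drop = FALSE]
  u <- pca$scores_all[, components, drop = FALSE]
  rec <- u %*% t(v)
  sweep(rec, 2L, pca$center, `+`)
}

#' RSN-aggregated mean connectivity matrix
#'
#' Averages edge values over the members of each unordered RSN pair within
#' an edge selection, yielding a 7 x 7 symmetric summary. Cells whose RSN
#' pair has no member edge inside the selection are `NA` (flagged
#' undefined).
#'
#' @param edge_values Numeric vector of edge values for the selected edges
#'   (one subject or a group mean).
#' @param sel The [select_edges()] selection (or integer edge ids).
#' @param labels Full-length per-edge RSN labels from [edge_rsn_labels()].
#' @return 7 x 7 symmetric matrix with RSN dimnames.
#' @export
rsn_average_fc <- function(edge_values, sel, labels) {
  edges <- if (inherits(sel, "edge_selection")) sel$edges else as.integer(sel)
  assert_that(length(edge_values) == length(edges),
              "edge_values must align with the selection")
  lab <- labels[edges]
  means <- tapply(edge_values, lab, mean)
  k <- length(RSN_LEVELS)
  m <- matrix(NA_real_, k, k, dimnames = list(RSN_LEVELS, RSN_LEVELS))
  for (a in seq_len(k)) for (b in a:k) {
    key <- paste(RSN_LEVELS[a], RSN_LEVELS[b], sep = "-")
    if (key %in% names(means)) m[a, b] <- m[b, a] <- means[[key]]
  }
  m
}

#' Archetype RSN matrices weighted by |y|
#'
#' Averages per-subject RSN matrices separately over subjects with positive
#' and negative component score `y`, weighting each subject by `|y|`:
#' `rFC y+ = sum_{y_i > 0} |y_i| M_i / sum |y_i|` and analogously for
#' `rFC y-`. These crystallize the connectivity patterns of the archetype
#' intense-experience (y+) and mild-experience (y-) subjects. Subjects with
#' `y` exactly 0 are excluded; a side with no subjects is `NULL` (reported
#' undefined).
#'
#' @param rsn_per_subject List of per-subject 7 x 7 RSN matrices.
#' @param y Per-subject component scores aligned with the list.
#' @return List with elements `y_plus` and `y_minus` (7 x 7 matrices or
#'   `NULL`).
#' @export
archetype_matrices <- function(rsn_per_subject, y) {
  assert_that(length(rsn_per_subject) == length(y),
              "matrices and scores disagree on subjects")
  side <- function(keep) {
    if (!any(keep)) return(NULL)
    w <- abs(y[keep])
    mats <- rsn_per_subject[keep]
    acc <- Reduce(`+`, Map(function(m, wi) m * wi, mats, w))
    acc / sum(w)
  }
  list(y_plus = side(y > 0), y_minus = side(y < 0))
}

#' Correlation of DMN-block connectivity with the behavior score b
#'
#' Summarizes each subject's mean connectivity in four DMN-centric blocks —
#' within-DMN, DMN-LIM, DMN-attentional (mean over DMN-VA and DMN-DA edges)
#' and DMN-sensory (mean over DMN-Vis and DMN-SM edges) — over the member
#' edges of an edge selection, taken directly from the (non-reconstructed)
#' full-scan connectomes; then correlates each block with `b` (Pearson,
#' two-sided p, Benjamini-Hochberg over the 4 blocks). Pass all edge ids to
#' reproduce the unselected all-edge control.
#'
#' @param edge_values Subjects x n_edges matrix of full-scan edge vectors.
#' @param sel [select_edges()] selection or integer edge ids (possibly all).
#' @param labels Full-length per-edge RSN labels.
#' @param b Behavioral PC1 scores aligned with `edge_values` rows.
#' @return Data frame: `block`, `r`, `p`, `p_adj`, plus attribute
#'   `per_subject` (subjects x 4 block-mean matrix).
#' @export
dmn_behavior_correlations <- function(edge_values, sel, labels, b) {
  assert_that(nrow(edge_values) >= 4, "need at least 4 subjects")
  edges <- if (inherits(sel, "edge_selection")) sel$edges else as.integer(sel)
  lab <- labels[edges]
  blocks <- list(
    "DMN-DMN" = "DMN-DMN",
    "DMN-LIM" = "LIM-DMN",
    "DMN-attentional" = c("DA-DMN", "VA-DMN"),
    "DMN-sensory" = c("Vis-DMN", "SM-DMN"))
  per_subject <- sapply(blocks, function(keys) {
    e <- edges[lab %in% keys]
    assert_that(length(e) >= 1, "block has no member edges in the selection")
    rowMeans(edge_values[, e, drop = FALSE])
  })
  res <- lapply(colnames(per_subject), function(bl) {
    ct <- pearson_with_p(per_subject[, bl], b)
    data.frame(block = bl, r = ct$r, p = ct$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "per_subject") <- per_subject
  out
}
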