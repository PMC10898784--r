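#' Within-condition identifiability matrix
#'
#' For `s` subjects of one condition, builds the (nonsymmetric, square)
#' matrix `A` whose entry `a[i, j]` is the Pearson correlation between the
#' second-half edge vector of subject `i` (rows) and the first-half edge
#' vector of subject `j` (columns), restricted to an edge selection.
#'
#' @param pairs List of [fc_pair()] objects, all of the same condition.
#' @param idx The [build_edge_index()].
#' @param selection Integer vector of edge ids to use (default: all edges).
#' @param selection_id Free-text provenance tag stored on the result.
#' @return An `identifiability_matrix`: s x s matrix with attributes
#'   `condition`, `subjects`, `selection_id`.
#' @export
identifiability_matrix <- function(pairs, idx, selection = NULL,
                                   selection_id = "all_edges") {
  conds <- unique(vapply(pairs, `[[`, character(1), "condition"))
  assert_that(length(conds) == 1,
              "all subjects must share one condition, got: %s",
              paste(conds, collapse = ", "))
  if (is.null(selection)) selection <- seq_len(n_edges(idx))
  assert_that(length(selection) >= 3,
              "edge selection must have at least 3 edges, got %d",
              length(selection))
  assert_that(all(selection >= 1 & selection <= n_edges(idx)),
              "edge selection out of range")
  e1 <- edge_matrix(pairs, idx, "first")[, selection, drop = FALSE]
  e2 <- edge_matrix(pairs, idx, "second")[, selection, drop = FALSE]
  sds <- c(apply(e1, 1L, stats::sd), apply(e2, 1L, stats::sd))
  if (any(sds == 0)) stopf("zero-variance selected-edge vector for a subject")
  a <- stats::cor(t(e2), t(e1))
  dimnames(a) <- list(rownames(e2), rownames(e1))
  structure(a, class = c("identifiability_matrix", class(a)),
            condition = conds, subjects = rownames(e1),
            selection_id = selection_id)
}

#' Iself, Iothers and Idiff from an identifiability matrix
#'
#' `Iself[i] = a[i, i]` (split-half self correlation); `Iothers[i]` is the
#' mean of the off-diagonal entries of row i and column i,
#' `(1 / (2 (s - 1))) * sum_{j != i} (a[i, j] + a[j, i])`, using only
#' within-condition pairs; `Idiff = Iself - Iothers` measures within-group
#' identifiability.
#'
#' @param a An [identifiability_matrix()] (or any square numeric matrix).
#' @return A data frame with columns `subject_id`, `condition`, `iself`,
#'   `iothers`, `idiff`.
#' @export
fingerprint_metrics <- function(a) {
  s <- nrow(a)
  assert_that(s >= 2, "need at least 2 subjects, got %d", s)
  assert_that(ncol(a) == s, "identifiability matrix must be square")
  iself <- diag(as.matrix(a))
  iothers <- (rowSums(a) + colSums(a) - 2 * iself) / (2 * (s - 1))
  subj <- attr(a, "subjects")
  if (is.null(subj)) subj <- rownames(a)
  if (is.null(subj)) subj <- as.character(seq_len(s))
  cond <- attr(a, "condition")
  if (is.null(cond)) cond <- NA_character_
  data.frame(subject_id = subj, condition = cond,
             iself = unname(iself), iothers = unname(iothers),
             idiff = unname(iself - iothers))
}

#' Identifiability over top-n ICC-ranked edge subsets
#'
#' Recomputes Iself/Iothers/Idiff for both conditions on the top-`n` edges of
#' an ICC ranking (typically the drug condition's), over an increasing grid
#' of `n`. The final grid point normally includes all edges, where the
#' metrics coincide with the full-connectome values.
#'
#' @param pairs_by_condition Named list of lists of [fc_pair()], one entry
#'   per condition.
#' @param icc Numeric per-edge ICC vector used for ranking (ties broken by
#'   ascending edge id).
#' @param idx The [build_edge_index()].
#' @param n_grid Strictly increasing integer vector of edge counts
#'   (default `seq(50, n_edges, by = 50)` capped to end at `n_edges`).
#' @return An `identifiability_curve` data frame: one row per
#'   (condition, n) with group mean and standard error (sd/sqrt(s)) of
#'   `idiff`, `iself`, `iothers`.
#' @export
identifiability_curve <- function(pairs_by_condition, icc, idx, n_grid = NULL) {
  ne <- n_edges(idx)
  assert_that(length(icc) == ne, "ranking must cover all %d edges", ne)
  if (is.null(n_grid)) n_grid <- unique(c(seq(50L, ne, by = 50L), ne))
  n_grid <- as.integer(n_grid)
  assert_that(all(diff(n_grid) > 0), "n_grid must be strictly increasing")
  assert_that(min(n_grid) >= 3 && max(n_grid) <= ne,
              "n_grid must lie within [3, %d]", ne)
  ranking <- order(-icc, seq_along(icc))
  rows <- list()
  for (n in n_grid) {
    sel <- ranking[seq_len(n)]
    for (cond in names(pairs_by_condition)) {
      m <- fingerprint_metrics(identifiability_matrix(
        pairs_by_condition[[cond]], idx, selection = sel,
        selection_id = sprintf("top_%d", n)))
      s <- nrow(m)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, n = n,
        idiff_mean = mean(m$idiff), idiff_se = stats::sd(m$idiff) / sqrt(s),
        iself_mean = mean(m$iself), iself_se = stats::sd(m$iself) / sqrt(s),
        iothers_mean = mean(m$iothers), iothers_se = stats::sd(m$iothers) / sqrt(s))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("identifiability_curve", "data.frame")
  out
}
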