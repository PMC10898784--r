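#' Cortical parcellation with resting-state-network labels
#'
#' A parcellation describes the `N` cortical regions (nodes) of the
#' connectome: a unique integer id, a text label, a hemisphere (`L`/`R`), one
#' of the seven canonical resting-state networks (RSNs: Vis, SM, DA, VA, LIM,
#' FPN, DMN), and a unit-sphere centroid used by the spherical-rotation (spin)
#' null model.
#'
#' @param regions A data frame with columns `id`, `label`, `hemisphere`,
#'   `rsn`, `x`, `y`, `z`.
#' @return An object of class `parcellation`: a validated data frame of
#'   regions with attribute `n_regions`.
#' @examples
#' parc <- make_parcellation(sim_config(n_regions = 14))
#' n_regions(parc)
#' @export
parcellation <- function(regions) {
  required <- c("id", "label", "hemisphere", "rsn", "x", "y", "z")
  missing_cols <- setdiff(required, names(regions))
  assert_that(length(missing_cols) == 0,
              "parcellation table lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  regions <- as.data.frame(regions)[required]
  regions$id <- as.integer(regions$id)
  if (anyDuplicated(regions$id)) {
    stopf("duplicate region id: %s",
          paste(unique(regions$id[duplicated(regions$id)]), collapse = ", "))
  }
  bad_rsn <- setdiff(unique(regions$rsn), RSN_LEVELS)
  assert_that(length(bad_rsn) == 0, "unknown RSN label: %s",
              paste(bad_rsn, collapse = ", "))
  assert_that(all(regions$hemisphere %in% c("L", "R")),
              "hemisphere must be 'L' or 'R'")
  coords <- as.matrix(regions[, c("x", "y", "z")])
  assert_that(all(is.finite(coords)), "non-finite centroid coordinates")
  nrm <- sqrt(rowSums(coords^2))
  assert_that(all(abs(nrm - 1) <= 1e-6),
              "centroids must lie on the unit sphere (max |norm-1| = %.3g)",
              max(abs(nrm - 1)))
  # renormalize away round-trip noise below the 1e-6 gate
  regions[, c("x", "y", "z")] <- coords / nrm
  structure(regions, class = c("parcellation", "data.frame"),
            n_regions = nrow(regions))
}

#' @rdname parcellation
#' @param parc A `parcellation`.
#' @export
n_regions <- function(parc) attr(parc, "n_regions")

#' Read a parcellation from a tab-delimited file
#'
#' Expects a header line `id label hemisphere rsn x y z` (tab-separated).
#' Centroids within 1e-6 of unit norm are renormalized exactly onto the
#' sphere; anything farther off, a duplicated id, or an unknown RSN label is
#' an error.
#'
#' @param path Path to the file.
#' @return A [parcellation()].
#' @export
load_parcellation <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  parcellation(tab)
}

#' Write a parcellation to a tab-delimited file
#'
#' @param parc A [parcellation()].
#' @param path Output path.
#' @export
write_parcellation <- function(parc, path) {
  utils::write.table(as.data.frame(parc), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d regions, %d RSNs, hemispheres L=%d R=%d\n",
              n_regions(x), length(unique(x$rsn)),
              sum(x$hemisphere == "L"), sum(x$hemisphere == "R")))
  invisible(x)
}

#' Canonical edge index of the upper triangle
#'
#' Enumerates the `N(N-1)/2` unordered region pairs (i, j), i < j, in
#' row-major upper-triangle order: (1,2), (1,3), ..., (1,N), (2,3), ...
#' This single canonical order makes ICC ranks, edge selections and PCA
#' loadings comparable across runs; for the 200-region parcellation it has
#' 19,900 edges.
#'
#' @param parc A [parcellation()] or a single region count.
#' @return An `edge_index`: data frame with columns `edge` (1-based edge id),
#'   `i`, `j` (1-based region row indices), and attribute `n_edges`.
#' @examples
#' idx <- build_edge_index(5)
#' n_edges(idx)  # 10
#' @export
build_edge_index <- function(parc) {
  n <- if (inherits(parc, "parcellation")) n_regions(parc) else as.integer(parc)
  assert_that(n >= 2, "need at least 2 regions")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  idx <- data.frame(edge = seq_along(i), i = i, j = j)
  structure(idx, class = c("edge_index", "data.frame"),
            n_edges = nrow(idx), n_regions = n)
}

#' @rdname build_edge_index
#' @param idx An `edge_index`.
#' @export
n_edges <- function(idx) attr(idx, "n_edges")

# Map region pairs (i, j), i < j, to their row-major upper-triangle edge id.
pair_to_edge <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1L) * n - lo * (lo - 1L) / 2L + (hi - lo)
}

#' Unordered RSN-pair label of every edge
#'
#' Labels each edge by the unordered pair of RSNs its endpoint regions belong
#' to (e.g. `"DMN-LIM"`; 28 possible labels for 7 RSNs: 7 within-network and
#' 21 between-network pairs). Labels are ordered by the canonical RSN order
#' (Vis, SM, DA, VA, LIM, FPN, DMN), so `DMN-LIM` and `LIM-DMN` edges share
#' the label `"LIM-DMN"`.
#'
#' @param idx An [build_edge_index()] edge index.
#' @param parc The matching [parcellation()].
#' @return Character vector of length `n_edges(idx)`.
#' @export
edge_rsn_labels <- function(idx, parc) {
  assert_that(attr(idx, "n_regions") == n_regions(parc),
              "edge index and parcellation disagree on region count")
  r <- factor(parc$rsn, levels = RSN_LEVELS)
  ri <- as.integer(r)[idx$i]
  rj <- as.integer(r)[idx$j]
  lo <- pmin(ri, rj); hi <- pmax(ri, rj)
  paste(RSN_LEVELS[lo], RSN_LEVELS[hi], sep = "-")
}

#' All 28 unordered RSN-pair labels in canonical order
#' @return Character vector of length 28.
#' @export
rsn_pair_levels <- function() {
  k <- length(RSN_LEVELS)
  out <- character(0)
  for (a in seq_len(k)) for (b in a:k) {
    out <- c(out, paste(RSN_LEVELS[a], RSN_LEVELS[b], sep = "-"))
  }
  out
}
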