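#' Parcellated BOLD time series for one subject
#'
#' @param data Numeric matrix, regions x timepoints (rows in parcellation
#'   order).
#' @param subject_id Subject identifier string.
#' @param condition `"psilocybin"` or `"placebo"`.
#' @param motion Nonnegative scalar motion covariate (count of
#'   motion-artifact volumes).
#' @param parc The [parcellation()] the rows refer to.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, subject_id, condition = c("psilocybin", "placebo"),
                      motion = 0, parc = NULL) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (!is.null(parc)) {
    assert_that(nrow(data) == n_regions(parc),
                "time series has %d rows but parcellation has %d regions",
                nrow(data), n_regions(parc))
  }
  if (anyNA(data) || !all(is.finite(data))) {
    bad <- which(apply(data, 1L, function(r) anyNA(r) || !all(is.finite(r))))
    stopf("missing or non-finite values in region(s): %s",
          paste(bad, collapse = ", "))
  }
  assert_that(ncol(data) >= 4, "need at least 4 timepoints, got %d", ncol(data))
  assert_that(is.numeric(motion) && length(motion) == 1 && motion >= 0,
              "motion must be a nonnegative scalar")
  structure(list(data = data, subject_id = as.character(subject_id),
                 condition = condition, motion = as.numeric(motion)),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> subject %s (%s): %d regions x %d timepoints, motion %g\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$motion))
  invisible(x)
}

#' Read one subject's regional time series from a delimited file
#'
#' The file holds a plain numeric matrix (tab-delimited, no header), one row
#' per region in parcellation order. Missing values are a hard error naming
#' the offending region; subjects with incomplete series should be excluded
#' upstream rather than imputed.
#'
#' @param path Path to the matrix file.
#' @param parc The [parcellation()] the rows must match.
#' @param subject_id,condition,motion Metadata, see [parcel_ts()].
#' @return A [parcel_ts()].
#' @export
load_timeseries <- function(path, parc, subject_id = basename(path),
                            condition = "psilocybin", motion = 0) {
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  parcel_ts(mat, subject_id = subject_id, condition = condition,
            motion = motion, parc = parc)
}

#' Split a time series into two equal halves
#'
#' Samples `1..floor(T/2)` form the first half and
#' `floor(T/2)+1 .. 2*floor(T/2)` the second; when `T` is odd the final
#' sample is dropped so both halves have equal length (an unbiased basis for
#' Iself).
#'
#' @param ts A [parcel_ts()].
#' @return A list with elements `first` and `second`, both `parcel_ts`.
#' @export
split_halves <- function(ts) {
  tp <- ncol(ts$data)
  assert_that(tp >= 8, "need at least 8 timepoints to split, got %d", tp)
  h <- tp %/% 2L
  mk <- function(cols) {
    out <- ts
    out$data <- ts$data[, cols, drop = FALSE]
    out
  }
  list(first = mk(seq_len(h)), second = mk(h + seq_len(h)))
}

#' Pearson functional connectome of a time series
#'
#' @param ts A [parcel_ts()] (or plain regions x timepoints matrix).
#' @param half_tag One of `"first"`, `"second"`, `"full"`; recorded on the
#'   result.
#' @return A `functional_connectome`: symmetric N x N matrix of Pearson
#'   correlations with unit diagonal, attributes `half_tag`, `subject_id`,
#'   `condition`.
#' @export
compute_fc <- function(ts, half_tag = c("full", "first", "second")) {
  half_tag <- match.arg(half_tag)
  data <- if (inherits(ts, "parcel_ts")) ts$data else as.matrix(ts)
  v <- apply(data, 1L, stats::var)
  if (any(v == 0)) {
    stopf("zero-variance time series in region(s): %s",
          paste(which(v == 0), collapse = ", "))
  }
  m <- stats::cor(t(data))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  structure(m, class = c("functional_connectome", class(m)),
            half_tag = half_tag,
            subject_id = if (inherits(ts, "parcel_ts")) ts$subject_id else NA_character_,
            condition = if (inherits(ts, "parcel_ts")) ts$condition else NA_character_)
}

#' First-half, second-half and full-scan connectomes of one subject
#'
#' @param ts A [parcel_ts()].
#' @return An `fc_pair`: list with `first`, `second`, `full` connectomes plus
#'   `subject_id`, `condition`, `motion`.
#' @export
fc_pair <- function(ts) {
  halves <- split_halves(ts)
  structure(list(first = compute_fc(halves$first, "first"),
                 second = compute_fc(halves$second, "second"),
                 full = compute_fc(ts, "full"),
                 subject_id = ts$subject_id, condition = ts$condition,
                 motion = ts$motion),
            class = "fc_pair")
}

#' Vectorize the upper triangle of a connectome
#'
#' Extracts edge values in canonical row-major upper-triangle order, so that
#' `v[e] = matrix[i_e, j_e]` for edge `e = (i_e, j_e)`.
#'
#' @param fc A square symmetric matrix (e.g. a `functional_connectome`).
#' @param idx The matching [build_edge_index()].
#' @return Numeric vector of length `n_edges(idx)`.
#' @export
vectorize_edges <- function(fc, idx) {
  assert_that(nrow(fc) == attr(idx, "n_regions"),
              "matrix is %d x %d but edge index expects %d regions",
              nrow(fc), ncol(fc), attr(idx, "n_regions"))
  as.numeric(fc[cbind(idx$i, idx$j)])
}

#' Rebuild the symmetric unit-diagonal matrix from an edge vector
#'
#' Inverse of [vectorize_edges()].
#'
#' @param v Edge vector in canonical order.
#' @param idx The matching [build_edge_index()].
#' @param diag Value for the diagonal (1 for correlation matrices).
#' @return Symmetric N x N matrix.
#' @export
unvectorize_edges <- function(v, idx, diag = 1) {
  n <- attr(idx, "n_regions")
  assert_that(length(v) == n_edges(idx),
              "edge vector has length %d, expected %d", length(v), n_edges(idx))
  m <- matrix(0, n, n)
  m[cbind(idx$i, idx$j)] <- v
  m <- m + t(m)
  diag(m) <- diag
  m
}

#' Load a cohort manifest and build split-half connectomes
#'
#' The manifest is a CSV with columns `subject_id,condition,motion,
#' timeseries_path` (paths relative to the manifest's directory or absolute).
#'
#' @param manifest Path to the manifest CSV.
#' @param parc The [parcellation()].
#' @return Named list of [fc_pair()] objects, one per subject.
#' @export
load_cohort_fcs <- function(manifest, parc) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  required <- c("subject_id", "condition", "motion", "timeseries_path")
  assert_that(all(required %in% names(tab)),
              "manifest must have columns %s", paste(required, collapse = ","))
  base <- dirname(normalizePath(manifest))
  pairs <- lapply(seq_len(nrow(tab)), function(r) {
    p <- tab$timeseries_path[r]
    if (!file.exists(p)) p <- file.path(base, p)
    ts <- load_timeseries(p, parc, subject_id = tab$subject_id[r],
                          condition = tab$condition[r], motion = tab$motion[r])
    fc_pair(ts)
  })
  names(pairs) <- tab$subject_id
  pairs
}

# Stack one half's edge vectors into a subjects x edges matrix.
edge_matrix <- function(pairs, idx, which = c("full", "first", "second")) {
  which <- match.arg(which)
  out <- t(vapply(pairs, function(p) vectorize_edges(p[[which]], idx),
                  numeric(n_edges(idx))))
  rownames(out) <- vapply(pairs, `[[`, character(1), "subject_id")
  out
}
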