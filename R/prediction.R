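#' Read a behavioral table of 11 altered-states subscale scores
#'
#' CSV with header `subject_id,UN,SP,BS,IS,DB,IC,AX,CI,EI,SY,CM`: the 11
#' subdimensions of the retrospective altered-states-of-consciousness
#' questionnaire, one row per treated subject.
#'
#' @param path CSV path.
#' @return Data frame with rownames = subject ids and the 11 subscale
#'   columns in fixed order.
#' @export
load_behavior <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(identical(names(tab), c("subject_id", ASC_SUBSCALES)),
              "behavior file must have columns subject_id,%s",
              paste(ASC_SUBSCALES, collapse = ","))
  out <- tab[, ASC_SUBSCALES]
  rownames(out) <- tab$subject_id
  assert_that(!anyNA(out), "behavior table contains missing values")
  out
}

#' PCA of the behavioral subscale table
#'
#' Columns are z-scored (subscales are on heterogeneous scales), then
#' decomposed by singular-value decomposition. The first component's subject
#' scores, `b`, summarize the overall intensity of the drug experience; its
#' sign is fixed so that the coefficient sum is positive, making high `b`
#' mean an intense experience.
#'
#' @param table Subjects x 11 numeric table (e.g. from [load_behavior()]).
#' @return A `behavioral_pca` list: `coefficients` (11 x k loading matrix),
#'   `scores` (subjects x k), `b` (PC1 scores), `variance_explained`.
#' @export
behavioral_pca <- function(table) {
  x <- as.matrix(table)
  assert_that(nrow(x) >= 3, "need at least 3 subjects, got %d", nrow(x))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stopf("constant behavioral column(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  if (sum(pc$rotation[, 1L]) < 0) {
    pc$rotation[, 1L] <- -pc$rotation[, 1L]
    pc$x[, 1L] <- -pc$x[, 1L]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coefficients = pc$rotation, scores = pc$x,
                 b = pc$x[, 1L], variance_explained = ve),
            class = "behavioral_pca")
}

#' Select connectome edges for prediction
#'
#' Either the deterministic top-`n` edges of an ICC ranking (ties broken by
#' ascending edge id) or a seeded uniform random sample without replacement.
#'
#' @param method `"icc_ranked"` or `"random"`.
#' @param n Number of edges (3 <= n <= n_edges).
#' @param idx The [build_edge_index()].
#' @param icc [edgewise_icc()] result or per-edge vector (required for
#'   `"icc_ranked"`).
#' @param seed Integer seed (required for `"random"`).
#' @return An `edge_selection` list: `edges` (integer ids), `method`, `n`,
#'   `seed`.
#' @export
select_edges <- function(method = c("icc_ranked", "random"), n, idx,
                         icc = NULL, seed = NULL) {
  method <- match.arg(method)
  ne <- n_edges(idx)
  assert_that(n >= 3 && n <= ne, "n must lie in [3, %d], got %d", ne, n)
  edges <- switch(method,
    icc_ranked = {
      v <- if (inherits(icc, "icc_result")) icc$icc else icc
      assert_that(!is.null(v) && length(v) == ne,
                  "icc_ranked selection needs a full per-edge ICC vector")
      order(-v, seq_len(ne))[seq_len(n)]
    },
    random = {
      assert_that(!is.null(seed), "random selection needs a seed")
      with_seed(seed, sample.int(ne, n))
    })
  structure(list(edges = as.integer(edges), method = method,
                 n = as.integer(n),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "edge_selection")
}

#' PCA of selected connectome edges across subjects
#'
#' Decomposes the subjects x edges matrix of full-scan connectivity values
#' restricted to an edge selection. Columns are mean-centered but not
#' rescaled (all edges already share the correlation scale); components come
#' from singular-value decomposition. Each component's sign is fixed so its
#' largest-magnitude loading is positive. The subject scores of PC1-3 are
#' the predictors x, y, z.
#'
#' @param edge_values Subjects x n_edges matrix of full-scan edge vectors
#'   (see [edge_matrix()] via [load_cohort_fcs()]), or a matrix already
#'   restricted to the selection.
#' @param sel An [select_edges()] selection, or `NULL` if `edge_values` is
#'   already restricted.
#' @param k Number of leading components to report as predictors
#'   (default 3; must satisfy `k <= min(s - 1, n)`).
#' @return An `edge_pca` list: `loadings` (n x k), `scores` (s x k, columns
#'   `PC1..PCk`), `variance_explained` (all components), `k`, `selection`.
#' @export
edge_pca <- function(edge_values, sel = NULL, k = 3) {
  x <- as.matrix(edge_values)
  if (!is.null(sel)) x <- x[, sel$edges, drop = FALSE]
  s <- nrow(x); n <- ncol(x)
  kmax <- min(s - 1L, n)
  assert_that(k >= 1 && k <= kmax,
              "k = %d exceeds min(s - 1, n) = %d", k, kmax)
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  ncomp <- max(ncomp, k)
  d <- sv$d[seq_len(ncomp)]
  u <- sv$u[, seq_len(ncomp), drop = FALSE]
  v <- sv$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest-|loading| entry positive, per component
  for (c in seq_len(ncomp)) {
    peak <- which.max(abs(v[, c]))
    if (v[peak, c] < 0) {
      v[, c] <- -v[, c]
      u[, c] <- -u[, c]
    }
  }
  scores <- u %*% diag(d, ncomp)
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  rownames(scores) <- rownames(x)
  colnames(v) <- paste0("PC", seq_len(ncomp))
  ve <- sv$d^2 / sum(sv$d^2)
  structure(list(loadings = v[, seq_len(k), drop = FALSE],
                 loadings_all = v, scores_all = scores,
                 scores = scores[, seq_len(k), drop = FALSE],
                 center = center, variance_explained = ve, k = as.integer(k),
                 selection = sel),
            class = "edge_pca")
}

#' Ordinary least-squares prediction of b from edge-PC scores
#'
#' Fits `b ~ predictors` with an intercept. For multi-predictor models the
#' overall p comes from the F test; for a single predictor it is the
#' correlation t-test p (identical to the slope test).
#'
#' @param b Response vector (behavioral PC1 scores).
#' @param predictors Numeric matrix or vector of subject-level predictor
#'   scores (e.g. columns of `edge_pca()$scores`).
#' @return A `model_fit` list: `coefficients`, `r_squared`, `p`,
#'   `predictors` (names), `df`.
#' @export
fit_linear_model <- function(b, predictors) {
  x <- as.matrix(predictors)
  assert_that(nrow(x) == length(b), "predictors and b disagree on subjects")
  assert_that(length(b) >= ncol(x) + 1,
              "need at least as many subjects as predictors + 1")
  if (is.null(colnames(x))) colnames(x) <- paste0("PC", seq_len(ncol(x)))
  fit <- stats::lm(b ~ x)
  assert_that(!any(is.na(stats::coef(fit))),
              "collinear predictors: rank-deficient design")
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (fit$df.residual == 0) {
    # saturated model (e.g. s - 1 predictors): R-squared 1, no valid p
    p <- NA_real_
  } else if (ncol(x) == 1) {
    p <- stats::cor.test(b, x[, 1L])$p.value
  } else {
    f <- sm$fstatistic
    p <- stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE)
  }
  structure(list(coefficients = stats::coef(fit), r_squared = unname(r2),
                 p = unname(p), predictors = colnames(x),
                 df = fit$df.residual),
            class = "model_fit")
}

#' Idiosyncrasy-informed prediction sweep over edge counts
#'
#' For every n in the grid: (a) fits `b ~ x + y + z` (the first k edge-PC
#' scores) on the top-n ICC-ranked edges, (b) fits the same model on
#' `ensemble_size` random edge selections (and optionally spin-rotation
#' surrogates, which keep the top-n edge set but read connectivity through a
#' spatial-contiguity-preserving region permutation), and (c) fits the
#' single-predictor models `b ~ x`, `b ~ y`, `b ~ z` on the ICC-ranked
#' selection. The whole sweep is a pure function of its inputs and `seed`.
#'
#' @param edge_values Subjects x n_edges matrix of full-scan edge vectors
#'   (treated-condition subjects).
#' @param icc [edgewise_icc()] result (or per-edge vector) that ranks edges.
#' @param b Behavioral PC1 scores, aligned with `edge_values` rows.
#' @param idx The [build_edge_index()].
#' @param n_grid Edge-count grid (default `seq(250, n_edges, 250)` plus a
#'   final all-edges point).
#' @param k Number of edge-PC predictors (default 3).
#' @param ensembles Character subset of `c("random", "spin")`.
#' @param ensemble_size Models per ensemble per n (default 100).
#' @param seed Master seed for all ensemble randomness.
#' @param parc Parcellation; required when `"spin"` is in `ensembles`.
#' @return A `prediction_sweep` list: `fits` (long data frame with columns
#'   `n`, `model` in icc_ranked/random/spin/single_PC1..k, `replicate`,
#'   `r_squared`, `p`), `n_grid`, `k`, `ensemble_size`, `seed`.
#' @export
prediction_sweep <- function(edge_values, icc, b, idx, n_grid = NULL, k = 3,
                             ensembles = "random", ensemble_size = 100,
                             seed = 1, parc = NULL) {
  ne <- n_edges(idx)
  v_icc <- if (inherits(icc, "icc_result")) icc$icc else icc
  if (is.null(n_grid)) n_grid <- unique(c(seq(250L, ne, by = 250L), ne))
  n_grid <- as.integer(n_grid)
  assert_that(min(n_grid) >= k + 1 && max(n_grid) <= ne,
              "n_grid must lie within [k + 1, %d]", ne)
  assert_that(all(ensembles %in% c("random", "spin")),
              "ensembles must be a subset of random, spin")
  if ("spin" %in% ensembles) {
    assert_that(!is.null(parc), "spin ensemble needs a parcellation")
  }
  seeds <- child_seeds(seed, length(n_grid) * ensemble_size * 2L)
  seed_mat <- matrix(seeds, ncol = 2L)
  rows <- list(); si <- 0L
  add <- function(n, model, rep, fit) {
    rows[[length(rows) + 1L]] <<- data.frame(
      n = n, model = model, replicate = rep,
      r_squared = fit$r_squared, p = fit$p)
  }
  spin_cache <- NULL
  if ("spin" %in% ensembles) {
    spin_seeds <- child_seeds(seed + 1L, ensemble_size)
    spin_cache <- lapply(spin_seeds, function(sd) spin_permutation(parc, seed = sd))
  }
  for (gi in seq_along(n_grid)) {
    n <- n_grid[gi]
    sel <- select_edges("icc_ranked", n, idx, icc = v_icc)
    pca <- edge_pca(edge_values, sel, k = k)
    add(n, "icc_ranked", 0L, fit_linear_model(b, pca$scores))
    for (c in seq_len(k)) {
      add(n, paste0("single_PC", c), 0L,
          fit_linear_model(b, pca$scores[, c, drop = FALSE]))
    }
    for (r in seq_len(ensemble_size)) {
      si <- (gi - 1L) * ensemble_size + r
      rsel <- select_edges("random", n, idx, seed = seed_mat[si, 1L])
      rpca <- edge_pca(edge_values, rsel, k = k)
      add(n, "random", r, fit_linear_model(b, rpca$scores))
      if ("spin" %in% ensembles) {
        perm <- spin_cache[[r]]
        pe <- permuted_edge_values(edge_values, sel$edges, perm, idx)
        spca <- edge_pca(pe, NULL, k = k)
        add(n, "spin", r, fit_linear_model(b, spca$scores))
      }
    }
  }
  structure(list(fits = do.call(rbind, rows), n_grid = n_grid,
                 k = as.integer(k), ensemble_size = as.integer(ensemble_size),
                 ensembles = ensembles, seed = seed),
            class = "prediction_sweep")
}

# Read the selected edges of each subject through a region permutation:
# edge (i, j) is looked up at (perm[i], perm[j]) in the full connectome.
permuted_edge_values <- function(edge_values, edges, perm, idx) {
  n <- attr(idx, "n_regions")
  pi_ <- perm[idx$i[edges]]
  pj <- perm[idx$j[edges]]
  ids <- pair_to_edge(pi_, pj, n)
  edge_values[, ids, drop = FALSE]
}

#' Compare ICC-ranked models against their null ensemble
#'
#' Per grid point, a two-sided one-sample t-test of the ensemble R-squared
#' values against the ICC-ranked model's R-squared as the reference mean,
#' Benjamini-Hochberg corrected across the grid. A degenerate ensemble whose
#' values all equal the reference yields t = 0, p = 1.
#'
#' @param sweep A [prediction_sweep()].
#' @param ensemble Which ensemble to test (`"random"` or `"spin"`).
#' @return Data frame: `n`, `r2_icc`, `r2_ensemble_mean`, `t`, `p`, `p_adj`.
#' @export
ensemble_comparison <- function(sweep, ensemble = "random") {
  fits <- sweep$fits
  assert_that(ensemble %in% fits$model, "ensemble '%s' not present", ensemble)
  rows <- lapply(sweep$n_grid, function(n) {
    ref <- fits$r_squared[fits$n == n & fits$model == "icc_ranked"]
    ens <- fits$r_squared[fits$n == n & fits$model == ensemble]
    assert_that(length(ens) >= 2, "ensemble size must be >= 2")
    if (stats::sd(ens) == 0) {
      tt <- list(statistic = 0, p.value = if (isTRUE(all.equal(mean(ens), ref))) 1 else 0)
    } else {
      tt <- stats::t.test(ens, mu = ref)
    }
    data.frame(n = n, r2_icc = ref, r2_ensemble_mean = mean(ens),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
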