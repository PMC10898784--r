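#' Configuration of the synthetic two-condition cohort
#'
#' The generator emulates the statistical skeleton of a placebo-controlled
#' psilocybin fMRI study: 21 treated and 25 placebo subjects, 200 cortical
#' regions in 7 RSNs, per-subject stationary Gaussian BOLD with a
#' subject-stable covariance made of (i) a block base structure shared by
#' everyone, (ii) an idiosyncratic subject-fixed perturbation localized on
#' condition-specific signature RSNs (FPN under placebo; DMN and Vis under
#' the drug), and (iii) for treated subjects a latent experience-intensity
#' score `b_true` linearly coupled to a fixed DMN-centric edge pattern
#' (negative on within-DMN and DMN-LIM edges, positive on DMN-DA and DMN-VA
#' edges, heavy-tailed magnitudes, unit Frobenius norm), and (iv) a
#' half-specific low-rank "scan state" component that makes unselected
#' edges carry temporally unstable between-subject variance. An 11-subscale
#' behavioral table with a dominant all-positive first component is derived
#' from `b_true`, and the motion covariate is drawn with a higher mean in
#' the drug condition.
#'
#' @param seed Master seed; every downstream draw derives from it.
#' @param s_psilocybin,s_placebo Subjects per condition.
#' @param n_regions Total region count; `rsn_counts` must sum to it.
#' @param rsn_counts Named integer vector of per-RSN region counts.
#' @param timepoints Scan length T (split-half analyses use T/2 each).
#' @param rho_within,rho_between Base correlation inside / between RSNs.
#' @param alpha Named per-condition strength of the idiosyncratic
#'   perturbation (entry SD of the signature-edge noise).
#' @param signature Named list of RSN sets carrying each condition's
#'   idiosyncratic perturbation.
#' @param beta Coupling of `b_true` to the planted pattern (per-edge effect
#'   is `beta * b_true / sqrt(2 * n_pattern_edges)`).
#' @param behavior_lambda Positive 11-vector of subscale loadings on the
#'   latent intensity.
#' @param behavior_noise SD of subscale measurement noise.
#' @param motion_mean Named per-condition mean motion-artifact volume count.
#' @param motion_sd SD of the motion draw.
#' @param state_strength Per-edge SD of the half-specific "scan state"
#'   covariance component (a low-rank Wishart perturbation redrawn for each
#'   scan half, emulating slow arousal/vigilance drift). It inflates
#'   between-subject connectivity variance everywhere while staying
#'   temporally unstable, so it dilutes non-idiosyncratic edge selections
#'   without inflating ICC.
#' @param state_rank Rank of the state component per half.
#' @param pattern_concentration Lognormal sdlog of the planted pattern's
#'   weight magnitudes (see [planted_pattern()]).
#' @param eig_floor Eigenvalue floor for the positive-definiteness repair.
#' @param planted_n Edge count at which the planted signal is meant to be
#'   detected by the prediction sweep (recorded in the ground truth).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       s_psilocybin = 21, s_placebo = 25,
                       n_regions = 200,
                       rsn_counts = NULL,
                       timepoints = 256,
                       rho_within = 0.35, rho_between = 0.05,
                       alpha = c(psilocybin = 0.10, placebo = 0.08),
                       signature = list(psilocybin = c("DMN", "Vis"),
                                        placebo = "FPN"),
                       beta = 5,
                       behavior_lambda = c(1.2, 0.8, 1.1, 1.3, 0.9, 0.7,
                                           0.5, 1.0, 0.9, 0.6, 1.1),
                       behavior_noise = 0.3,
                       motion_mean = c(psilocybin = 8, placebo = 5),
                       motion_sd = 2,
                       state_strength = 0.15,
                       state_rank = 5,
                       pattern_concentration = 1,
                       eig_floor = 1e-4,
                       planted_n = 1000) {
  if (is.null(rsn_counts)) {
    rsn_counts <- round(c(Vis = 30, SM = 34, DA = 26, VA = 24, LIM = 12,
                          FPN = 30, DMN = 44) * n_regions / 200)
  }
  assert_that(sum(rsn_counts) == n_regions,
              "rsn_counts sum to %d, expected %d", sum(rsn_counts), n_regions)
  assert_that(identical(sort(names(rsn_counts)), sort(RSN_LEVELS)),
              "rsn_counts must name the 7 RSNs")
  assert_that(all(alpha >= 0) && beta >= 0, "strengths must be nonnegative")
  assert_that(length(behavior_lambda) == 11 && all(behavior_lambda > 0),
              "behavior_lambda must be 11 positive loadings")
  assert_that(all(unlist(signature) %in% RSN_LEVELS),
              "signature sets must use known RSN labels")
  assert_that(timepoints >= 8, "need at least 8 timepoints")
  structure(list(seed = as.integer(seed),
                 s_psilocybin = as.integer(s_psilocybin),
                 s_placebo = as.integer(s_placebo),
                 n_regions = as.integer(n_regions),
                 rsn_counts = rsn_counts[RSN_LEVELS],
                 timepoints = as.integer(timepoints),
                 rho_within = rho_within, rho_between = rho_between,
                 alpha = alpha, signature = signature, beta = beta,
                 behavior_lambda = behavior_lambda,
                 behavior_noise = behavior_noise,
                 motion_mean = motion_mean, motion_sd = motion_sd,
                 state_strength = state_strength,
                 state_rank = as.integer(state_rank),
                 pattern_concentration = pattern_concentration,
                 eig_floor = eig_floor, planted_n = as.integer(planted_n)),
            class = "sim_config")
}

#' Deterministic synthetic parcellation
#'
#' Regions are split evenly between hemispheres per RSN (an odd count puts
#' the extra region on the left); centroids come from a Fibonacci spiral
#' lattice restricted to the left (x < 0) half of the unit sphere, mirrored
#' in x for the right hemisphere, so RSNs occupy spatially contiguous bands
#' and the spin null has honest geometry. Seedless and fully deterministic.
#'
#' @param config A [sim_config()].
#' @return A [parcellation()] with regions ordered L then R, RSNs in
#'   canonical order within each hemisphere.
#' @export
make_parcellation <- function(config) {
  counts <- config$rsn_counts
  n_l <- ceiling(counts / 2)
  n_r <- counts - n_l
  h <- sum(n_l)
  lat <- fibonacci_hemisphere(max(h, sum(n_r)))
  build_side <- function(side_counts, hemi, sgn) {
    pts <- lat[seq_len(sum(side_counts)), , drop = FALSE]
    pts[, 1L] <- sgn * pts[, 1L]
    rsn <- rep(names(side_counts), side_counts)
    data.frame(label = paste(hemi, rsn, unlist(lapply(side_counts, seq_len)),
                             sep = "_"),
               hemisphere = hemi, rsn = rsn,
               x = pts[, 1L], y = pts[, 2L], z = pts[, 3L])
  }
  tab <- rbind(build_side(n_l, "L", 1), build_side(n_r, "R", -1))
  tab <- cbind(id = seq_len(nrow(tab)), tab)
  parcellation(tab)
}

# Fibonacci spiral lattice on the x < 0 hemisphere of the unit sphere.
fibonacci_hemisphere <- function(m) {
  i <- seq_len(m)
  x <- -(2 * i - 1) / (2 * m)          # uniform in (-1, 0)
  r <- sqrt(pmax(0, 1 - x^2))
  golden <- pi * (3 - sqrt(5))
  cbind(x = x, y = r * cos(i * golden), z = r * sin(i * golden))
}

#' Subject-level target correlation matrix
#'
#' Builds `Sigma = C_base(rho_w, rho_b) + alpha_c * W + beta * b_true * P`,
#' where `W` is a subject-fixed symmetric Gaussian perturbation supported on
#' the condition's signature-RSN edges and `P` is the fixed unit-Frobenius
#' DMN-centric pattern; eigenvalues are clipped at the configured floor and
#' the result rescaled to unit diagonal so it is a samplable correlation
#' matrix.
#'
#' @param config A [sim_config()].
#' @param parc The cohort [parcellation()] (from [make_parcellation()]).
#' @param condition `"psilocybin"` or `"placebo"`.
#' @param b_true Latent intensity score (0 for placebo subjects).
#' @param seed Seed for the subject's `W` draw.
#' @return N x N correlation matrix (unit diagonal, eigenvalues >= floor
#'   before the diagonal rescale).
#' @export
make_subject_covariance <- function(config, parc, condition, b_true = 0,
                                    seed = 1) {
  repair_correlation(subject_sigma_raw(config, parc, condition, b_true, seed),
                     config$eig_floor)
}

# Subject-stable raw covariance: C_base + alpha * W + beta * b_true * P
# (before positive-definiteness repair).
subject_sigma_raw <- function(config, parc, condition, b_true, seed) {
  n <- n_regions(parc)
  base <- base_covariance(config, parc)
  sig <- config$signature[[condition]]
  in_sig <- parc$rsn %in% sig
  w <- matrix(0, n, n)
  if (any(in_sig) && config$alpha[[condition]] > 0) {
    rows <- which(in_sig)
    m <- length(rows)
    g <- with_seed(seed, {
      up <- matrix(0, m, m)
      up[upper.tri(up)] <- stats::rnorm(m * (m - 1) / 2)
      up + t(up)
    })
    w[rows, rows] <- g
  }
  p <- planted_pattern(parc, config$pattern_concentration)
  base + config$alpha[[condition]] * w + config$beta * b_true * p
}

# Half-specific scan-state component: a low-rank Wishart perturbation with
# per-edge SD `state_strength`, redrawn independently for each scan half.
# Being positive semidefinite it never fights the eigenvalue repair, and its
# diagonal inflation is absorbed by the correlation rescale.
state_component <- function(config, n, seed) {
  if (config$state_strength == 0) return(matrix(0, n, n))
  q <- config$state_rank
  s <- with_seed(seed, matrix(stats::rnorm(n * q), n, q))
  config$state_strength / sqrt(q) * tcrossprod(s)
}

# Per-half target covariances of one subject: stable part shared, state
# part redrawn per half.
subject_sigma_halves <- function(config, parc, condition, b_true, seeds) {
  raw <- subject_sigma_raw(config, parc, condition, b_true, seeds[1L])
  n <- nrow(raw)
  lapply(seeds[2:3], function(sd) {
    repair_correlation(raw + state_component(config, n, sd), config$eig_floor)
  })
}

# Shared block-constant base: rho_within inside an RSN, rho_between across.
base_covariance <- function(config, parc) {
  r <- as.integer(factor(parc$rsn, levels = RSN_LEVELS))
  same <- outer(r, r, `==`)
  m <- ifelse(same, config$rho_within, config$rho_between)
  diag(m) <- 1
  m
}

#' Planted behavior-coupled edge pattern
#'
#' The fixed symmetric pattern `P`: negative weights on within-DMN and
#' DMN-LIM edges, positive on DMN-DA and DMN-VA edges, 0 elsewhere,
#' normalized to unit Frobenius norm. Positive `b_true` therefore lowers
#' within-DMN and DMN-LIM connectivity and raises DMN-attentional
#' connectivity. Weight magnitudes are heavy-tailed (lognormal with
#' log-scale SD `concentration`, drawn under a fixed internal seed so the
#' pattern is a deterministic function of the parcellation): as in real
#' effect maps, a minority of edges carries most of the pattern energy,
#' which is what makes reliability-ranked edge selection informative.
#'
#' @param parc The [parcellation()].
#' @param concentration Lognormal sdlog of the weight magnitudes
#'   (0 = uniform magnitudes).
#' @return N x N symmetric matrix with zero diagonal and `||P||_F = 1`.
#' @export
planted_pattern <- function(parc, concentration = 1) {
  n <- n_regions(parc)
  rsn <- parc$rsn
  p <- matrix(0, n, n)
  dmn <- rsn == "DMN"
  fill <- function(a, b, v) {
    p[a, b] <<- v
    p[b, a] <<- v
  }
  fill(dmn, dmn, -1)
  fill(dmn, rsn == "LIM", -1)
  fill(dmn, rsn == "DA", 1)
  fill(dmn, rsn == "VA", 1)
  diag(p) <- 0
  if (concentration > 0) {
    sup <- which(upper.tri(p) & p != 0)
    mag <- with_seed(424243L, exp(concentration * stats::rnorm(length(sup))))
    w <- matrix(0, n, n)
    w[sup] <- mag
    w <- w + t(w)
    p <- p * w
  }
  p / sqrt(sum(p^2))
}

# Clip eigenvalues at `floor`, rescale to unit diagonal.
repair_correlation <- function(m, floor = 1e-4) {
  es <- eigen(m, symmetric = TRUE)
  vals <- pmax(es$values, floor)
  out <- es$vectors %*% (vals * t(es$vectors))
  out <- (out + t(out)) / 2
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out
}

#' Sample a stationary Gaussian regional time series
#'
#' T independent draws from a zero-mean multivariate normal with the given
#' covariance (factorized once by Cholesky).
#'
#' @param sigma Positive-definite N x N covariance.
#' @param timepoints Number of samples T.
#' @param seed Seed for the draw.
#' @return N x T matrix.
#' @export
sample_timeseries <- function(sigma, timepoints, seed = 1) {
  ch <- tryCatch(chol(sigma),
                 error = function(e) stopf("covariance is not positive definite"))
  n <- nrow(sigma)
  z <- with_seed(seed, matrix(stats::rnorm(n * timepoints), n, timepoints))
  crossprod(ch, z)
}

#' Behavioral table from latent intensity scores
#'
#' Each of the 11 subscales loads positively on the (shifted) latent score:
#' `subscale_j = lambda_j * (b_true - min(b_true)) + noise`, clipped at 0.
#' With the default noise this yields a dominant first component with
#' all-positive coefficients, as expected of an intensity-like instrument.
#'
#' @param b_true Latent scores of the treated subjects.
#' @param lambda Positive 11-vector of loadings.
#' @param noise Noise SD.
#' @param seed Seed for the noise draw.
#' @param subject_ids Optional row names.
#' @return Subjects x 11 data frame with the canonical subscale columns.
#' @export
make_behavior <- function(b_true, lambda, noise, seed = 1,
                          subject_ids = NULL) {
  assert_that(all(lambda > 0), "lambda must be positive")
  s <- length(b_true)
  shifted <- b_true - min(b_true)
  eps <- with_seed(seed, matrix(stats::rnorm(s * 11, sd = noise), s, 11))
  tab <- pmax(outer(shifted, lambda) + eps, 0)
  colnames(tab) <- ASC_SUBSCALES
  out <- as.data.frame(tab)
  if (!is.null(subject_ids)) rownames(out) <- subject_ids
  out
}

#' Generate a complete synthetic cohort
#'
#' Draws the full study: parcellation, per-subject covariances and time
#' series for both conditions, motion covariates, the treated-condition
#' behavioral table, and the ground truth (latent scores, planted pattern,
#' signature sets). With `dir` given, writes the file tree the loaders
#' expect: `parcellation.tsv`, `manifest.csv`, `ts/<subject_id>.tsv`,
#' `behavior.csv`, `truth.json`. Regeneration with the same config is
#' byte-identical.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return A `synthetic_cohort` list: `parc`, `subjects` (list of
#'   [parcel_ts()]), `behavior`, `manifest` (data frame), `truth` (list with
#'   `b_true`, `pattern_edges`, `pattern_weights`, `signature`, `planted_n`).
#' @export
generate_cohort <- function(config, dir = NULL) {
  parc <- make_parcellation(config)
  idx <- build_edge_index(parc)
  n_subj <- config$s_psilocybin + config$s_placebo
  seeds <- child_seeds(config$seed, 3L + 5L * n_subj)
  b_true <- with_seed(seeds[1L],
                      stats::rnorm(config$s_psilocybin))
  conditions <- rep(c("psilocybin", "placebo"),
                    c(config$s_psilocybin, config$s_placebo))
  ids <- c(sprintf("psi%02d", seq_len(config$s_psilocybin)),
           sprintf("pla%02d", seq_len(config$s_placebo)))
  motion <- with_seed(seeds[2L], {
    mu <- config$motion_mean[conditions]
    round(pmax(0, stats::rnorm(n_subj, mean = mu, sd = config$motion_sd)))
  })
  subjects <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    bt <- if (conditions[s] == "psilocybin") b_true[s] else 0
    ssd <- seeds[3L + (s - 1L) * 5L + 1:5]
    sig <- subject_sigma_halves(config, parc, conditions[s], bt, ssd[1:3])
    t1 <- config$timepoints %/% 2L
    t2 <- config$timepoints - t1
    data <- cbind(sample_timeseries(sig[[1L]], t1, seed = ssd[4L]),
                  sample_timeseries(sig[[2L]], t2, seed = ssd[5L]))
    subjects[[s]] <- parcel_ts(data, ids[s], conditions[s],
                               motion = motion[s], parc = parc)
  }
  names(subjects) <- ids
  behavior <- make_behavior(b_true, config$behavior_lambda,
                            config$behavior_noise, seed = seeds[3L],
                            subject_ids = ids[conditions == "psilocybin"])
  pmat <- planted_pattern(parc, config$pattern_concentration)
  pvec <- vectorize_edges(pmat, idx)
  pattern_edges <- which(pvec != 0)
  truth <- list(b_true = stats::setNames(b_true,
                                         ids[conditions == "psilocybin"]),
                pattern_edges = pattern_edges,
                pattern_weights = pvec[pattern_edges],
                signature = config$signature,
                planted_n = config$planted_n)
  manifest <- data.frame(subject_id = ids, condition = conditions,
                         motion = motion,
                         timeseries_path = file.path("ts", paste0(ids, ".tsv")))
  cohort <- structure(list(parc = parc, subjects = subjects,
                           behavior = behavior, manifest = manifest,
                           truth = truth, config = config),
                      class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d psilocybin, %d placebo), %d regions, T = %d\n",
              length(x$subjects), x$config$s_psilocybin, x$config$s_placebo,
              x$config$n_regions, x$config$timepoints))
  invisible(x)
}

#' Write a synthetic cohort's file tree
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "ts"), recursive = TRUE, showWarnings = FALSE)
  write_parcellation(cohort$parc, file.path(dir, "parcellation.tsv"))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  for (s in cohort$subjects) {
    utils::write.table(format(s$data, digits = 10, trim = TRUE),
                       file.path(dir, "ts", paste0(s$subject_id, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  behav <- cbind(subject_id = rownames(cohort$behavior), cohort$behavior)
  utils::write.csv(behav, file.path(dir, "behavior.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Split a cohort's connectome pairs by condition
#'
#' Convenience wrapper: computes [fc_pair()] for every subject and returns
#' them grouped by condition.
#'
#' @param cohort A [generate_cohort()] result.
#' @return Named list with elements `psilocybin` and `placebo`.
#' @export
cohort_fc_pairs <- function(cohort) {
  pairs <- lapply(cohort$subjects, fc_pair)
  split(pairs, vapply(pairs, `[[`, character(1), "condition"))[
    c("psilocybin", "placebo")]
}
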