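#' Spherical-rotation (spin) permutation of a parcellation
#'
#' Spatial null model for cortical maps: region assignments are shuffled by
#' randomly rotating their spherical centroid projections, which preserves
#' the spatial contiguity of the permuted map. A uniform random rotation
#' (QR-orthonormalized Gaussian matrix, determinant +1) is drawn for the
#' left hemisphere and applied x-mirrored to the right hemisphere, so the
#' permutation never crosses hemispheres. Rotated centroids are matched to
#' original positions by greedy nearest-neighbor assignment without
#' replacement, resolving the regions with the worst nearest-available
#' distance first.
#'
#' @param parc A [parcellation()] with unit-sphere centroids.
#' @param seed Integer seed for the rotation draw.
#' @param rotation Optional 3 x 3 rotation matrix to use for the left
#'   hemisphere instead of a random draw (test hook; the identity matrix
#'   yields the identity permutation).
#' @return Integer vector `perm` of length N: region r of the surrogate map
#'   takes the data of region `perm[r]`; a hemisphere-preserving bijection.
#' @export
spin_permutation <- function(parc, seed = 1, rotation = NULL) {
  coords <- as.matrix(parc[, c("x", "y", "z")])
  hemi <- parc$hemisphere
  assert_that(sum(hemi == "L") >= 2 && sum(hemi == "R") >= 2,
              "each hemisphere needs at least 2 regions")
  rot_l <- if (is.null(rotation)) with_seed(seed, random_rotation()) else rotation
  mirror <- diag(c(-1, 1, 1))
  rot_r <- mirror %*% rot_l %*% mirror
  perm <- integer(nrow(parc))
  for (h in c("L", "R")) {
    rows <- which(hemi == h)
    rot <- if (h == "L") rot_l else rot_r
    rotated <- coords[rows, , drop = FALSE] %*% t(rot)
    perm[rows] <- rows[greedy_match(rotated, coords[rows, , drop = FALSE])]
  }
  perm
}

# Uniform random 3x3 rotation: QR of a Gaussian matrix with the sign of R's
# diagonal absorbed into Q, then determinant forced to +1.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  q
}

# Greedy nearest-neighbor matching without replacement. rotated[r, ] is
# region r's rotated centroid; targets[t, ] the original slots. Returns m
# with m[r] = index of the slot whose original position region r moves onto,
# i.e. surrogate slot t carries region match^{-1}(t). Unmatched regions are
# processed in decreasing order of their nearest-available distance.
greedy_match <- function(rotated, targets) {
  n <- nrow(rotated)
  d <- as.matrix(stats::dist(rbind(rotated, targets)))[seq_len(n),
                                                       n + seq_len(n)]
  assign <- integer(n)
  free_regions <- seq_len(n)
  free_slots <- seq_len(n)
  while (length(free_regions) > 0L) {
    sub <- d[free_regions, free_slots, drop = FALSE]
    nearest <- apply(sub, 1L, min)
    r_pick <- which.max(nearest)
    s_pick <- which.min(sub[r_pick, ])
    assign[free_regions[r_pick]] <- free_slots[s_pick]
    free_regions <- free_regions[-r_pick]
    free_slots <- free_slots[-s_pick]
  }
  # region r sits on slot assign[r]; slot t displays region inverse[t]
  inverse <- integer(n)
  inverse[assign] <- seq_len(n)
  inverse
}
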