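# Spherical parcellation geometry: the scaffold for spatial autocorrelation
# in the synthetic generator and for spin permutations.

#' Construct a parcellation geometry
#'
#' A parcellation geometry holds one representative unit-sphere centroid per
#' cortical parcel. It stands in for the spherical surface projection on
#' which spin permutations rotate parcel labels.
#'
#' @param centroids Numeric matrix, one row per region, three columns; each
#'   row must have unit Euclidean norm (tolerance `1e-9`).
#' @param region_id Character vector of unique region identifiers, one per
#'   centroid row.
#' @return An object of class `ironmap_geometry` with elements `region_id`,
#'   `centroids` and `n_regions`.
#' @export
parcellation_geometry <- function(centroids, region_id = NULL) {
  centroids <- as.matrix(centroids)
  assert_that(ncol(centroids) == 3L, "centroids must have 3 columns")
  n <- nrow(centroids)
  assert_that(n >= 10L, "a parcellation needs at least 10 regions, got %d", n = n)
  region_id <- region_id %||% sprintf("R%03d", seq_len(n))
  region_id <- as.character(region_id)
  assert_that(length(region_id) == n, "one region_id per centroid required")
  assert_that(!anyDuplicated(region_id), "region ids must be unique")
  norms <- sqrt(rowSums(centroids^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop_ironmap("all centroids must lie on the unit sphere (|norm - 1| <= 1e-9)",
                 "ironmap_geometry_error")
  }
  rownames(centroids) <- region_id
  structure(
    list(region_id = region_id, centroids = centroids, n_regions = n),
    class = "ironmap_geometry"
  )
}

#' @export
print.ironmap_geometry <- function(x, ...) {
  cat(sprintf("<ironmap_geometry> %d regions on the unit sphere\n", x$n_regions))
  invisible(x)
}

#' Generate an approximately uniform spherical parcellation
#'
#' Places `n_regions` centroids on the unit sphere with a Fibonacci lattice
#' (approximately evenly spread) and applies a seeded uniform random rotation
#' so different seeds give different, equally well-spread geometries.
#'
#' @param n_regions Number of parcels (>= 10). The study scale is 180
#'   left-hemisphere parcels.
#' @param seed Integer seed; the geometry is deterministic given the seed.
#' @return An `ironmap_geometry`.
#' @examples
#' geom <- generate_parcellation(20, seed = 1)
#' @export
generate_parcellation <- function(n_regions, seed = 1L) {
  assert_that(is.numeric(n_regions) && n_regions >= 10,
              "n_regions must be at least 10")
  n <- as.integer(n_regions)
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  rot <- local_seed(seed, random_rotation())
  pts <- pts %*% t(rot)
  pts <- pts / sqrt(rowSums(pts^2)) # renormalize against rounding drift
  parcellation_geometry(pts, sprintf("R%03d", seq_len(n)))
}

#' Draw a uniform random 3-D rotation
#'
#' Orthogonalizes a Gaussian matrix (QR with sign-fixed diagonal, Haar
#' measure) and forces the determinant to +1 so the result is a proper
#' rotation.
#' @return A 3x3 rotation matrix.
#' @keywords internal
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  q <- q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Great-circle distances between unit vectors
#'
#' @param a,b Matrices of unit row vectors (b defaults to a).
#' @return Matrix of angles in radians, `nrow(a)` x `nrow(b)`.
#' @keywords internal
great_circle_distance <- function(a, b = a) {
  d <- tcrossprod(a, b)
  acos(pmin(pmax(d, -1), 1)) # operand order preserves the dim attribute
}

# Lower-triangular factor of a Gaussian-kernel covariance on great-circle
# distance, unit marginal variance. `ell` is the correlation length in
# radians on the unit sphere.
spatial_covariance_factor <- function(geometry, ell) {
  d <- great_circle_distance(geometry$centroids)
  K <- exp(-d^2 / (2 * ell^2))
  # jitter keeps the factorization stable for near-duplicate centroids
  K <- K + diag(1e-8, nrow(K))
  t(chol(K))
}

#' Sample smooth Gaussian fields on a parcellation
#'
#' Draws fields with unit marginal variance and Gaussian-kernel covariance
#' `exp(-d^2 / (2 ell^2))` in great-circle distance `d`.
#'
#' @param geometry An `ironmap_geometry`.
#' @param n_fields Number of independent fields (columns).
#' @param ell Correlation length in radians (default 0.5).
#' @param seed Optional integer seed.
#' @return `n_regions` x `n_fields` matrix.
#' @export
sample_smooth_fields <- function(geometry, n_fields = 1L, ell = 0.5, seed = NULL) {
  L <- spatial_covariance_factor(geometry, ell)
  z <- local_seed(seed, matrix(stats::rnorm(geometry$n_regions * n_fields),
                               geometry$n_regions, n_fields))
  out <- L %*% z
  rownames(out) <- geometry$region_id
  out
}
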