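# Internal geometry and unit helpers. The package works in mm and kg
# throughout; densities are kg m^-3, so every mass computation funnels
# through mm3_to_m3() and nowhere else.

MM3_TO_M3 <- 1e-9

mm3_to_m3 <- function(volume_mm3) volume_mm3 * MM3_TO_M3

#' Radius of the reflective motion-capture markers (mm)
#'
#' Spherical markers of 12.7 mm diameter are assumed for all captures; the
#' radius matters when a suspension line is reconstructed from markers glued
#' to the string, whose centres sit one radius off the string axis.
#'
#' @return Marker radius in mm (6.35).
#' @export
marker_radius_mm <- function() 6.35

vec3 <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) == 3L)
  x
}

norm3 <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < 1e-12) abort("cannot normalise a near-zero vector", class = "commass_degeneracy")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix about a unit axis, angle in radians.
rotation_about_axis <- function(axis, angle) {
  u <- unit3(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniform random rotation (draws from the current RNG stream).
random_rotation <- function() {
  # QR of a Gaussian matrix with sign fix gives a Haar-distributed rotation
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# A unit vector perpendicular to v (arbitrary but deterministic).
perpendicular_of <- function(v) {
  v <- unit3(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(cross3(v, ref))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          class = "commass_validation")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive", name), class = "commass_validation")
  }
  invisible(x)
}

# Deterministic per-cell seed derivation: master seed plus a counter,
# folded into the 32-bit integer range R's RNG accepts.
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 1009 + as.numeric(counter)) %% 2147483647)
}
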