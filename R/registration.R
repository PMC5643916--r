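#' Rigid transform objects
#'
#' A rigid transform is a proper rotation (3x3, det +1) plus a translation
#' (mm), mapping `p -> rotation %*% p + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- vec3(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    abort("rotation is not orthonormal", class = "commass_validation")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    abort("rotation must be proper (det +1)", class = "commass_validation")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", paste(round(x$translation, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param t A [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation), -t(t$rotation) %*% t$translation)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first Rigid transforms.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  second$rotation %*% first$translation + second$translation)
}

#' Apply a rigid transform to a marker set
#'
#' @param ms A marker set tibble.
#' @param t A [rigid_transform()].
#' @return The transformed marker set; labels and row order unchanged.
#' @export
apply_transform <- function(ms, t) {
  validate_marker_set(ms)
  stopifnot(inherits(t, "rigid_transform"))
  m <- unname(marker_matrix(ms)) %*% t(t$rotation)
  ms$x <- m[, 1] + t$translation[1]
  ms$y <- m[, 2] + t$translation[2]
  ms$z <- m[, 3] + t$translation[3]
  ms
}

# Shared-label coordinate matrices in matching row order.
shared_marker_matrices <- function(source, target) {
  shared <- intersect(source$label, target$label)
  if (length(shared) < 3L) {
    abort("need at least 3 shared marker labels for registration",
          class = "commass_correspondence")
  }
  list(P = marker_matrix(source[match(shared, source$label), ]),
       Q = marker_matrix(target[match(shared, target$label), ]),
       labels = shared)
}

#' Least-squares rigid registration of two labelled marker sets
#'
#' Finds the rotation and translation minimising the sum of squared distances
#' between correspondingly labelled markers (correspondence is by label only),
#' via the closed-form covariance/SVD solution. Reflections are excluded: if
#' the optimal orthogonal matrix has determinant -1 the smallest-singular-value
#' axis is flipped and a warning is emitted, since physical captures cannot be
#' mirrored.
#'
#' @param source,target Marker sets sharing at least 3 non-collinear labels.
#' @return An object of class `rigid_fit`: the `transform` mapping source onto
#'   target, the root-mean-square residual `rmsd` (mm), per-marker residuals,
#'   and the shared labels used. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' ms <- marker_set(LETTERS[1:4],
#'                  x = c(0, 100, 0, 0), y = c(0, 0, 50, 0), z = c(0, 0, 0, 25))
#' t <- rigid_transform(rotation_z(pi / 2), c(10, 0, 0))
#' fit <- fit_rigid_transform(ms, apply_transform(ms, t))
#' fit$rmsd
fit_rigid_transform <- function(source, target) {
  sm <- shared_marker_matrices(source, target)
  P <- sm$P
  Q <- sm$Q
  pbar <- colMeans(P)
  qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar)
  Qc <- sweep(Q, 2, qbar)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-9 * max(sv_p[1], 1)) {
    abort("shared markers are collinear; registration is degenerate",
          class = "commass_degeneracy")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- det(s$v %*% t(s$u))
  if (d < 0) {
    warn("optimal orthogonal map is a reflection; flipping smallest singular axis")
  }
  S <- diag(c(1, 1, sign(d)))
  R <- s$v %*% S %*% t(s$u)
  tr <- qbar - as.numeric(R %*% pbar)
  fitted <- P %*% t(R) + matrix(tr, nrow(P), 3, byrow = TRUE)
  res <- sqrt(rowSums((Q - fitted)^2))
  out <- list(transform = rigid_transform(R, tr),
              rmsd = sqrt(mean(res^2)),
              residuals = tibble::tibble(label = sm$labels, residual = as.numeric(res)),
              n_markers = length(sm$labels))
  class(out) <- "rigid_fit"
  out
}

#' @export
print.rigid_fit <- function(x, ...) {
  cat(sprintf("Rigid registration over %d shared markers; RMSD %.4g mm\n",
              x$n_markers, x$rmsd))
  invisible(x)
}

#' @export
tidy.rigid_fit <- function(x, ...) x$residuals

#' @export
glance.rigid_fit <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_markers = x$n_markers)
}

#' Elementary rotations
#'
#' Convenience constructors for rotations about the coordinate axes (angle in
#' radians).
#'
#' @param angle Rotation angle, radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_z <- function(angle) rotation_about_axis(c(0, 0, 1), angle)

#' @rdname rotation_z
#' @export
rotation_y <- function(angle) rotation_about_axis(c(0, 1, 0), angle)

#' @rdname rotation_z
#' @export
rotation_x <- function(angle) rotation_about_axis(c(1, 0, 0), angle)
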