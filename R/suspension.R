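#' Suspension lines
#'
#' A suspension line is the infinite 3D line of a string from which the
#' specimen hung; at rest it passes through the centre of mass. Lines are kept
#' as a tibble with a point on the line (`px,py,pz`, mm), a unit direction
#' (`dx,dy,dz`) and a `capture_id`, one row per line, so collections of lines
#' from repeated hangs bind together naturally.
#'
#' @param point Length-3 numeric, a point on the line (mm).
#' @param direction Length-3 numeric; normalised internally.
#' @param capture_id Identifier for the capture the line came from.
#' @return A one-row `suspension_lines` tibble.
#' @export
suspension_line <- function(point, direction, capture_id = NA_character_) {
  point <- vec3(point)
  direction <- unit3(vec3(direction))
  out <- tibble::tibble(capture_id = as.character(capture_id),
                        px = point[1], py = point[2], pz = point[3],
                        dx = direction[1], dy = direction[2], dz = direction[3])
  class(out) <- c("suspension_lines", class(out))
  out
}

line_point <- function(lines, i) c(lines$px[i], lines$py[i], lines$pz[i])
line_dir <- function(lines, i) c(lines$dx[i], lines$dy[i], lines$dz[i])

#' Build a suspension line from the two string markers of a capture
#'
#' The line is taken through the two marker centres. Because the markers are
#' glued to the string, their centres sit one marker radius (6.35 mm) off the
#' true string axis; by default the line is left uncorrected, and optionally
#' it can be translated by that radius along a caller-supplied normal (the
#' offset direction is unobservable from two collinear markers).
#'
#' @param ms A marker set containing the string markers.
#' @param labels Labels of the two string markers (default `STR1`, `STR2`).
#' @param correct_radius_offset If `TRUE`, translate the line by the marker
#'   radius along `offset_normal`.
#' @param offset_normal Unit offset direction, required when correcting;
#'   must be perpendicular to the line (its parallel component is removed).
#' @param capture_id Capture identifier; defaults to the set's condition id.
#' @return A one-row `suspension_lines` tibble.
#' @export
line_from_string_markers <- function(ms, labels = c("STR1", "STR2"),
                                     correct_radius_offset = FALSE,
                                     offset_normal = NULL,
                                     capture_id = NULL) {
  validate_marker_set(ms)
  if (!all(labels %in% ms$label)) {
    abort(paste0("string markers not found: ",
                 paste(setdiff(labels, ms$label), collapse = ", ")),
          class = "commass_correspondence")
  }
  m <- marker_matrix(ms[match(labels, ms$label), ])
  sep <- m[2, ] - m[1, ]
  if (norm3(sep) <= 10) {
    abort("string markers are closer than 10 mm; line direction is unreliable",
          class = "commass_degeneracy")
  }
  point <- m[1, ]
  direction <- unit3(sep)
  if (isTRUE(correct_radius_offset)) {
    if (is.null(offset_normal)) {
      abort("offset_normal must be supplied to correct the marker-radius offset",
            class = "commass_validation")
    }
    n <- vec3(offset_normal)
    n <- n - sum(n * direction) * direction
    point <- point + marker_radius_mm() * unit3(n)
  }
  capture_id <- capture_id %||% attr(ms, "condition_id") %||% NA_character_
  suspension_line(point, direction, capture_id)
}

#' Closest point of approach between two 3D lines
#'
#' Two lines in 3D almost never intersect; the standard skew-line solution
#' gives the unique pair of mutually closest points, whose connecting segment
#' is perpendicular to both lines. Their midpoint is the pairwise CoM estimate
#' used by the suspension method.
#'
#' @param a,b One-row `suspension_lines` tibbles (or any row with the same
#'   columns).
#' @param parallel_tol Reject pairs whose unit-direction cross product has
#'   norm below this (default 1e-8).
#' @return A list with `point_a`, `point_b`, `midpoint` (mm) and `gap`, the
#'   minimum inter-line distance (mm).
#' @export
#' @examples
#' a <- suspension_line(c(0, 0, 0), c(1, 0, 0))
#' b <- suspension_line(c(0, 0, 1), c(0, 1, 0))
#' closest_point_of_approach(a, b)$midpoint  # (0, 0, 0.5)
closest_point_of_approach <- function(a, b, parallel_tol = 1e-8) {
  p1 <- line_point(a, 1); d1 <- line_dir(a, 1)
  p2 <- line_point(b, 1); d2 <- line_dir(b, 1)
  cr <- cross3(d1, d2)
  if (norm3(cr) <= parallel_tol) {
    w <- p2 - p1
    perp <- norm3(w - sum(w * d1) * d1)
    abort(sprintf("lines are parallel (perpendicular distance %.4g mm)", perp),
          class = "commass_degeneracy")
  }
  w0 <- p1 - p2
  b_ <- sum(d1 * d2)
  d_ <- sum(d1 * w0)
  e_ <- sum(d2 * w0)
  denom <- 1 - b_^2
  s <- (b_ * e_ - d_) / denom
  t <- (e_ - b_ * d_) / denom
  pa <- p1 + s * d1
  pb <- p2 + t * d2
  list(point_a = pa, point_b = pb, midpoint = (pa + pb) / 2,
       gap = norm3(pa - pb))
}

#' Estimate CoM from a collection of suspension lines
#'
#' Every unordered pair of lines contributes one CoM estimate: the midpoint of
#' the pair's closest points of approach. The overall suspension CoM is the
#' unweighted mean of all pair midpoints (n lines give choose(n, 2) pairs: 3
#' for 3 lines, 45 for 10). Near-parallel pairs cannot localise a point along
#' the lines and are skipped with a warning, never silently dropped. An
#' optional inverse-gap weighting is available but off by default, matching
#' the plain protocol.
#'
#' @param lines A `suspension_lines` tibble with at least 2 usable lines
#'   (3 or more recommended).
#' @param weighted If `TRUE`, weight pair midpoints by `1/(gap + eps)`.
#' @param parallel_tol Parallelism tolerance passed to
#'   [closest_point_of_approach()].
#' @return A `com_estimate` (method `"suspension"`); `tidy()` returns the
#'   per-pair midpoints and gaps.
#' @export
estimate_com_suspension <- function(lines, weighted = FALSE, parallel_tol = 1e-8) {
  n <- nrow(lines)
  if (is.null(n) || n < 2L) {
    abort("need at least two suspension lines", class = "commass_insufficient_data")
  }
  idx <- combn(n, 2L)
  rows <- vector("list", ncol(idx))
  skipped <- 0L
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    cpa <- tryCatch(
      closest_point_of_approach(lines[i, ], lines[j, ], parallel_tol = parallel_tol),
      commass_degeneracy = function(e) NULL)
    if (is.null(cpa)) {
      skipped <- skipped + 1L
      next
    }
    rows[[k]] <- tibble::tibble(
      line_i = i, line_j = j,
      mid_x = cpa$midpoint[1], mid_y = cpa$midpoint[2], mid_z = cpa$midpoint[3],
      gap = cpa$gap)
  }
  if (skipped > 0L) {
    warn(sprintf("skipped %d near-parallel line pair(s)", skipped))
  }
  pairs <- dplyr::bind_rows(rows)
  if (nrow(pairs) == 0L) {
    abort("no usable (non-parallel) line pairs", class = "commass_insufficient_data")
  }
  w <- if (isTRUE(weighted)) 1 / (pairs$gap + 1e-6) else rep(1, nrow(pairs))
  com <- c(sum(pairs$mid_x * w), sum(pairs$mid_y * w), sum(pairs$mid_z * w)) / sum(w)
  est <- new_com_estimate(com, "suspension", n_runs = n, intermediates = pairs)
  est$n_pairs <- nrow(pairs)
  est$n_parallel_skipped <- skipped
  est$mean_gap <- mean(pairs$gap)
  est
}

#' Apply a rigid transform to suspension lines
#'
#' @param lines A `suspension_lines` tibble.
#' @param t A [rigid_transform()].
#' @return The transformed lines.
#' @export
transform_lines <- function(lines, t) {
  stopifnot(inherits(t, "rigid_transform"))
  P <- as.matrix(lines[, c("px", "py", "pz")]) %*% t(t$rotation)
  D <- as.matrix(lines[, c("dx", "dy", "dz")]) %*% t(t$rotation)
  lines$px <- P[, 1] + t$translation[1]
  lines$py <- P[, 2] + t$translation[2]
  lines$pz <- P[, 3] + t$translation[3]
  lines$dx <- D[, 1]; lines$dy <- D[, 2]; lines$dz <- D[, 3]
  lines
}

#' Run the full suspension pipeline over repeated captures
#'
#' Each capture arrives in its own frame (the specimen hangs differently every
#' time), so the captures are first registered to `reference` using the
#' specimen markers (every label except the string markers), the string
#' markers are carried through the fitted transform, one line is built per
#' capture, and [estimate_com_suspension()] triangulates the CoM.
#'
#' @param captures List of marker sets, each containing specimen markers plus
#'   the two string markers.
#' @param reference Marker set defining the common frame (e.g. a specimen's
#'   nominal markers); defaults to the first capture.
#' @param string_labels Labels of the string markers.
#' @param weighted,parallel_tol Passed to [estimate_com_suspension()].
#' @return A `com_estimate` in the reference frame, with the registration
#'   RMSDs recorded in `$registration`.
#' @export
estimate_com_suspension_from_captures <- function(captures, reference = NULL,
                                                  string_labels = c("STR1", "STR2"),
                                                  weighted = FALSE,
                                                  parallel_tol = 1e-8) {
  if (length(captures) < 2L) {
    abort("need at least two captures", class = "commass_insufficient_data")
  }
  reference <- reference %||% captures[[1]]
  ref_spec <- reference[!reference$label %in% string_labels, ]
  lines <- vector("list", length(captures))
  rmsds <- numeric(length(captures))
  for (i in seq_along(captures)) {
    cap <- captures[[i]]
    spec_markers <- cap[!cap$label %in% string_labels, ]
    fit <- fit_rigid_transform(spec_markers, ref_spec)
    rmsds[i] <- fit$rmsd
    aligned <- apply_transform(cap, fit$transform)
    lines[[i]] <- line_from_string_markers(aligned, labels = string_labels,
                                           capture_id = as.character(i))
  }
  lines <- dplyr::bind_rows(lines)
  est <- estimate_com_suspension(lines, weighted = weighted,
                                 parallel_tol = parallel_tol)
  est$registration <- tibble::tibble(capture = seq_along(captures), rmsd = rmsds)
  est
}

#' Plot the pairwise suspension estimates
#'
#' Scatter of the pair midpoints in two projections with the overall CoM
#' highlighted, echoing the spread of pairwise string-intersection estimates
#' around the final suspension CoM.
#'
#' @param object A suspension `com_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.com_estimate <- function(object, ...) {
  pairs <- object$intermediates
  if (is.null(pairs) || !all(c("mid_x", "mid_y", "mid_z") %in% names(pairs))) {
    abort("this estimate has no pair midpoints to plot", class = "commass_validation")
  }
  long <- dplyr::bind_rows(
    tibble::tibble(view = "x-y", h = pairs$mid_x, v = pairs$mid_y),
    tibble::tibble(view = "x-z", h = pairs$mid_x, v = pairs$mid_z))
  com <- dplyr::bind_rows(
    tibble::tibble(view = "x-y", h = object$com[1], v = object$com[2]),
    tibble::tibble(view = "x-z", h = object$com[1], v = object$com[3]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$h, y = .data$v)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = com, colour = "red", shape = 4, size = 3, stroke = 1.5) +
    ggplot2::facet_wrap(~view, scales = "free") +
    ggplot2::labs(x = "mm", y = "mm",
                  title = sprintf("Pairwise CoM estimates (%d pairs), overall CoM in red",
                                  nrow(pairs)))
}
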