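#' Scales (reaction-board) runs
#'
#' One run places the specimen on a plank resting on two scales, with the
#' proximal face (or beak tip) at the proximal plank edge. `w1` and `w2` are
#' the proximal and distal scale readings (kg, plank tared out), `L` the
#' distance between supports (mm) and `dL` the distance from the proximal
#' plank edge to the proximal support (mm). Runs are rows of a tibble so
#' repeated runs over axes and orientations stack.
#'
#' @param w1,w2 Scale readings, kg (non-negative, `w1 + w2 > 0`).
#' @param L Distance between supports, mm.
#' @param dL Proximal plank edge to proximal support, mm.
#' @param axis Axis label the plank is aligned with (e.g. `"x"`).
#' @param orientation `"forward"` or `"reversed"` specimen placement.
#' @param length_mm Specimen length along `axis` (needed to combine reversed
#'   repeats); may be `NA` for forward-only work.
#' @return A one-row `scales_runs` tibble.
#' @export
scales_run <- function(w1, w2, L, dL, axis = "x",
                       orientation = c("forward", "reversed"),
                       length_mm = NA_real_) {
  orientation <- match.arg(orientation)
  run <- tibble::tibble(w1 = as.numeric(w1), w2 = as.numeric(w2),
                        L = as.numeric(L), dL = as.numeric(dL),
                        axis = as.character(axis), orientation = orientation,
                        length_mm = as.numeric(length_mm))
  validate_scales_runs(run)
  class(run) <- c("scales_runs", class(run))
  run
}

validate_scales_runs <- function(runs) {
  need <- c("w1", "w2", "L", "dL", "axis", "orientation")
  if (!all(need %in% names(runs))) {
    abort(paste0("scales runs need columns ", paste(need, collapse = ", ")),
          class = "commass_validation")
  }
  if (any(runs$w1 < 0 | runs$w2 < 0)) {
    abort("scale readings must be non-negative", class = "commass_validation")
  }
  if (any(runs$w1 + runs$w2 <= 0)) {
    abort("w1 + w2 must be positive (no load on the scales)",
          class = "commass_validation")
  }
  if (any(runs$L <= 0) || any(runs$dL < 0)) {
    abort("need L > 0 and dL >= 0", class = "commass_validation")
  }
  invisible(runs)
}

#' 1D CoM coordinate from a scales run
#'
#' Torque balance about the proximal support gives the CoM distance from the
#' proximal plank edge along the plank axis:
#' `com = w2 * L / (w1 + w2) + dL`. With equal readings this is the midpoint
#' `dL + L/2`; with all load on the proximal scale it is `dL` exactly.
#'
#' @param runs A `scales_runs` tibble (any number of rows).
#' @return The input with a `com_mm` column appended (mm from the proximal
#'   plank edge, in each run's own orientation).
#' @export
#' @examples
#' com_1d_from_run(scales_run(w1 = 1, w2 = 1, L = 100, dL = 10))$com_mm  # 60
com_1d_from_run <- function(runs) {
  validate_scales_runs(runs)
  dplyr::mutate(runs, com_mm = .data$w2 * .data$L / (.data$w1 + .data$w2) + .data$dL)
}

#' Combine forward and reversed scales runs for one axis
#'
#' Placement against the proximal plank edge carries a systematic skew: if the
#' specimen actually sits `delta` mm beyond the edge, every forward coordinate
#' is biased by `+delta`. Flipping the specimen end-for-end biases the reversed
#' coordinate by the same `+delta` in the flipped frame, so the symmetric
#' combination `(c_fwd + (length - c_rev)) / 2`, expressed in the forward
#' frame, cancels any additive placement offset exactly.
#'
#' @param fwd,rev Single forward- and reversed-orientation rows carrying
#'   `com_mm` (from [com_1d_from_run()]) for the same axis.
#' @param specimen_length Specimen length along the axis, mm; defaults to the
#'   runs' `length_mm`.
#' @return A one-row tibble with the corrected `com_mm` (forward frame),
#'   `axis`, `n_runs = 2` and `orientation_coverage = "forward_and_reversed"`.
#' @export
combine_forward_reversed <- function(fwd, rev, specimen_length = NULL) {
  if (!"com_mm" %in% names(fwd)) fwd <- com_1d_from_run(fwd)
  if (!"com_mm" %in% names(rev)) rev <- com_1d_from_run(rev)
  if (nrow(fwd) != 1L || nrow(rev) != 1L) {
    abort("combine one forward and one reversed run at a time",
          class = "commass_validation")
  }
  if (fwd$axis != rev$axis) {
    abort("forward and reversed runs are on different axes",
          class = "commass_validation")
  }
  if (fwd$orientation != "forward" || rev$orientation != "reversed") {
    abort("runs must be one forward and one reversed", class = "commass_validation")
  }
  len <- specimen_length %||% fwd$length_mm
  if (is.null(len) || is.na(len) || len <= 0) {
    abort("specimen length along the axis is required", class = "commass_validation")
  }
  corrected <- (fwd$com_mm + (len - rev$com_mm)) / 2
  tibble::tibble(axis = fwd$axis, com_mm = corrected, n_runs = 2L,
                 orientation_coverage = "forward_and_reversed",
                 length_mm = len)
}

#' Per-axis CoM coordinates from a table of scales runs
#'
#' Groups runs by axis, combines forward/reversed pairs where both are present
#' (averaging repeats within each orientation first) and keeps forward-only
#' axes as-is. Warns when a coordinate falls outside `[0, length]`.
#'
#' @param runs A `scales_runs` tibble.
#' @return A tibble with one row per axis: `axis`, `com_mm` (forward frame,
#'   from the proximal face), `n_runs`, `orientation_coverage`.
#' @export
axis_coms_from_runs <- function(runs) {
  runs <- com_1d_from_run(runs)
  out <- lapply(split(runs, runs$axis), function(ax) {
    fwd <- ax[ax$orientation == "forward", ]
    rev <- ax[ax$orientation == "reversed", ]
    if (nrow(fwd) == 0L) {
      abort(sprintf("axis %s has no forward run", ax$axis[1]),
            class = "commass_validation")
    }
    mean_run <- function(d) {
      d <- d[1, ] |> dplyr::mutate(com_mm = mean(d$com_mm))
      d
    }
    if (nrow(rev) > 0L) {
      res <- combine_forward_reversed(mean_run(fwd), mean_run(rev))
      res$n_runs <- nrow(ax)
      res
    } else {
      tibble::tibble(axis = ax$axis[1], com_mm = mean(fwd$com_mm),
                     n_runs = nrow(fwd),
                     orientation_coverage = "forward_only",
                     length_mm = fwd$length_mm[1])
    }
  })
  out <- dplyr::bind_rows(out)
  bad <- !is.na(out$length_mm) & (out$com_mm < 0 | out$com_mm > out$length_mm)
  if (any(bad)) {
    warn(sprintf("axis CoM outside [0, length] for axis %s",
                 paste(out$axis[bad], collapse = ", ")))
  }
  out
}

#' World frame from plank and ruler markers
#'
#' The plank carries a marker at each end, as does a ruler laid perpendicular
#' to it. The returned transform maps capture coordinates into a frame whose
#' first axis is the plank direction, second the component of the ruler
#' direction orthogonal to it (Gram-Schmidt), third their cross product;
#' origin at the first plank marker.
#'
#' @param plank_m1,plank_m2,ruler_m1,ruler_m2 Length-3 marker positions (mm),
#'   or single-row marker-set slices.
#' @return A [rigid_transform()] from capture to world coordinates.
#' @export
build_world_frame <- function(plank_m1, plank_m2, ruler_m1, ruler_m2) {
  as_pt <- function(p) if (is.data.frame(p)) c(p$x[1], p$y[1], p$z[1]) else vec3(p)
  p1 <- as_pt(plank_m1); p2 <- as_pt(plank_m2)
  r1 <- as_pt(ruler_m1); r2 <- as_pt(ruler_m2)
  e1 <- unit3(p2 - p1)
  rdir <- unit3(r2 - r1)
  ang <- acos(pmin(1, abs(sum(e1 * rdir)))) * 180 / pi
  if (90 - ang > 85) {
    abort("plank and ruler are near-parallel; frame is degenerate",
          class = "commass_degeneracy")
  }
  e2 <- unit3(rdir - sum(rdir * e1) * e1)
  e3 <- cross3(e1, e2)
  R <- rbind(e1, e2, e3)
  dimnames(R) <- NULL
  rigid_transform(R, -as.numeric(R %*% p1))
}

#' Assemble per-axis scales coordinates into a CoM estimate
#'
#' Three per-axis coordinates (mm from the proximal reference along each world
#' axis) combine into a 3D CoM: `proximal_reference_point + sum(coord_i *
#' axis_i)`. A single-axis input returns a 1D, axis-tagged estimate (the bird
#' case, where only the cranio-caudal axis is measured).
#'
#' @param axis_coms Tibble from [axis_coms_from_runs()] (or with columns
#'   `axis`, `com_mm`), one or three distinct axes.
#' @param frame Optional [rigid_transform()] into the world frame whose axes
#'   the coordinates refer to (identity by default).
#' @param proximal_reference_point The 3D position of the proximal reference
#'   (e.g. the corner of the brick's proximal faces), world frame, mm.
#' @return A `com_estimate` (method `"scales"`).
#' @export
assemble_3d <- function(axis_coms, frame = NULL,
                        proximal_reference_point = c(0, 0, 0)) {
  if (anyDuplicated(axis_coms$axis)) {
    abort("duplicate axis in per-axis CoM table", class = "commass_validation")
  }
  n_runs <- if ("n_runs" %in% names(axis_coms)) sum(axis_coms$n_runs) else nrow(axis_coms)
  if (nrow(axis_coms) == 1L) {
    est <- new_com_estimate(axis_coms$com_mm, "scales", n_runs = n_runs,
                            intermediates = axis_coms, axis = axis_coms$axis)
    return(est)
  }
  if (nrow(axis_coms) != 3L) {
    abort("need exactly one or three axes", class = "commass_validation")
  }
  axes <- match(axis_coms$axis, c("x", "y", "z"))
  if (anyNA(axes)) {
    abort("3D assembly expects axes named x, y, z", class = "commass_validation")
  }
  coord <- numeric(3)
  coord[axes] <- axis_coms$com_mm
  origin <- vec3(proximal_reference_point)
  basis <- diag(3)
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "rigid_transform"))
    basis <- t(frame$rotation)  # world axes expressed in capture coordinates
  }
  com <- origin + as.numeric(basis %*% coord)
  new_com_estimate(com, "scales", n_runs = n_runs, intermediates = axis_coms)
}
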