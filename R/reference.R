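#' Face-pair specification for geometric centres
#'
#' One row per axis naming the two markers on opposite faces whose mean gives
#' the centre coordinate along that axis. The default is the brick scheme
#' with pairs E/F, C/D and A/B along x, y and z.
#'
#' @param axis Axis labels (`"x"`, `"y"`, `"z"`).
#' @param label_a,label_b Marker labels of the opposite-face pair per axis.
#' @return A tibble with columns `axis`, `label_a`, `label_b`.
#' @export
face_pair_spec <- function(axis = c("x", "y", "z"),
                           label_a = c("E", "C", "A"),
                           label_b = c("F", "D", "B")) {
  spec <- tibble::tibble(axis = axis, label_a = label_a, label_b = label_b)
  if (anyDuplicated(spec$axis)) {
    abort("one face pair per axis", class = "commass_validation")
  }
  if (any(spec$label_a == spec$label_b)) {
    abort("face-pair labels must be distinct", class = "commass_validation")
  }
  spec
}

#' Geometric centre from opposite-face marker pairs
#'
#' For a box-like specimen aligned with the world axes, the centre coordinate
#' along each axis is the mean of the two markers on the opposite faces for
#' that axis; combining the three 1D coordinates gives the 3D geometric
#' centre, the reference truth for uniform bricks.
#'
#' @param ms A marker set, aligned to the world axes.
#' @param specs A [face_pair_spec()] tibble with the three axes.
#' @return A `com_estimate` (method `"geometric"`).
#' @export
geometric_centre <- function(ms, specs = face_pair_spec()) {
  validate_marker_set(ms)
  missing <- setdiff(c(specs$label_a, specs$label_b), ms$label)
  if (length(missing) > 0L) {
    abort(paste0("missing marker label(s): ", paste(missing, collapse = ", ")),
          class = "commass_correspondence")
  }
  if (anyDuplicated(specs$axis) || nrow(specs) != 3L) {
    abort("need three distinct axes", class = "commass_validation")
  }
  m <- marker_matrix(ms)
  com <- numeric(3)
  per_axis <- vector("list", 3L)
  for (i in seq_len(3L)) {
    ax <- match(specs$axis[i], c("x", "y", "z"))
    a <- m[specs$label_a[i], ax]
    b <- m[specs$label_b[i], ax]
    com[ax] <- (a + b) / 2
    per_axis[[i]] <- tibble::tibble(axis = specs$axis[i],
                                    coord_a = a, coord_b = b,
                                    centre = (a + b) / 2)
  }
  new_com_estimate(com, "geometric", n_runs = 1L,
                   intermediates = dplyr::bind_rows(per_axis))
}

#' Error of a CoM estimate against a reference
#'
#' Both estimates must live in the same frame (register first). 3D pairs give
#' the Euclidean distance plus signed per-axis components; if either estimate
#' is 1D (the bird scales case) the comparison is restricted to that axis and
#' flagged as one-dimensional.
#'
#' @param est,ref `com_estimate` objects (or bare length-3/length-1 numeric
#'   coordinates; 1D numeric input needs `est` to be a `com_estimate` to know
#'   its axis).
#' @param reference_length Optional length (mm) for normalisation, passed to
#'   [normalise_error()].
#' @return A one-row `error_report` tibble: `method`, `n_runs`, `dist_mm`,
#'   `dx`, `dy`, `dz`, `dimensionality`, `normalised`.
#' @export
com_error <- function(est, ref, reference_length = NULL) {
  est_com <- if (inherits(est, "com_estimate")) est$com else as.numeric(est)
  ref_com <- if (inherits(ref, "com_estimate")) ref$com else as.numeric(ref)
  method <- if (inherits(est, "com_estimate")) est$method else NA_character_
  n_runs <- if (inherits(est, "com_estimate")) est$n_runs else NA_integer_
  d <- c(NA_real_, NA_real_, NA_real_)
  if (length(est_com) == 3L && length(ref_com) == 3L) {
    d <- est_com - ref_com
    dist <- norm3(d)
    dim_ <- "3d"
  } else {
    axis <- if (inherits(est, "com_estimate") && length(est$com) == 1L) est$axis
            else if (inherits(ref, "com_estimate") && length(ref$com) == 1L) ref$axis
            else NULL
    if (is.null(axis)) {
      abort("1D comparison needs an axis-tagged com_estimate",
            class = "commass_validation")
    }
    ax <- match(axis, c("x", "y", "z"))
    e1 <- if (length(est_com) == 3L) est_com[ax] else est_com
    r1 <- if (length(ref_com) == 3L) ref_com[ax] else ref_com
    d[ax] <- e1 - r1
    dist <- abs(e1 - r1)
    dim_ <- paste0("1d-", axis)
  }
  rep_ <- tibble::tibble(method = method, n_runs = n_runs, dist_mm = dist,
                         dx = d[1], dy = d[2], dz = d[3],
                         dimensionality = dim_, normalised = NA_real_)
  class(rep_) <- c("error_report", class(rep_))
  if (!is.null(reference_length)) rep_ <- normalise_error(rep_, reference_length)
  rep_
}

#' Normalise an error report by a reference length
#'
#' Fills the `normalised` column with `dist_mm / reference_length` (a fraction
#' of, e.g., the brick's longest side or the bird's cranio-caudal length).
#' Idempotent.
#'
#' @param report An `error_report` tibble from [com_error()].
#' @param reference_length Positive length, mm.
#' @return The report with `normalised` filled in.
#' @export
normalise_error <- function(report, reference_length) {
  assert_scalar_number(reference_length, "reference_length", positive = TRUE)
  report$normalised <- report$dist_mm / reference_length
  report
}

#' Repeatability range of a set of CoM estimates
#'
#' The headline repeatability figure is the maximum pairwise 3D distance among
#' the estimates; the full pair table is kept alongside. When a reference is
#' supplied, the range (max minus min) of distances-to-reference is also
#' reported, the range-style summary used for repeated runs of one method.
#'
#' @param estimates List of `com_estimate` objects (or length-3 coordinates)
#'   in a common frame.
#' @param reference Optional reference estimate/coordinates.
#' @return A list with `max_pairwise_mm`, `pairs` (tibble), and when a
#'   reference is given, `distances_to_reference` and `reference_range_mm`.
#' @export
repeatability_range <- function(estimates, reference = NULL) {
  if (length(estimates) < 2L) {
    abort("need at least two estimates", class = "commass_insufficient_data")
  }
  coords <- t(vapply(estimates, function(e) {
    if (inherits(e, "com_estimate")) e$com else vec3(e)
  }, numeric(3)))
  idx <- combn(nrow(coords), 2L)
  d <- sqrt(colSums((t(coords[idx[1, ], , drop = FALSE]) -
                     t(coords[idx[2, ], , drop = FALSE]))^2))
  pairs <- tibble::tibble(i = idx[1, ], j = idx[2, ], distance_mm = as.numeric(d))
  out <- list(max_pairwise_mm = max(pairs$distance_mm), pairs = pairs)
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "com_estimate")) reference$com else vec3(reference)
    dref <- sqrt(rowSums(sweep(coords, 2, ref)^2))
    out$distances_to_reference <- dref
    out$reference_range_mm <- max(dref) - min(dref)
  }
  out
}
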