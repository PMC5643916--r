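#' Build a marker set
#'
#' A marker set is a tibble with columns `label`, `x`, `y`, `z` holding the
#' 3D coordinates (mm) of labelled reflective markers captured in one
#' condition. All user-facing functions in the package accept and return
#' marker sets in this form so calls chain with the pipe.
#'
#' @param label Character vector of unique, non-empty marker labels.
#' @param x,y,z Numeric coordinate vectors, mm.
#' @param specimen_id,condition_id Optional identifiers stored as attributes.
#'
#' @return A tibble of class `marker_set` with one row per marker.
#' @export
#' @examples
#' marker_set(c("A", "B"), x = c(0, 3), y = c(0, 4), z = c(0, 0))
marker_set <- function(label, x, y, z, specimen_id = NULL, condition_id = NULL) {
  ms <- tibble::tibble(label = as.character(label),
                       x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  validate_marker_set(ms)
  attr(ms, "specimen_id") <- specimen_id
  attr(ms, "condition_id") <- condition_id
  class(ms) <- c("marker_set", class(ms))
  ms
}

validate_marker_set <- function(ms) {
  if (!all(c("label", "x", "y", "z") %in% names(ms))) {
    abort("a marker set needs columns label, x, y, z", class = "commass_validation")
  }
  if (nrow(ms) == 0L) {
    abort("marker set is empty", class = "commass_validation")
  }
  if (any(!nzchar(ms$label)) || anyNA(ms$label)) {
    abort("marker labels must be non-empty", class = "commass_validation")
  }
  if (anyDuplicated(ms$label)) {
    dup <- unique(ms$label[duplicated(ms$label)])
    abort(paste0("duplicate marker label(s): ", paste(dup, collapse = ", ")),
          class = "commass_validation")
  }
  if (!all(is.finite(ms$x) & is.finite(ms$y) & is.finite(ms$z))) {
    abort("marker positions must be finite", class = "commass_validation")
  }
  invisible(ms)
}

as_marker_set <- function(df) {
  validate_marker_set(df)
  if (!inherits(df, "marker_set")) class(df) <- c("marker_set", class(df))
  df
}

marker_matrix <- function(ms) {
  m <- as.matrix(ms[, c("x", "y", "z")])
  rownames(m) <- ms$label
  m
}

#' Read a marker capture from CSV
#'
#' Expects rows of `label,x_mm,y_mm,z_mm` (header optional, detected from the
#' first row); `#`-prefixed lines are comments. Coordinates are taken as mm
#' verbatim.
#'
#' @param path Path to a marker CSV file.
#' @return A [marker_set()] tibble preserving row order.
#' @export
read_marker_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "commass_validation")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    abort(paste0("no marker rows in ", path), class = "commass_validation")
  }
  first <- strsplit(lines[[keep[1]]], ",")[[1]]
  has_header <- length(first) >= 4 && is.na(suppressWarnings(as.numeric(first[2])))
  data_idx <- if (has_header) keep[-1] else keep
  if (length(data_idx) == 0L) {
    abort(paste0("no marker rows in ", path), class = "commass_validation")
  }
  rows <- lapply(data_idx, function(i) {
    f <- trimws(strsplit(lines[[i]], ",")[[1]])
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (length(f) < 4 || anyNA(xyz)) {
      abort(sprintf("malformed marker row at line %d of %s", i, path),
            class = "commass_parse")
    }
    tibble::tibble(label = f[1], x = xyz[1], y = xyz[2], z = xyz[3])
  })
  ms <- dplyr::bind_rows(rows)
  as_marker_set(ms)
}

#' Write a marker set to CSV
#'
#' @param ms A marker set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(ms, path) {
  validate_marker_set(ms)
  readr::write_csv(ms[, c("label", "x", "y", "z")], path)
  invisible(path)
}

#' Pairwise 3D distances between markers
#'
#' Computes the Euclidean distance between every unordered pair of markers.
#' Distances are invariant under any rigid transform of the set, which is what
#' makes their discrepancies a posture-change metric.
#'
#' @param ms A marker set.
#' @return A tibble with columns `label_a`, `label_b`, `distance` (mm), one
#'   row per unordered pair, labels in row order.
#' @export
inter_marker_distances <- function(ms) {
  validate_marker_set(ms)
  if (nrow(ms) < 2L) {
    abort("need at least two markers", class = "commass_validation")
  }
  m <- marker_matrix(ms)
  idx <- combn(nrow(ms), 2L)
  d <- sqrt(rowSums((m[idx[1, ], , drop = FALSE] - m[idx[2, ], , drop = FALSE])^2))
  tibble::tibble(label_a = ms$label[idx[1, ]],
                 label_b = ms$label[idx[2, ]],
                 distance = as.numeric(d))
}

#' Posture shift between two captures of the same specimen
#'
#' The score is the sum over shared marker pairs of the absolute change in
#' inter-marker distance between conditions `a` and `b`. It is zero (to
#' tolerance) exactly when the two conditions differ by a rigid motion, so a
#' positive score quantifies genuine deformation such as a joint rotation.
#'
#' @param a,b Marker sets with identical label sets.
#' @return An object of class `posture_shift` with the total `score` (mm) and
#'   a per-pair discrepancy table; see [tidy()] and [glance()].
#' @export
posture_shift_score <- function(a, b) {
  validate_marker_set(a)
  validate_marker_set(b)
  if (!setequal(a$label, b$label)) {
    abort("marker label sets differ between conditions", class = "commass_correspondence")
  }
  b <- b[match(a$label, b$label), ]
  da <- inter_marker_distances(a)
  db <- inter_marker_distances(b)
  pairs <- dplyr::mutate(da,
                         distance_b = db$distance,
                         discrepancy = abs(.data$distance - db$distance))
  pairs <- dplyr::rename(pairs, distance_a = "distance")
  out <- list(score = sum(pairs$discrepancy), pairs = pairs)
  class(out) <- "posture_shift"
  out
}

#' @export
print.posture_shift <- function(x, ...) {
  cat(sprintf("Posture shift: %.4g mm summed over %d marker pairs\n",
              x$score, nrow(x$pairs)))
  worst <- x$pairs[which.max(x$pairs$discrepancy), ]
  cat(sprintf("  largest pair discrepancy: %s-%s (%.4g mm)\n",
              worst$label_a, worst$label_b, worst$discrepancy))
  invisible(x)
}

#' @export
tidy.posture_shift <- function(x, ...) x$pairs

#' @export
glance.posture_shift <- function(x, ...) {
  tibble::tibble(score = x$score, n_pairs = nrow(x$pairs))
}
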