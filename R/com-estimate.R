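# Common result container for all CoM methodologies.

new_com_estimate <- function(com, method, n_runs, intermediates = NULL,
                             axis = NULL, mass_kg = NULL) {
  method <- match.arg(method, c("suspension", "scales", "volumetric", "geometric"))
  com <- as.numeric(com)
  if (!all(is.finite(com))) {
    abort("CoM estimate is not finite", class = "commass_validation")
  }
  structure(list(com = com, method = method, n_runs = n_runs,
                 intermediates = intermediates, axis = axis, mass_kg = mass_kg),
            class = "com_estimate")
}

#' Extract the estimated CoM coordinates
#'
#' @param est A `com_estimate` as returned by [estimate_com_suspension()],
#'   [assemble_3d()], [composite_com()] or [geometric_centre()].
#' @return Numeric coordinates, mm: length 3 for 3D estimates, length 1
#'   (named by axis) for 1D scales estimates.
#' @export
com_coordinates <- function(est) {
  stopifnot(inherits(est, "com_estimate"))
  if (!is.null(est$axis) && length(est$com) == 1L) setNames(est$com, est$axis) else est$com
}

#' @export
print.com_estimate <- function(x, ...) {
  if (length(x$com) == 3L) {
    cat(sprintf("CoM estimate (%s, %d run%s): (%.3f, %.3f, %.3f) mm\n",
                x$method, x$n_runs, if (x$n_runs == 1) "" else "s",
                x$com[1], x$com[2], x$com[3]))
  } else {
    cat(sprintf("CoM estimate (%s, %d run%s): %.3f mm along %s axis (1D)\n",
                x$method, x$n_runs, if (x$n_runs == 1) "" else "s",
                x$com[1], x$axis))
  }
  if (!is.null(x$mass_kg)) cat(sprintf("  total mass: %.6g kg\n", x$mass_kg))
  invisible(x)
}

#' @export
tidy.com_estimate <- function(x, ...) {
  x$intermediates %||% tibble::tibble()
}

#' @export
glance.com_estimate <- function(x, ...) {
  if (length(x$com) == 3L) {
    tibble::tibble(method = x$method, n_runs = x$n_runs,
                   com_x = x$com[1], com_y = x$com[2], com_z = x$com[3])
  } else {
    tibble::tibble(method = x$method, n_runs = x$n_runs,
                   axis = x$axis, coordinate = x$com[1])
  }
}
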