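#' Experiment configuration
#'
#' Describes a full comparative study on synthetic specimens: which
#' specimens, which methods and repeat structures, the noise model and the
#' master seed. Per-cell seeds are derived deterministically from the master
#' seed by a counter scheme (`derive = (seed * 1009 + counter) mod 2^31 - 1`),
#' so every cell of the report can be re-run in isolation. Round-trips
#' losslessly through YAML via [write_experiment_config()] /
#' [read_experiment_config()].
#'
#' @param specimens Named list of `specimen` generator calls, given as lists
#'   `list(kind = "brick"|"bird", ...args)`.
#' @param methods Subset of `c("suspension", "scales", "volumetric",
#'   "geometric")`.
#' @param suspension_positions Integer vector of suspension repeat arms
#'   (default `c(3, 10)`).
#' @param scales_arms Character subset of `c("forward_only",
#'   "forward_and_reversed")`.
#' @param n_replicates Monte-Carlo replicates per cell.
#' @param noise A [noise_model()].
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(specimens = list(brick1 = list(kind = "brick")),
                              methods = c("suspension", "scales",
                                          "volumetric", "geometric"),
                              suspension_positions = c(3, 10),
                              scales_arms = c("forward_only",
                                              "forward_and_reversed"),
                              n_replicates = 20,
                              noise = noise_model(),
                              seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  scales_arms <- match.arg(scales_arms, several.ok = TRUE)
  structure(list(specimens = specimens, methods = methods,
                 suspension_positions = suspension_positions,
                 scales_arms = scales_arms, n_replicates = n_replicates,
                 noise = noise, seed = seed),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param cfg An `experiment_config`.
#' @param path File path for the YAML form.
#' @export
write_experiment_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$noise <- unclass(out$noise)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(specimens = raw$specimens, methods = raw$methods,
                    suspension_positions = as.integer(raw$suspension_positions),
                    scales_arms = raw$scales_arms,
                    n_replicates = raw$n_replicates,
                    noise = do.call(noise_model, raw$noise),
                    seed = raw$seed)
}

build_specimen <- function(spec_def) {
  kind <- spec_def$kind %||% "brick"
  args <- spec_def[setdiff(names(spec_def), "kind")]
  switch(kind,
         brick = do.call(make_brick, args),
         bird = do.call(make_birdlike, args),
         abort(sprintf("unknown specimen kind '%s'", kind),
               class = "commass_validation"))
}

# One replicate of one method arm; returns the estimated CoM (specimen frame).
run_method_cell <- function(spec, method, arm, noise, cell_seed) {
  if (method == "suspension") {
    caps <- simulate_suspension_capture(spec, n_positions = arm, noise = noise,
                                        seed = cell_seed)
    est <- estimate_com_suspension_from_captures(caps, reference = spec$markers)
  } else if (method == "scales") {
    runs <- simulate_scales_runs(spec, reversed = (arm == "forward_and_reversed"),
                                 noise = noise, seed = cell_seed)
    est <- assemble_3d(axis_coms_from_runs(runs),
                       proximal_reference_point = spec$bbox["lo", ])
  } else if (method == "volumetric") {
    est <- composite_com(spec$components, check_containment = FALSE)
  } else if (method == "geometric") {
    ms <- simulate_marker_capture(spec, noise = noise, seed = cell_seed)
    est <- geometric_centre(ms)
  } else {
    abort(sprintf("unknown method '%s'", method), class = "commass_validation")
  }
  est
}

#' Run the full comparative study
#'
#' For every specimen x method x repeat arm x replicate: simulate the
#' captures, run the estimation pipeline, and measure the 3D error against
#' the specimen's analytically known CoM. Failures in a cell are caught,
#' logged and marked rather than aborting the study. Fully reproducible from
#' `(config, seed)`.
#'
#' @param cfg An [experiment_config()].
#' @return An `experiment_report`: a tidy tibble with one row per
#'   specimen/method/arm/replicate (`error_mm`, per-axis components,
#'   `cell_seed`, `ok`).
#' @export
run_comparison <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  counter <- 0L
  rows <- list()
  for (spec_name in names(cfg$specimens)) {
    spec <- build_specimen(cfg$specimens[[spec_name]])
    arms <- list()
    if ("suspension" %in% cfg$methods) {
      for (np in cfg$suspension_positions) {
        arms[[length(arms) + 1L]] <- list(method = "suspension", arm = np,
                                          arm_label = sprintf("n%d", np))
      }
    }
    if ("scales" %in% cfg$methods) {
      for (sa in cfg$scales_arms) {
        arms[[length(arms) + 1L]] <- list(method = "scales", arm = sa,
                                          arm_label = sa)
      }
    }
    if ("volumetric" %in% cfg$methods) {
      arms[[length(arms) + 1L]] <- list(method = "volumetric", arm = NA,
                                        arm_label = "mesh")
    }
    if ("geometric" %in% cfg$methods) {
      # the opposite-face geometric centre only exists for box-like
      # specimens carrying the six face markers
      fp <- face_pair_spec()
      if (all(c(fp$label_a, fp$label_b) %in% spec$markers$label)) {
        arms[[length(arms) + 1L]] <- list(method = "geometric", arm = NA,
                                          arm_label = "markers")
      }
    }
    for (arm in arms) {
      for (rep_i in seq_len(cfg$n_replicates)) {
        counter <- counter + 1L
        cell_seed <- derive_seed(cfg$seed, counter)
        est <- tryCatch(
          run_method_cell(spec, arm$method, arm$arm, cfg$noise, cell_seed),
          error = function(e) e)
        if (inherits(est, "error")) {
          rows[[counter]] <- tibble::tibble(
            specimen = spec_name, method = arm$method, arm = arm$arm_label,
            replicate = rep_i, cell_seed = cell_seed, ok = FALSE,
            error_mm = NA_real_, dx = NA_real_, dy = NA_real_, dz = NA_real_,
            message = conditionMessage(est))
          next
        }
        err <- com_error(est, spec$true_com)
        rows[[counter]] <- tibble::tibble(
          specimen = spec_name, method = arm$method, arm = arm$arm_label,
          replicate = rep_i, cell_seed = cell_seed, ok = TRUE,
          error_mm = err$dist_mm, dx = err$dx, dy = err$dy, dz = err$dz,
          message = NA_character_)
      }
    }
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("experiment_report", class(report))
  attr(report, "config") <- cfg
  report
}

#' Summarise an experiment report per method arm
#'
#' @param report An `experiment_report`.
#' @return A tibble with median/maximum error and inter-replicate range per
#'   specimen, method and arm.
#' @export
summarise_comparison <- function(report) {
  report |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(.data$specimen, .data$method, .data$arm) |>
    dplyr::summarise(n = dplyr::n(),
                     median_error_mm = median(.data$error_mm),
                     max_error_mm = max(.data$error_mm),
                     range_mm = max(.data$error_mm) - min(.data$error_mm),
                     .groups = "drop")
}

#' Percent improvement between two repeat arms
#'
#' Reports `100 * (err_a - err_b) / err_a` per specimen (positive when arm b
#' is closer to the truth), using the median over replicates within each arm.
#' An arm-a error of zero makes the ratio undefined and is reported as `NA`.
#'
#' @param report An `experiment_report`.
#' @param method The method whose arms are compared.
#' @param arm_a,arm_b Arm labels (e.g. `"n3"`, `"n10"`).
#' @return A tibble with one row per specimen.
#' @export
improvement_summary <- function(report, method, arm_a, arm_b) {
  sub <- dplyr::filter(report, .data$ok, .data$method == !!method,
                       .data$arm %in% c(arm_a, arm_b))
  med <- sub |>
    dplyr::group_by(.data$specimen, .data$arm) |>
    dplyr::summarise(err = median(.data$error_mm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "err")
  if (!all(c(arm_a, arm_b) %in% names(med))) {
    abort("both arms must be present in the report", class = "commass_validation")
  }
  ea <- med[[arm_a]]
  eb <- med[[arm_b]]
  tibble::tibble(specimen = med$specimen,
                 err_a = ea, err_b = eb,
                 improvement_pct = ifelse(ea == 0, NA_real_,
                                          100 * (ea - eb) / ea))
}

#' Plot an experiment report
#'
#' Error-versus-method plot in the style of the classic method-comparison
#' figure: one point per replicate, methods (and repeat arms) on the x axis,
#' 3D error to the true CoM on the y axis.
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, ...) {
  dat <- dplyr::filter(object, .data$ok) |>
    dplyr::mutate(cell = paste(.data$method, .data$arm))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cell, y = .data$error_mm)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~specimen, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "3D distance to true CoM (mm)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
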