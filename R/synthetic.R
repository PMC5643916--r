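#' Measurement noise model for simulated experiments
#'
#' Groups every noise source the simulators inject. Defaults are pinned to the
#' instrumentation the methods are typically run with: 1.32 mm motion-capture
#' marker error (applied as a per-axis Gaussian standard deviation) and a
#' 0.1 g scale quantiser; every other source defaults to zero so noise is
#' opt-in.
#'
#' @param marker_sigma Marker jitter, mm (per-axis Gaussian sd).
#' @param string_angle_sigma Angular error of the string line, degrees.
#' @param attachment_offset_sigma Lateral offset of the string attachment from
#'   the line through the CoM, mm.
#' @param scale_reading_sigma Scale reading noise, kg.
#' @param scale_quantum Scale resolution, kg (default 1e-4, i.e. 0.1 g; 0
#'   disables quantisation).
#' @param proximal_skew_delta Systematic specimen placement offset past the
#'   proximal plank edge, mm (the cause of the proximal skew the reversed
#'   repeats cancel).
#' @return A `noise_model` list.
#' @export
noise_model <- function(marker_sigma = 1.32, string_angle_sigma = 0,
                        attachment_offset_sigma = 0, scale_reading_sigma = 0,
                        scale_quantum = 1e-4, proximal_skew_delta = 0) {
  nm <- list(marker_sigma = marker_sigma,
             string_angle_sigma = string_angle_sigma,
             attachment_offset_sigma = attachment_offset_sigma,
             scale_reading_sigma = scale_reading_sigma,
             scale_quantum = scale_quantum,
             proximal_skew_delta = proximal_skew_delta)
  sig <- unlist(nm[c("marker_sigma", "string_angle_sigma",
                     "attachment_offset_sigma", "scale_reading_sigma",
                     "scale_quantum")])
  if (any(sig < 0)) abort("noise magnitudes must be >= 0", class = "commass_validation")
  structure(nm, class = "noise_model")
}

#' Noise-free model
#'
#' Convenience: every source zero (including the scale quantiser), for
#' closure tests where pipelines must recover the truth exactly.
#'
#' @return A `noise_model` with all sources zero.
#' @export
noise_model_zero <- function() {
  noise_model(marker_sigma = 0, string_angle_sigma = 0,
              attachment_offset_sigma = 0, scale_reading_sigma = 0,
              scale_quantum = 0, proximal_skew_delta = 0)
}

# Analytic (closed-form) composite CoM and mass from the per-component
# primitive volumes and centroids carried on a specimen's component table.
# Deliberately independent of the mesh integration pipeline.
analytic_mass_com <- function(components) {
  s <- ifelse(components$role == "flesh", 1, -1)
  mass <- components$density * mm3_to_m3(components$vol_mm3)
  net <- sum(s * mass)
  com <- c(sum(s * mass * components$acx),
           sum(s * mass * components$acy),
           sum(s * mass * components$acz)) / net
  list(mass_kg = net, com = com)
}

new_specimen <- function(components, markers, marker_component, nominal_lengths,
                         specimen_id = "specimen") {
  amc <- analytic_mass_com(components)
  bbox <- specimen_bbox_of(components)
  structure(list(components = components, markers = markers,
                 marker_component = marker_component,
                 true_com = amc$com, true_mass_kg = amc$mass_kg,
                 nominal_lengths = nominal_lengths, bbox = bbox,
                 specimen_id = specimen_id),
            class = "specimen")
}

specimen_bbox_of <- function(components) {
  flesh <- components$mesh[components$role == "flesh"]
  v <- do.call(rbind, lapply(flesh, function(m) m$vertices))
  rbind(lo = apply(v, 2, min), hi = apply(v, 2, max))
}

#' @export
print.specimen <- function(x, ...) {
  cat(sprintf("Synthetic specimen '%s': %d component(s), mass %.4g kg\n",
              x$specimen_id, nrow(x$components), x$true_mass_kg))
  cat(sprintf("  true CoM (mm): (%.3f, %.3f, %.3f)\n",
              x$true_com[1], x$true_com[2], x$true_com[3]))
  invisible(x)
}

#' Synthetic brick specimen
#'
#' A homogeneous box with six face-centre markers labelled A-F (pairs E/F,
#' C/D and A/B opposite along x, y and z, so corner ADE is the origin). The
#' true CoM is at half-dimensions by symmetry. Mimics the calibration objects
#' used to benchmark the methods; the default matches a ~3.13 kg engineering
#' brick of 216 x 99 x 67 mm.
#'
#' @param dims Side lengths along x, y, z (mm).
#' @param mass_kg Total mass; used to derive the uniform density.
#' @param density Alternatively a density (kg m^-3); overrides `mass_kg`.
#' @param specimen_id Identifier.
#' @return A `specimen` with analytically known CoM.
#' @export
make_brick <- function(dims = c(216, 99, 67), mass_kg = 3.13, density = NULL,
                       specimen_id = "brick") {
  dims <- vec3(dims)
  if (any(dims <= 0)) abort("brick dimensions must be positive", class = "commass_validation")
  vol <- prod(dims)
  density <- density %||% (mass_kg / mm3_to_m3(vol))
  mesh <- mesh_box(dims, component_id = "brick")
  comp <- body_component(mesh, role = "flesh", segment = "whole",
                         density = density, component_id = "brick")
  comp$vol_mm3 <- vol
  comp$acx <- dims[1] / 2; comp$acy <- dims[2] / 2; comp$acz <- dims[3] / 2
  markers <- marker_set(
    label = c("E", "F", "D", "C", "A", "B"),
    x = c(0, dims[1], dims[1] / 2, dims[1] / 2, dims[1] / 2, dims[1] / 2),
    y = c(dims[2] / 2, dims[2] / 2, 0, dims[2], dims[2] / 2, dims[2] / 2),
    z = c(dims[3] / 2, dims[3] / 2, dims[3] / 2, dims[3] / 2, 0, dims[3]),
    specimen_id = specimen_id)
  new_specimen(comp, markers,
               marker_component = setNames(rep("brick", 6), markers$label),
               nominal_lengths = setNames(dims, c("x", "y", "z")),
               specimen_id = specimen_id)
}

# One segment primitive for the bird builder.
bird_ellipsoid <- function(id, segment, center, semiaxes, density, role = "flesh",
                           subdivisions = 3) {
  comp <- body_component(mesh_ellipsoid(semiaxes, center, subdivisions,
                                        component_id = id),
                         role = role, segment = segment, density = density,
                         component_id = id)
  comp$vol_mm3 <- 4 / 3 * pi * prod(semiaxes)
  comp$acx <- center[1]; comp$acy <- center[2]; comp$acz <- center[3]
  comp
}

bird_box <- function(id, segment, origin, dims, density, role = "flesh") {
  comp <- body_component(mesh_box(dims, origin, component_id = id),
                         role = role, segment = segment, density = density,
                         component_id = id)
  comp$vol_mm3 <- prod(dims)
  ctr <- origin + dims / 2
  comp$acx <- ctr[1]; comp$acy <- ctr[2]; comp$acz <- ctr[3]
  comp
}

#' Synthetic bird-like specimen
#'
#' A segmented composite body in a standardised posture: ellipsoidal head and
#' trunk, box neck, two folded-wing boxes (forelimbs), two hanging hindlimb
#' boxes, and (optionally) a cranially placed ellipsoidal air cavity inside
#' the trunk. x is cranio-caudal (beak tip near x = 0), y left-right, z
#' dorso-ventral. The true CoM comes from closed-form primitive volumes and
#' centroids, independent of the mesh pipeline, so the two act as mutual
#' oracles. Seven markers follow the standard avian scheme (head, two
#' neck/tail trunk junctions, two wing tips, two distal hindlimbs).
#'
#' @param densities Named per-segment densities (kg m^-3); defaults to a
#'   uniform 1000 for all segments.
#' @param cavity Include the trunk air cavity?
#' @param subdivisions Icosphere subdivisions for curved parts (default 3;
#'   all ellipsoids share one discretisation so their relative volume deficit
#'   is identical).
#' @param specimen_id Identifier.
#' @return A `specimen`.
#' @export
make_birdlike <- function(densities = NULL, cavity = TRUE, subdivisions = 3,
                          specimen_id = "bird") {
  dens <- c(head = 1000, neck = 1000, trunk = 1000,
            forelimb = 1000, hindlimb = 1000)
  if (!is.null(densities)) dens[names(densities)] <- densities
  comps <- dplyr::bind_rows(
    bird_ellipsoid("head", "head", c(40, 0, 100), c(30, 22, 22), dens[["head"]],
                   subdivisions = subdivisions),
    bird_box("neck", "neck", c(58, -12, 25), c(70, 24, 65), dens[["neck"]]),
    bird_ellipsoid("trunk", "trunk", c(240, 0, 40), c(120, 55, 60),
                   dens[["trunk"]], subdivisions = subdivisions),
    bird_box("forelimb_l", "forelimb", c(160, 55, 30), c(140, 18, 50),
             dens[["forelimb"]]),
    bird_box("forelimb_r", "forelimb", c(160, -73, 30), c(140, 18, 50),
             dens[["forelimb"]]),
    bird_box("hindlimb_l", "hindlimb", c(250, 30, -75), c(25, 20, 90),
             dens[["hindlimb"]]),
    bird_box("hindlimb_r", "hindlimb", c(250, -50, -75), c(25, 20, 90),
             dens[["hindlimb"]]))
  if (cavity) {
    cav_center <- c(190, 0, 55)
    cav_semi <- c(45, 25, 30)
    trunk_center <- c(240, 0, 40)
    trunk_semi <- c(120, 55, 60)
    if (any(abs(cav_center - trunk_center) + cav_semi >= trunk_semi)) {
      abort("air cavity does not fit inside the trunk", class = "commass_validation")
    }
    comps <- dplyr::bind_rows(
      comps,
      bird_ellipsoid("trunk_air", "trunk", cav_center, cav_semi,
                     dens[["trunk"]], role = "air", subdivisions = subdivisions))
  }
  markers <- marker_set(
    label = c("HEAD", "NECKJ", "TAILJ", "WINGL", "WINGR", "FOOTL", "FOOTR"),
    x = c(10, 240 + 120 * cospi(5 / 6), 240 + 120 * cospi(1 / 6), 300, 300, 262.5, 262.5),
    y = c(0, 55 * sinpi(5 / 6), 55 * sinpi(1 / 6), 73, -73, 40, -40),
    z = c(100, 40, 40, 80, 80, -75, -75),
    specimen_id = specimen_id)
  marker_component <- setNames(
    c("head", "trunk", "trunk", "forelimb_l", "forelimb_r",
      "hindlimb_l", "hindlimb_r"), markers$label)
  lengths <- c(x = 360 - 10, y = 2 * 73, z = 122 - (-75))
  new_specimen(comps, markers, marker_component, lengths, specimen_id)
}

#' Rigid posture change of selected segments
#'
#' Rotates the listed segments (meshes, analytic centroids, their cavities and
#' attached markers) rigidly about a joint pivot and recomputes the true CoM
#' from the closed forms. Mass is conserved exactly; the resulting specimen is
#' a discrete posture state of the same body.
#'
#' @param spec A `specimen`.
#' @param pivot Joint centre, mm.
#' @param axis Rotation axis (length-3).
#' @param angle_deg Rotation angle, degrees.
#' @param moving_segments Character vector of segment labels to move (matched
#'   against the component `segment` column) or component ids.
#' @return The reposed `specimen`.
#' @export
simulate_posture_change <- function(spec, pivot, axis, angle_deg, moving_segments) {
  stopifnot(inherits(spec, "specimen"))
  comps <- spec$components
  move <- comps$segment %in% moving_segments | comps$component_id %in% moving_segments
  if (!any(move)) {
    abort(paste0("no component matches segment(s): ",
                 paste(moving_segments, collapse = ", ")),
          class = "commass_validation")
  }
  R <- rotation_about_axis(vec3(axis), angle_deg * pi / 180)
  pivot <- vec3(pivot)
  t <- rigid_transform(R, pivot - as.numeric(R %*% pivot))
  for (i in which(move)) {
    comps$mesh[[i]] <- transform_mesh(comps$mesh[[i]], t)
    ac <- as.numeric(R %*% (c(comps$acx[i], comps$acy[i], comps$acz[i]) - pivot)) + pivot
    comps$acx[i] <- ac[1]; comps$acy[i] <- ac[2]; comps$acz[i] <- ac[3]
  }
  markers <- spec$markers
  moved_ids <- comps$component_id[move]
  mk_move <- spec$marker_component[markers$label] %in% moved_ids
  if (any(mk_move)) {
    moved_part <- apply_transform(as_marker_set(markers[mk_move, ]), t)
    markers[mk_move, c("x", "y", "z")] <- moved_part[, c("x", "y", "z")]
  }
  new_specimen(comps, markers, spec$marker_component, spec$nominal_lengths,
               spec$specimen_id)
}

# Per-axis Gaussian marker jitter.
jitter_markers <- function(ms, sigma) {
  if (sigma <= 0) return(ms)
  n <- nrow(ms)
  ms$x <- ms$x + rnorm(n, 0, sigma)
  ms$y <- ms$y + rnorm(n, 0, sigma)
  ms$z <- ms$z + rnorm(n, 0, sigma)
  ms
}

random_capture_frame <- function(span = 500) {
  rigid_transform(random_rotation(), runif(3, -span, span))
}

#' Simulate a plain marker capture of a specimen
#'
#' Applies marker jitter and (optionally) a random rigid capture frame to the
#' specimen's nominal markers.
#'
#' @param spec A `specimen`.
#' @param noise A [noise_model()].
#' @param seed RNG seed.
#' @param own_frame If `TRUE`, return the capture in a random rigid frame
#'   (forcing downstream registration).
#' @return A marker set.
#' @export
simulate_marker_capture <- function(spec, noise = noise_model(), seed = 1,
                                    own_frame = FALSE) {
  set.seed(seed)
  ms <- jitter_markers(spec$markers, noise$marker_sigma)
  if (own_frame) ms <- apply_transform(ms, random_capture_frame())
  ms
}

#' Simulate suspension captures of a specimen
#'
#' For each hang, an attachment point is sampled on the specimen's bounding
#' surface, stratified across the three planes (each axis gets at least one
#' hang); the ideal string line runs from the attachment through the true CoM
#' (gravity equilibrium). The attachment is perturbed laterally by
#' `attachment_offset_sigma` and the line direction by `string_angle_sigma`;
#' two string markers are placed on the line at least 100 mm apart outside the
#' body; all markers get jitter; and each capture is returned in its own
#' random rigid frame (a different hanging pose each time), so downstream code
#' must register the captures before triangulating.
#'
#' @param spec A `specimen`.
#' @param n_positions Number of hangs (at least 3).
#' @param noise A [noise_model()].
#' @param seed RNG seed; the whole capture list is a deterministic function of
#'   `(spec, n_positions, noise, seed)`.
#' @return A list of marker sets, each containing the specimen markers plus
#'   `STR1`/`STR2`.
#' @export
simulate_suspension_capture <- function(spec, n_positions = 3,
                                        noise = noise_model(), seed = 1) {
  stopifnot(inherits(spec, "specimen"))
  if (n_positions < 3) {
    abort("at least three suspension positions are required",
          class = "commass_validation")
  }
  set.seed(seed)
  lo <- spec$bbox["lo", ]; hi <- spec$bbox["hi", ]
  captures <- vector("list", n_positions)
  for (k in seq_len(n_positions)) {
    ax <- ((k - 1L) %% 3L) + 1L            # stratified: cycle the three planes
    side <- sample(c(0, 1), 1)
    att <- runif(3, lo, hi)
    att[ax] <- if (side == 1) hi[ax] else lo[ax]
    dir <- unit3(spec$true_com - att)
    if (noise$attachment_offset_sigma > 0) {
      u <- perpendicular_of(dir)
      v <- cross3(dir, u)
      att <- att + rnorm(1, 0, noise$attachment_offset_sigma) * u +
                   rnorm(1, 0, noise$attachment_offset_sigma) * v
    }
    if (noise$string_angle_sigma > 0) {
      ang <- rnorm(1, 0, noise$string_angle_sigma * pi / 180)
      pivot_axis <- rotation_about_axis(dir, runif(1, 0, 2 * pi)) %*% perpendicular_of(dir)
      dir <- as.numeric(rotation_about_axis(pivot_axis, ang) %*% dir)
    }
    str1 <- att - 60 * dir
    str2 <- att - 220 * dir
    ms <- spec$markers
    ms <- dplyr::bind_rows(ms, tibble::tibble(
      label = c("STR1", "STR2"),
      x = c(str1[1], str2[1]), y = c(str1[2], str2[2]), z = c(str1[3], str2[3])))
    ms <- as_marker_set(ms)
    ms <- jitter_markers(ms, noise$marker_sigma)
    ms <- apply_transform(ms, random_capture_frame())
    attr(ms, "condition_id") <- sprintf("suspension_%02d", k)
    captures[[k]] <- ms
  }
  captures
}

#' Simulate one scales run for a specimen
#'
#' Places the specimen plank-down along `axis` with its proximal face nominally
#' at the proximal plank edge, offset by the systematic `proximal_skew_delta`;
#' computes the two ideal scale readings from torque balance about the
#' supports; adds reading noise and quantises to the scale resolution. Also
#' emits the plank/ruler marker capture (`PLK1`, `PLK2`, `RUL1`, `RUL2`) in a
#' random rigid capture frame.
#'
#' @param spec A `specimen`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param orientation `"forward"` or `"reversed"`.
#' @param noise A [noise_model()].
#' @param seed RNG seed.
#' @param L Distance between supports, mm (default: specimen length along the
#'   axis).
#' @param dL Proximal plank edge to proximal support, mm.
#' @return A list with `run` (a [scales_run()] row) and `markers` (the
#'   plank/ruler capture).
#' @export
simulate_scales_capture <- function(spec, axis = "x",
                                    orientation = c("forward", "reversed"),
                                    noise = noise_model(), seed = 1,
                                    L = NULL, dL = 15) {
  stopifnot(inherits(spec, "specimen"))
  orientation <- match.arg(orientation)
  set.seed(seed)
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) abort("axis must be x, y or z", class = "commass_validation")
  len <- unname(spec$nominal_lengths[axis])
  if (!is.finite(len) || len <= 0) {
    abort("specimen has no finite length along this axis", class = "commass_validation")
  }
  L <- L %||% len
  c_true <- spec$true_com[ax] - spec$bbox["lo", ax]   # from the proximal face
  c_run <- if (orientation == "forward") c_true else len - c_true
  lever <- noise$proximal_skew_delta + c_run - dL     # CoM to proximal support
  if (lever <= 0 || lever >= L) {
    abort("CoM lies outside the support span; the specimen would tip",
          class = "commass_validation")
  }
  W <- spec$true_mass_kg
  w2 <- W * lever / L
  w1 <- W - w2
  if (noise$scale_reading_sigma > 0) {
    w1 <- w1 + rnorm(1, 0, noise$scale_reading_sigma)
    w2 <- w2 + rnorm(1, 0, noise$scale_reading_sigma)
  }
  if (noise$scale_quantum > 0) {
    w1 <- round(w1 / noise$scale_quantum) * noise$scale_quantum
    w2 <- round(w2 / noise$scale_quantum) * noise$scale_quantum
  }
  run <- scales_run(w1 = max(w1, 0), w2 = max(w2, 0), L = L, dL = dL,
                    axis = axis, orientation = orientation, length_mm = len)
  # plank along the measurement axis, ruler perpendicular in the table plane
  e1 <- diag(3)[ax, ]
  e2 <- diag(3)[(ax %% 3) + 1, ]
  plank_len <- L + 2 * dL
  ms <- marker_set(label = c("PLK1", "PLK2", "RUL1", "RUL2"),
                   x = c(0, plank_len * e1[1], 0, 500 * e2[1]),
                   y = c(0, plank_len * e1[2], 0, 500 * e2[2]),
                   z = c(0, plank_len * e1[3], 0, 500 * e2[3]))
  ms <- jitter_markers(ms, noise$marker_sigma)
  ms <- apply_transform(ms, random_capture_frame())
  list(run = run, markers = ms)
}

#' Full simulated scales study of a specimen
#'
#' Runs [simulate_scales_capture()] for each requested axis (forward, plus
#' reversed repeats if asked) and stacks the runs.
#'
#' @param spec A `specimen`.
#' @param axes Axes to measure.
#' @param reversed Include reversed repeats?
#' @param noise A [noise_model()].
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @param dL Plank-edge-to-support distance, mm.
#' @return A `scales_runs` tibble.
#' @export
simulate_scales_runs <- function(spec, axes = c("x", "y", "z"), reversed = TRUE,
                                 noise = noise_model(), seed = 1, dL = 15) {
  counter <- 0L
  rows <- list()
  for (axis in axes) {
    for (ori in if (reversed) c("forward", "reversed") else "forward") {
      counter <- counter + 1L
      cap <- simulate_scales_capture(spec, axis = axis, orientation = ori,
                                     noise = noise,
                                     seed = derive_seed(seed, counter), dL = dL)
      rows[[counter]] <- cap$run
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scales_runs", class(out))
  out
}
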