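test_that("synthetic bricks carry analytic truth consistent with the mesh", {
  b1 <- make_brick(dims = c(216, 99, 67), mass_kg = 3.13)
  expect_equal(b1$true_mass_kg, 3.13)
  expect_equal(b1$true_com, c(108, 49.5, 33.5))
  expect_equal(b1$nominal_lengths, c(x = 216, y = 99, z = 67))

  cube <- make_brick(dims = c(1, 1, 1), density = 1000)
  expect_equal(cube$true_com, c(0.5, 0.5, 0.5))
  expect_equal(cube$true_mass_kg, 1e-6)

  est <- composite_com(b1$components)
  expect_lt(dist3(est$com, b1$true_com), 1e-9)
  expect_equal(est$mass_kg, b1$true_mass_kg, tolerance = 1e-12)

  expect_error(make_brick(dims = c(0, 10, 10)), class = "commass_validation")
})

test_that("bird-like specimens agree between analytic and mesh pipelines", {
  bird <- make_birdlike()
  est <- composite_com(bird$components, check_containment = FALSE)
  expect_lt(dist3(est$com, bird$true_com), 0.1)

  # markers sit on (or within a hair of) the body: every marker is inside a
  # slightly inflated bounding box
  lo <- bird$bbox["lo", ]; hi <- bird$bbox["hi", ]
  m <- as.matrix(bird$markers[, c("x", "y", "z")])
  expect_true(all(t(m) >= lo - 1e-9 & t(m) <= hi + 1e-9))

  solo <- make_birdlike(cavity = FALSE)
  expect_gt(solo$true_mass_kg, bird$true_mass_kg)
  # the cavity sits cranially and dorsally, so removing its mass moves the
  # CoM caudally and ventrally
  expect_gt(bird$true_com[1], solo$true_com[1])
  expect_lt(bird$true_com[3], solo$true_com[3])
})

test_that("suspension simulation is deterministic and closes noiselessly", {
  brick <- make_brick()
  caps_a <- simulate_suspension_capture(brick, 4, noise_model(), seed = 99)
  caps_b <- simulate_suspension_capture(brick, 4, noise_model(), seed = 99)
  expect_identical(caps_a, caps_b)

  caps0 <- simulate_suspension_capture(brick, 5, noise_model_zero(), seed = 7)
  est <- estimate_com_suspension_from_captures(caps0, reference = brick$markers)
  expect_lt(dist3(est$com, brick$true_com), 1e-9)
  expect_lt(max(est$intermediates$gap), 1e-9)
  expect_lt(max(est$registration$rmsd), 1e-9)

  expect_error(simulate_suspension_capture(brick, 2, noise_model()),
               class = "commass_validation")
})

test_that("string markers are far apart and each capture is in its own frame", {
  brick <- make_brick()
  caps <- simulate_suspension_capture(brick, 3, noise_model_zero(), seed = 3)
  for (cap in caps) {
    s <- cap[cap$label %in% c("STR1", "STR2"), ]
    expect_gte(dist3(c(s$x[1], s$y[1], s$z[1]), c(s$x[2], s$y[2], s$z[2])),
               100)
  }
  # frames differ: raw marker positions disagree across captures even though
  # the specimen is rigid
  a <- caps[[1]][caps[[1]]$label == "A", c("x", "y", "z")]
  b <- caps[[2]][caps[[2]]$label == "A", c("x", "y", "z")]
  expect_gt(dist3(unlist(a), unlist(b)), 1)
})

test_that("scales simulation closes, reproduces the skew, and cancels it", {
  brick <- make_brick()
  # noiseless closure, all axes, forward only
  runs0 <- simulate_scales_runs(brick, reversed = FALSE,
                                noise = noise_model_zero(), seed = 5)
  ax0 <- axis_coms_from_runs(runs0)
  truth <- brick$true_com - brick$bbox["lo", ]
  expect_equal(ax0$com_mm[match(c("x", "y", "z"), ax0$axis)],
               unname(truth), tolerance = 1e-9)

  # a 5 mm proximal skew biases every forward axis by exactly +5 mm ...
  nm_skew <- noise_model(marker_sigma = 0, proximal_skew_delta = 5,
                         scale_quantum = 0)
  runs_f <- simulate_scales_runs(brick, reversed = FALSE, noise = nm_skew,
                                 seed = 6)
  ax_f <- axis_coms_from_runs(runs_f)
  expect_equal(ax_f$com_mm[match(c("x", "y", "z"), ax_f$axis)] - unname(truth),
               rep(5, 3), tolerance = 1e-9)

  # ... and the reversed repeats cancel it exactly
  runs_fr <- simulate_scales_runs(brick, reversed = TRUE, noise = nm_skew,
                                  seed = 6)
  ax_fr <- axis_coms_from_runs(runs_fr)
  expect_equal(ax_fr$com_mm[match(c("x", "y", "z"), ax_fr$axis)],
               unname(truth), tolerance = 1e-9)

  est <- assemble_3d(ax_fr, proximal_reference_point = brick$bbox["lo", ])
  expect_lt(dist3(est$com, brick$true_com), 1e-9)
})

test_that("0.1 g quantisation alone induces a sub-0.05 mm CoM error", {
  brick <- make_brick()  # 3.13 kg
  nm <- noise_model(marker_sigma = 0, scale_quantum = 1e-4)
  errs <- vapply(1:50, function(s) {
    runs <- simulate_scales_runs(brick, axes = "x", reversed = FALSE,
                                 noise = nm, seed = s)
    abs(axis_coms_from_runs(runs)$com_mm - (brick$true_com[1] - brick$bbox["lo", 1]))
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("scales capture emits a plank/ruler frame that registration recovers", {
  brick <- make_brick()
  cap <- simulate_scales_capture(brick, axis = "x", noise = noise_model_zero(),
                                 seed = 8)
  m <- cap$markers
  frame <- build_world_frame(m[m$label == "PLK1", ], m[m$label == "PLK2", ],
                             m[m$label == "RUL1", ], m[m$label == "RUL2", ])
  aligned <- apply_transform(m, frame)
  # plank back on the first axis, ruler in the plane of the second
  expect_equal(aligned$y[aligned$label == "PLK2"], 0, tolerance = 1e-6)
  expect_equal(aligned$z[aligned$label == "PLK2"], 0, tolerance = 1e-6)
  expect_equal(aligned$z[aligned$label == "RUL2"], 0, tolerance = 1e-6)
  expect_gt(aligned$x[aligned$label == "PLK2"], 0)
})

test_that("posture changes are rigid per segment and conserve mass", {
  bird <- make_birdlike()
  same <- simulate_posture_change(bird, c(0, 0, 0), c(0, 0, 1), 0, "hindlimb")
  expect_equal(same$true_com, bird$true_com, tolerance = 1e-12)
  expect_identical(same$true_mass_kg, bird$true_mass_kg)

  # rotating a segment about an axis through its own centroid leaves the
  # composite CoM unchanged
  hl <- bird$components[bird$components$component_id == "hindlimb_l", ]
  centroid <- c(hl$acx, hl$acy, hl$acz)
  spun <- simulate_posture_change(bird, centroid, c(0, 0, 1), 90, "hindlimb_l")
  expect_equal(spun$true_com, bird$true_com, tolerance = 1e-9)

  # a hip rotation matches the point-mass lever closed form
  pivot <- c(262.5, 0, 15)
  bent <- simulate_posture_change(bird, pivot, c(0, 1, 0), 45, "hindlimb")
  expect_equal(bent$true_mass_kg, bird$true_mass_kg, tolerance = 1e-15)
  comp <- bird$components
  move <- comp$segment == "hindlimb"
  mass <- comp$density * comp$vol_mm3 * 1e-9 *
    ifelse(comp$role == "flesh", 1, -1)
  R <- rotation_y(45 * pi / 180)
  shift <- rep(0, 3)
  for (i in which(move)) {
    old <- c(comp$acx[i], comp$acy[i], comp$acz[i])
    new <- as.numeric(R %*% (old - pivot)) + pivot
    shift <- shift + mass[i] * (new - old)
  }
  expect_equal(bent$true_com - bird$true_com, shift / sum(mass),
               tolerance = 1e-9)

  expect_error(simulate_posture_change(bird, c(0, 0, 0), c(0, 0, 1), 10, "tail"),
               class = "commass_validation")
})
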