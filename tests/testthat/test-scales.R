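test_that("1D CoM from a scales run follows torque balance", {
  expect_equal(com_1d_from_run(scales_run(1, 1, L = 100, dL = 10))$com_mm, 60)
  expect_equal(com_1d_from_run(scales_run(2.5, 0, L = 300, dL = 12))$com_mm, 12)
  # frozen from the independent torque-balance solution about the proximal
  # support: x = W2 * L / W = 1 * 200 / 4 = 50, plus dL
  expect_equal(com_1d_from_run(scales_run(3, 1, L = 200, dL = 15))$com_mm, 65)

  expect_error(scales_run(0, 0, L = 100, dL = 0), class = "commass_validation")
  expect_error(scales_run(1, 1, L = -5, dL = 0), class = "commass_validation")
})

test_that("1D CoM always lies within the support span", {
  set.seed(13)
  for (k in 1:200) {
    run <- scales_run(runif(1, 0, 5), runif(1, 1e-6, 5),
                      L = runif(1, 50, 500), dL = runif(1, 0, 30))
    com <- com_1d_from_run(run)$com_mm
    expect_gte(com, run$dL)
    expect_lte(com, run$dL + run$L)
  }
})

test_that("taring offset shifts asymmetric runs toward the midpoint", {
  base <- scales_run(3, 1, L = 200, dL = 0)
  tared <- scales_run(3 + 0.5, 1 + 0.5, L = 200, dL = 0)
  mid <- 100
  expect_lt(abs(com_1d_from_run(tared)$com_mm - mid),
            abs(com_1d_from_run(base)$com_mm - mid))
  sym <- com_1d_from_run(scales_run(2, 2, L = 200, dL = 0))$com_mm
  sym_tared <- com_1d_from_run(scales_run(2.5, 2.5, L = 200, dL = 0))$com_mm
  expect_equal(sym, sym_tared)
})

test_that("forward/reversed combination cancels additive placement skew exactly", {
  # consistency cases first
  fwd <- com_1d_from_run(scales_run(1, 1, L = 200, dL = 10,
                                    orientation = "forward", length_mm = 216))
  rev <- com_1d_from_run(scales_run(1, 1, L = 200, dL = 10,
                                    orientation = "reversed", length_mm = 216))
  comb <- combine_forward_reversed(fwd, rev)
  expect_equal(comb$com_mm, (fwd$com_mm + (216 - rev$com_mm)) / 2)

  # arithmetic of the stated rule
  fwd$com_mm <- 110; rev$com_mm <- 106
  expect_equal(combine_forward_reversed(fwd, rev)$com_mm, (110 + 110) / 2)

  # property: any additive proximal skew delta cancels exactly
  c_true <- 83.2
  len <- 216
  for (delta in seq(-20, 20, by = 2.5)) {
    f <- fwd; f$com_mm <- c_true + delta
    r <- rev; r$com_mm <- (len - c_true) + delta
    expect_equal(combine_forward_reversed(f, r)$com_mm, c_true,
                 tolerance = 1e-12)
  }

  r_bad <- rev; r_bad$axis <- "y"
  expect_error(combine_forward_reversed(fwd, r_bad), class = "commass_validation")
})

test_that("world frame construction recovers plank/ruler geometry", {
  id <- build_world_frame(c(0, 0, 0), c(100, 0, 0), c(0, 0, 0), c(0, 80, 0))
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)

  set.seed(17)
  R <- rand_rigid(span = 0)$rotation
  pts <- list(c(0, 0, 0), c(100, 0, 0), c(0, 0, 0), c(0, 80, 0))
  rot <- lapply(pts, function(p) as.numeric(R %*% p))
  frame <- build_world_frame(rot[[1]], rot[[2]], rot[[3]], rot[[4]])
  expect_equal(frame$rotation, t(R), tolerance = 1e-9)

  # ruler at 80 degrees to the plank still yields an orthonormal frame whose
  # second axis spans the ruler's in-plane component
  ruler_dir <- c(cos(80 * pi / 180), sin(80 * pi / 180), 0)
  fr <- build_world_frame(c(0, 0, 0), c(100, 0, 0), c(0, 0, 0), 200 * ruler_dir)
  expect_equal(crossprod(fr$rotation), diag(3), tolerance = 1e-9)
  mapped <- as.numeric(fr$rotation %*% ruler_dir)
  expect_equal(mapped[3], 0, tolerance = 1e-9)
  expect_gt(mapped[2], 0)

  expect_error(build_world_frame(c(0, 0, 0), c(100, 0, 0),
                                 c(0, 0, 0), c(100, 2, 0)),
               class = "commass_degeneracy")
})

test_that("per-axis coordinates assemble into 3D or 1D estimates", {
  axis_coms <- tibble::tibble(axis = c("x", "y", "z"),
                              com_mm = c(108, 49.5, 33.5))
  est <- assemble_3d(axis_coms)
  expect_equal(est$com, c(108, 49.5, 33.5))
  expect_equal(est$method, "scales")

  one <- assemble_3d(tibble::tibble(axis = "x", com_mm = 230))
  expect_equal(length(one$com), 1L)
  expect_equal(one$axis, "x")

  expect_error(assemble_3d(tibble::tibble(axis = c("x", "x", "z"),
                                          com_mm = c(1, 2, 3))),
               class = "commass_validation")
})

test_that("scales error scales linearly with reading noise", {
  brick <- make_brick()
  sigmas <- c(1e-4, 1e-3, 1e-2)
  med_err <- vapply(seq_along(sigmas), function(si) {
    nm <- noise_model(marker_sigma = 0, scale_reading_sigma = sigmas[si],
                      scale_quantum = 0)
    # common random numbers across the sigma ladder: the same replicate seed
    # reuses the same standardised draws, isolating the pure sigma scaling
    errs <- vapply(1:200, function(r) {
      runs <- simulate_scales_runs(brick, axes = "x", reversed = FALSE,
                                   noise = nm, seed = r)
      abs(axis_coms_from_runs(runs)$com_mm -
            (brick$true_com[1] - brick$bbox["lo", 1]))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  slope <- diff(log(med_err)) / diff(log(sigmas))
  expect_true(all(abs(slope - 1) < 0.1))
})
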