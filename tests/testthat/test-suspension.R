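test_that("string-marker lines are built and offset-corrected correctly", {
  ms <- marker_set(c("STR1", "STR2"), x = c(0, 0), y = c(0, 0), z = c(0, 100))
  ln <- line_from_string_markers(ms)
  expect_equal(c(ln$px, ln$py, ln$pz), c(0, 0, 0))
  expect_equal(c(ln$dx, ln$dy, ln$dz), c(0, 0, 1))

  near <- marker_set(c("STR1", "STR2"), x = c(0, 0), y = c(0, 0), z = c(0, 5))
  expect_error(line_from_string_markers(near), class = "commass_degeneracy")

  # correcting the marker-radius offset shifts the line by exactly 6.35 mm
  # perpendicular to itself
  corr <- line_from_string_markers(ms, correct_radius_offset = TRUE,
                                   offset_normal = c(1, 0, 0))
  expect_equal(c(corr$dx, corr$dy, corr$dz), c(ln$dx, ln$dy, ln$dz))
  expect_equal(corr$px - ln$px, marker_radius_mm())
})

test_that("closest point of approach solves intersecting and skew cases", {
  a <- suspension_line(c(1, 2, 3), c(1, 0, 0))
  b <- suspension_line(c(1, 2, 3), c(0, 1, 0))
  cpa <- closest_point_of_approach(a, b)
  expect_equal(cpa$midpoint, c(1, 2, 3), tolerance = 1e-12)
  expect_equal(cpa$gap, 0, tolerance = 1e-12)

  a <- suspension_line(c(0, 0, 0), c(1, 0, 0))
  b <- suspension_line(c(0, 0, 1), c(0, 1, 0))
  cpa <- closest_point_of_approach(a, b)
  expect_equal(cpa$point_a, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(cpa$point_b, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(cpa$midpoint, c(0, 0, 0.5), tolerance = 1e-12)
  expect_equal(cpa$gap, 1, tolerance = 1e-12)

  par_b <- suspension_line(c(0, 5, 0), c(-1, 0, 0))
  expect_error(closest_point_of_approach(a, par_b), class = "commass_degeneracy",
               regexp = "5")
})

test_that("the connecting segment is perpendicular to both lines", {
  set.seed(21)
  for (k in 1:50) {
    a <- suspension_line(runif(3, -100, 100), rand_unit())
    b <- suspension_line(runif(3, -100, 100), rand_unit())
    cpa <- closest_point_of_approach(a, b)
    seg <- cpa$point_a - cpa$point_b
    expect_lt(abs(sum(seg * c(a$dx, a$dy, a$dz))), 1e-9)
    expect_lt(abs(sum(seg * c(b$dx, b$dy, b$dz))), 1e-9)
  }
})

test_that("suspension CoM enumerates all pairs and recovers concurrency", {
  com <- c(10, -5, 20)
  set.seed(2)
  mk_lines <- function(n) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      d <- rand_unit()
      suspension_line(com + runif(1, 20, 80) * d, d, as.character(i))
    }))
  }
  lines3 <- mk_lines(3)
  est3 <- estimate_com_suspension(lines3)
  expect_equal(est3$n_pairs, 3L)
  expect_equal(est3$com, com, tolerance = 1e-9)
  expect_lt(max(est3$intermediates$gap), 1e-9)

  lines10 <- mk_lines(10)
  est10 <- estimate_com_suspension(lines10)
  expect_equal(est10$n_pairs, 45L)
  expect_equal(est10$com, com, tolerance = 1e-9)

  expect_error(estimate_com_suspension(lines3[1, ]),
               class = "commass_insufficient_data")
})

test_that("suspension estimate is equivariant under rigid transforms", {
  set.seed(31)
  lines <- dplyr::bind_rows(lapply(1:5, function(i) {
    suspension_line(runif(3, -50, 50), rand_unit(), as.character(i))
  }))
  est <- estimate_com_suspension(lines)
  for (k in 1:10) {
    t <- rand_rigid()
    est_t <- estimate_com_suspension(transform_lines(lines, t))
    expect_equal(est_t$com,
                 as.numeric(t$rotation %*% est$com) + t$translation,
                 tolerance = 1e-9)
  }
})

test_that("parallel pairs are skipped with a warning, not silently dropped", {
  lines <- dplyr::bind_rows(
    suspension_line(c(0, 0, 0), c(1, 0, 0), "1"),
    suspension_line(c(0, 10, 0), c(1, 0, 0), "2"),
    suspension_line(c(5, 0, 0), c(0, 1, 0), "3"))
  expect_warning(est <- estimate_com_suspension(lines), "parallel")
  expect_equal(est$n_pairs, 2L)
  expect_equal(est$n_parallel_skipped, 1L)
})

test_that("mean gap grows monotonically with angular noise", {
  com <- c(0, 0, 0)
  sigmas <- c(0, 0.5, 1, 2)
  mean_gaps <- vapply(seq_along(sigmas), function(si) {
    sigma <- sigmas[si]
    set.seed(1000 + si)
    gaps <- replicate(100, {
      lines <- dplyr::bind_rows(lapply(1:3, function(i) {
        d0 <- rand_unit()
        att <- com - 80 * d0          # attachment anchored on the ideal line
        d <- if (sigma > 0) tilt_direction(d0, rnorm(1, 0, sigma)) else d0
        suspension_line(att, d, as.character(i))
      }))
      mean(estimate_com_suspension(lines)$intermediates$gap)
    })
    mean(gaps)
  }, numeric(1))
  expect_equal(mean_gaps[1], 0, tolerance = 1e-9)
  expect_true(all(diff(mean_gaps) > 0))
})

test_that("suspension error improves from 3 to 10 positions under noise", {
  brick <- make_brick()
  nm <- noise_model(marker_sigma = 0, string_angle_sigma = 1,
                    attachment_offset_sigma = 0)
  err <- function(n, seed) {
    caps <- simulate_suspension_capture(brick, n, nm, seed = seed)
    est <- estimate_com_suspension_from_captures(caps, reference = brick$markers)
    dist3(est$com, brick$true_com)
  }
  e3 <- vapply(1:60, function(s) err(3, s), numeric(1))
  e10 <- vapply(1:60, function(s) err(10, s), numeric(1))
  expect_lt(median(e10), median(e3))
})
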