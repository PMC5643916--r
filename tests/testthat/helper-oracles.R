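# Independent numerical oracles used to cross-check closed-form results.

# Minimum distance between two lines by numerical minimisation of the
# 2-parameter inter-point distance: a finite-difference Newton step (exact for
# a quadratic objective) followed by a BFGS polish.
oracle_line_gap <- function(p1, d1, p2, d2) {
  f <- function(st) sum((p1 + st[1] * d1 - p2 - st[2] * d2)^2)
  h <- 1
  g <- c((f(c(h, 0)) - f(c(-h, 0))) / (2 * h),
         (f(c(0, h)) - f(c(0, -h))) / (2 * h))
  f0 <- f(c(0, 0))
  H <- matrix(c((f(c(h, 0)) - 2 * f0 + f(c(-h, 0))) / h^2,
                (f(c(h, h)) - f(c(h, -h)) - f(c(-h, h)) + f(c(-h, -h))) / (4 * h^2),
                (f(c(h, h)) - f(c(h, -h)) - f(c(-h, h)) + f(c(-h, -h))) / (4 * h^2),
                (f(c(0, h)) - 2 * f0 + f(c(0, -h))) / h^2), 2, 2)
  st <- -solve(H, g)
  fit <- optim(st, f, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 200))
  sqrt(min(f(st), fit$value))
}

# Best rigid superposition RMSD by numerical minimisation over Euler angles
# and translation, multi-start to dodge local minima.
oracle_rigid_rmsd <- function(P, Q, n_starts = 8) {
  obj <- function(par) {
    R <- commass::rotation_z(par[3]) %*% commass::rotation_y(par[2]) %*%
      commass::rotation_x(par[1])
    fitted <- P %*% t(R) + matrix(par[4:6], nrow(P), 3, byrow = TRUE)
    sum((Q - fitted)^2)
  }
  best <- Inf
  for (k in seq_len(n_starts)) {
    start <- c(runif(3, -pi, pi), colMeans(Q) - colMeans(P))
    fit <- optim(start, obj, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 2000))
    best <- min(best, fit$value)
  }
  sqrt(best / nrow(P))
}

# Random unit vector / random rigid transform drawing from the current RNG.
rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

rand_rigid <- function(span = 100) {
  M <- matrix(rnorm(9), 3, 3)
  qrd <- qr(M)
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rigid_transform(Q, runif(3, -span, span))
}

# A well-conditioned 5-marker test cloud.
test_markers <- function() {
  marker_set(c("A", "B", "C", "D", "E"),
             x = c(0, 100, 0, 0, 60),
             y = c(0, 0, 80, 10, 50),
             z = c(0, 0, 0, 60, 40))
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

marker_matrix_of <- function(ms) as.matrix(ms[, c("x", "y", "z")])

# Tilt a unit direction by `deg` degrees about a random perpendicular axis
# (Rodrigues form, written out so it stays independent of package internals).
tilt_direction <- function(d, deg) {
  perp <- rnorm(3)
  perp <- perp - sum(perp * d) * d
  u <- perp / sqrt(sum(perp^2))
  ang <- deg * pi / 180
  d * cos(ang) + c(u[2] * d[3] - u[3] * d[2],
                   u[3] * d[1] - u[1] * d[3],
                   u[1] * d[2] - u[2] * d[1]) * sin(ang) +
    u * sum(u * d) * (1 - cos(ang))
}
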