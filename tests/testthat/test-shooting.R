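test_that("kernel matrix is a unit-diagonal Gaussian", {
  a <- matrix(c(0, 0, 1, 0, 0, 3), 3, 2, byrow = TRUE)
  K <- kernel_matrix(a, a, sigma = 1)
  expect_equal(diag(K), rep(1, 3))
  expect_equal(K, t(K))
  expect_equal(K[1, 2], exp(-0.5))
  expect_lt(kernel_matrix(matrix(c(0, 0), 1), matrix(c(10, 0), 1), 1)[1, 1],
            1e-21)
})

test_that("rhs vector-Jacobian product matches numeric differentiation", {
  set.seed(11)
  q <- matrix(rnorm(10), 5, 2); p <- matrix(rnorm(10), 5, 2)
  a <- matrix(rnorm(10), 5, 2); b <- matrix(rnorm(10), 5, 2)
  sig <- 1.3
  vjp <- lgrbsn:::shooting_vjp(q, p, a, b, sig)
  L <- function(qq, pp) {
    f <- lgrbsn:::shooting_rhs(qq, pp, sig)
    sum(a * f$dq) + sum(b * f$dp)
  }
  h <- 1e-6
  for (i in 1:5) for (k in 1:2) {
    qp <- q; qp[i, k] <- qp[i, k] + h
    qm <- q; qm[i, k] <- qm[i, k] - h
    expect_equal(vjp$gq[i, k], (L(qp, p) - L(qm, p)) / (2 * h), tolerance = 1e-5)
    pp <- p; pp[i, k] <- pp[i, k] + h
    pm <- p; pm[i, k] <- pm[i, k] - h
    expect_equal(vjp$gp[i, k], (L(q, pp) - L(q, pm)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("objective gradient through RK4 matches finite differences", {
  set.seed(5)
  q0 <- matrix(rnorm(8), 4, 2)
  corr <- landmark_correspondence(q0, q0 + matrix(rnorm(8, sd = 0.4), 4, 2), 0.1)
  p0 <- matrix(0.2, 4, 2)
  ob <- lgrbsn:::shooting_objective(p0, corr, sigma = 1.5, steps = 8)
  h <- 1e-6
  for (i in 1:4) for (k in 1:2) {
    pp <- p0; pp[i, k] <- pp[i, k] + h
    pm <- p0; pm[i, k] <- pm[i, k] - h
    num <- (lgrbsn:::shooting_objective(pp, corr, 1.5, 8, want_grad = FALSE)$value -
            lgrbsn:::shooting_objective(pm, corr, 1.5, 8, want_grad = FALSE)$value) / (2 * h)
    expect_equal(ob$grad[i, k], num, tolerance = 1e-5)
  }
})

test_that("single-landmark geodesic is a straight unit-speed line", {
  st <- shoot(matrix(c(0, 0), 1), matrix(c(1, 0), 1), sigma = 2, steps = 20)
  expect_equal(st$q[21, 1, ], c(1, 0), tolerance = 1e-9)
  expect_equal(st$p[21, 1, ], c(1, 0), tolerance = 1e-12)
  # zero momentum keeps everything still with zero energy
  st0 <- shoot(matrix(c(2, 3), 1), matrix(c(0, 0), 1), sigma = 2, steps = 5)
  expect_equal(st0$q[6, 1, ], c(2, 3))
  expect_identical(hamiltonian(matrix(c(2, 3), 1), matrix(c(0, 0), 1), 2), 0)
})

test_that("far-separated landmarks decouple into isolated flows", {
  sig <- 1
  q0 <- matrix(c(0, 0, 10, 0), 2, 2, byrow = TRUE)   # 10 sigma apart
  p0 <- matrix(c(0.8, 0.3, -0.8, -0.3), 2, 2, byrow = TRUE)
  st <- shoot(q0, p0, sig, steps = 20)
  s1 <- shoot(q0[1, , drop = FALSE], p0[1, , drop = FALSE], sig, steps = 20)
  s2 <- shoot(q0[2, , drop = FALSE], p0[2, , drop = FALSE], sig, steps = 20)
  expect_lt(max(abs(st$q[21, 1, ] - s1$q[21, 1, ])), 1e-6)
  expect_lt(max(abs(st$q[21, 2, ] - s2$q[21, 1, ])), 1e-6)
})

test_that("Hamiltonian is conserved and drift shrinks with step refinement", {
  set.seed(3)
  q0 <- matrix(runif(20, 0, 4), 10, 2)
  p0 <- matrix(rnorm(20, sd = 1), 10, 2)
  drift <- function(steps) {
    st <- shoot(q0, p0, sigma = 1.5, steps = steps)
    n <- steps + 1
    h0 <- hamiltonian(q0, p0, 1.5)
    h1 <- hamiltonian(matrix(st$q[n, , ], ncol = 2),
                      matrix(st$p[n, , ], ncol = 2), 1.5)
    abs(h1 - h0) / max(abs(h0), 1e-12)
  }
  expect_lt(drift(20), 0.01)
  expect_lt(drift(10), drift(5))
})

test_that("momentum optimization solves the analytic one-pair problem", {
  # already matched: zero momentum, zero objective
  q <- matrix(c(1, 2, 3, 1), 2, 2, byrow = TRUE)
  m0 <- optimize_momentum(landmark_correspondence(q, q, 0.1), sigma = 1)
  expect_equal(max(abs(m0$p0)), 0)
  expect_equal(m0$objective_trace[length(m0$objective_trace)], 0)

  # one pair (0,0) -> (1,0), sigma 1, Sigma = 1e-4: p0 ~ (1, 0)
  m1 <- optimize_momentum(
    landmark_correspondence(matrix(c(0, 0), 1), matrix(c(1, 0), 1), 1e-4),
    sigma = 1)
  expect_lt(sqrt(sum((m1$state$q[dim(m1$state$q)[1], 1, ] - c(1, 0))^2)), 0.01)
  expect_equal(m1$p0[1, 1], 1, tolerance = 0.02)
  expect_lt(abs(m1$p0[1, 2]), 0.02)
  # trace is non-increasing and ends no higher than it starts
  expect_true(all(diff(m1$objective_trace) <= 1e-12))
})

test_that("large-kernel two-pair translation is recovered rigidly", {
  q0 <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  y <- q0 + rep(c(1, 0), each = 2)
  m <- optimize_momentum(landmark_correspondence(q0, y, 1e-4), sigma = 10)
  ends <- m$state$q[dim(m$state$q)[1], , ]
  expect_lt(max(sqrt(rowSums((ends - y)^2))), 0.01)
  expect_lt(max(abs(m$p0[1, ] - m$p0[2, ])) / max(abs(m$p0)), 0.01)
})

test_that("gradient-descent path also reduces the objective monotonically", {
  set.seed(9)
  q0 <- matrix(runif(12, 0, 5), 6, 2)
  corr <- landmark_correspondence(q0, q0 + matrix(rnorm(12, sd = 0.5), 6, 2), 0.05)
  m <- optimize_momentum(corr, sigma = 2, max_iter = 50, method = "gd")
  expect_true(all(diff(m$objective_trace) <= 1e-12))
  expect_lt(mean(m$matching_error), mean(sqrt(rowSums((corr$fixed - corr$moving)^2) / 0.05)))
})

test_that("exact-matching limit: shrinking covariance shrinks the miss", {
  errs <- vapply(c(1, 0.1, 0.01, 0.001), function(s2) {
    m <- optimize_momentum(
      landmark_correspondence(matrix(c(0, 0), 1), matrix(c(1, 0), 1), s2),
      sigma = 1)
    sqrt(sum((m$state$q[dim(m$state$q)[1], 1, ] - c(1, 0))^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("rasterized fields reproduce landmark flow and decay", {
  g <- lg_grid(c(21, 21), origin = c(-10, -10))
  zero <- shoot(matrix(c(0, 0), 1), matrix(c(0, 0), 1), sigma = 2, steps = 10)
  expect_equal(max(abs(rasterize_field(zero, g, "forward")$values)), 0)

  st <- shoot(matrix(c(0, 0), 1), matrix(c(1, 0), 1), sigma = 1, steps = 20)
  fwd <- rasterize_field(st, g, "forward")
  # at the landmark: the full unit displacement; far away: Gaussian decay
  expect_equal(fwd$values[11, 11, ], c(1, 0), tolerance = 1e-6)
  far <- sqrt(fwd$values[21, 11, 1]^2 + fwd$values[21, 11, 2]^2)
  expect_lt(far, 1e-6)
})

test_that("forward and reversed flows are mutually consistent", {
  ph <- small_phantom()
  corr <- landmark_correspondence(ph$moving_landmarks[[2]],
                                  ph$fixed_landmarks[[2]], 0.01)
  m <- optimize_momentum(corr, sigma = 5, steps = 40)
  g <- ph$fixed$grid
  fwd <- rasterize_field(m$state, g, "forward")
  rev <- rasterize_field(m$state, g, "reverse")
  # U_rev(U_fwd(x)) ~ x on nearly all grid points
  pts <- grid_points(g)
  there <- pts + lgrbsn:::field_matrix(fwd)
  back <- there + lgrbsn:::interp_field_at(rev, there)
  err <- sqrt(rowSums((back - pts)^2))
  expect_gt(mean(err < 0.1), 0.99)
  # the rasterized forward field reproduces the landmark endpoints
  lmflow <- lgrbsn:::interp_field_at(fwd, corr$moving)
  ends <- m$state$q[dim(m$state$q)[1], , ]
  expect_lt(max(sqrt(rowSums((corr$moving + lmflow - ends)^2))), 0.05)
})

test_that("register_region is diffeomorphic and symmetric in its roles", {
  ph <- small_phantom()
  g <- ph$fixed$grid
  # identity correspondence: both fields vanish
  idc <- landmark_correspondence(ph$fixed_landmarks[[1]],
                                 ph$fixed_landmarks[[1]], 0.01)
  reg0 <- register_region(idc, sigma = 5, g, g)
  expect_lt(max(abs(reg0$forward$values)), 1e-9)
  expect_lt(max(abs(reg0$reverse$values)), 1e-9)

  corr <- landmark_correspondence(ph$moving_landmarks[[2]],
                                  ph$fixed_landmarks[[2]], 0.01)
  reg <- register_region(corr, sigma = 5, g, g)
  expect_identical(count_nonpositive_jacobian(deformation_map(reg$forward)), 0L)
  expect_identical(count_nonpositive_jacobian(deformation_map(reg$reverse)), 0L)
  # post-warp landmark error stays sub-pixel
  ends <- corr$moving + lgrbsn:::interp_field_at(reg$forward, corr$moving)
  expect_lt(sqrt(mean(rowSums((ends - corr$fixed)^2))), 0.25)

  # swapping moving/fixed swaps forward and reverse roles
  swapped <- register_region(
    landmark_correspondence(corr$fixed, corr$moving, 0.01), sigma = 5, g, g)
  pts <- grid_points(g)
  there <- pts + lgrbsn:::field_matrix(reg$forward)
  back <- there + lgrbsn:::interp_field_at(swapped$forward, there)
  expect_lt(mean(sqrt(rowSums((back - pts)^2))), 0.1)
})

test_that("landmark caps thin the correspondence before optimization", {
  set.seed(2)
  q0 <- matrix(runif(600, 0, 20), 300, 2)
  corr <- landmark_correspondence(q0, q0, 0.1)
  g <- lg_grid(c(8, 8))
  reg <- register_region(corr, sigma = 5, g, g, max_landmarks = 50L,
                         steps = 2L, max_iter = 2L)
  expect_lte(nrow(reg$match$corr$moving), 50L)
})
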