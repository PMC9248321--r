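test_that("residual vanishes exactly for mutual inverses", {
  g <- lg_grid(c(10, 10))
  z_f <- displacement_field(g, 0, "subject", "forward")
  z_r <- displacement_field(g, 0, "template", "reverse")
  expect_equal(max(abs(residual(z_f, z_r)$values)), 0)

  pf <- displacement_field(g, c(1.5, -0.5), "subject", "forward")
  pr <- displacement_field(g, c(-1.5, 0.5), "template", "reverse")
  expect_equal(max(abs(residual(pf, pr)$values)), 0)

  # one-sided translation leaves exactly that translation as residual
  r <- residual(displacement_field(g, c(1, 0), "subject", "forward"), z_r)
  expect_equal(r$values[, , 1], array(1, c(10, 10)))
  expect_equal(r$values[, , 2], array(0, c(10, 10)))
  expect_error(residual(pf, pf), "forward and one reverse")
})

test_that("demons velocity follows the stabilized gradient formula", {
  g <- lg_grid(c(11, 5))
  edge5 <- array(0L, c(11, 5)); edge5[1:5, ] <- 1L
  edge6 <- array(0L, c(11, 5)); edge6[1:6, ] <- 1L
  F5 <- label_image(g, edge5)
  idU <- deformation_map(displacement_field(g, 0))

  # already matched: zero velocity
  v0 <- demons_velocity(F5, F5, idU, alpha = 1)
  expect_equal(max(abs(v0$values)), 0)

  # constant image: gradient guard forces zero
  const <- structure(array(0.5, c(11, 5)), grid = g)
  vc <- demons_velocity(const, structure(array(1, c(11, 5)), grid = g), idU, 1)
  expect_equal(max(abs(vc$values)), 0)

  # 1D step edge against its shifted copy: hand evaluation at one voxel
  Fs <- lgrbsn:::soften_mask(F5, 1)
  Ms <- lgrbsn:::soften_mask(label_image(g, edge6), 1)
  v <- demons_velocity(Fs, Ms, idU, alpha = 1)
  i <- 6; j <- 3
  gradx <- (Fs[i + 1, j] - Fs[i - 1, j]) / 2
  grady <- (Fs[i, j + 1] - Fs[i, j - 1]) / 2
  diffv <- Fs[i, j] - Ms[i, j]
  den <- gradx^2 + grady^2 + diffv^2
  expect_equal(v$values[i, j, 1], diffv * gradx / den, tolerance = 1e-12)
  expect_equal(v$values[i, j, 2], diffv * grady / den, tolerance = 1e-12)
})

test_that("structure-demons sum is linear over disjoint structures", {
  g <- lg_grid(c(12, 12))
  idU <- deformation_map(displacement_field(g, 0))
  a_f <- array(0L, c(12, 12)); a_f[2:4, 2:4] <- 1L
  a_m <- array(0L, c(12, 12)); a_m[3:5, 2:4] <- 1L
  b_f <- array(0L, c(12, 12)); b_f[8:10, 8:10] <- 1L
  b_m <- array(0L, c(12, 12)); b_m[8:10, 9:11] <- 1L
  mk <- function(x) label_image(g, x)

  empty <- demons_velocity_sum(list(), list(), idU, 1)
  expect_equal(max(abs(empty$values)), 0)

  one <- demons_velocity_sum(list(mk(a_f)), list(mk(a_m)), idU, 1)
  expect_equal(one$values, demons_velocity(mk(a_f), mk(a_m), idU, 1)$values)

  both <- demons_velocity_sum(list(mk(a_f), mk(b_f)), list(mk(a_m), mk(b_m)), idU, 1)
  expect_equal(both$values,
               demons_velocity(mk(a_f), mk(a_m), idU, 1)$values +
               demons_velocity(mk(b_f), mk(b_m), idU, 1)$values,
               tolerance = 1e-12)
  expect_error(demons_velocity_sum(list(mk(a_f)), list(), idU, 1), "length")
})

test_that("matched mutual inverses are a fixed point of the update", {
  g <- lg_grid(c(16, 16))
  mask <- array(0L, c(16, 16)); mask[5:12, 5:12] <- 1L
  bundle <- mask_bundle(label_image(g, mask), label_image(g, mask))
  u_sm <- displacement_field(g, 0, "subject", "forward")
  u_ms <- displacement_field(g, 0, "template", "reverse")
  st <- bijectivity_step(u_sm, u_ms, bundle, bijectivity_config())
  expect_equal(max(abs(st$u_sm$values)), 0)
  expect_equal(max(abs(st$u_ms$values)), 0)
})

test_that("residual-only updates contract translations at rate |1-2*beta*w1|", {
  g <- lg_grid(c(12, 12))
  mask <- label_image(g, array(1L, c(12, 12)))
  bundle <- mask_bundle(mask, mask)
  for (beta in c(0.25, 0.5)) {
    cfg <- bijectivity_config(w = c(1, 0, 0), beta = beta)
    u_sm <- displacement_field(g, c(1, 0), "subject", "forward")
    u_ms <- displacement_field(g, 0, "template", "reverse")
    err0 <- max(abs(residual(u_sm, u_ms)$values))
    st <- bijectivity_step(u_sm, u_ms, bundle, cfg)
    err1 <- max(abs(residual(st$u_sm, st$u_ms)$values))
    expect_equal(err1 / err0, abs(1 - 2 * beta), tolerance = 1e-10)
  }
  # the printed one-step example: beta = 1, w1 = 1 zeroes the forward field
  cfg1 <- bijectivity_config(w = c(1, 0, 0), beta = 1)
  st1 <- bijectivity_step(displacement_field(g, c(1, 0), "subject", "forward"),
                          displacement_field(g, 0, "template", "reverse"),
                          bundle, cfg1)
  expect_equal(max(abs(st1$u_sm$values)), 0, tolerance = 1e-12)
})

test_that("bijective matched input exits the loop at iteration 0", {
  g <- lg_grid(c(16, 16))
  mask <- array(0L, c(16, 16)); mask[5:12, 5:12] <- 1L
  bundle <- mask_bundle(label_image(g, mask), label_image(g, mask))
  out <- enforce_bijectivity(displacement_field(g, 0, "subject", "forward"),
                             displacement_field(g, 0, "template", "reverse"),
                             bundle, bijectivity_config())
  expect_identical(max(out$history$iteration), 0L)
  expect_equal(max(abs(out$u_sm$values)), 0)
})

test_that("the loop repairs a genuinely folded field", {
  fx <- folded_field_pair()
  U0 <- deformation_map(fx$u_sm)
  expect_gt(count_nonpositive_jacobian(U0), 0L)
  mask <- array(0L, fx$grid$shape); mask[10:38, 10:38] <- 1L
  bundle <- mask_bundle(label_image(fx$grid, mask), label_image(fx$grid, mask))
  cfg <- bijectivity_config(w = c(0.8, 0.2, 0), max_iter = 150)
  out <- enforce_bijectivity(fx$u_sm, fx$u_ms, bundle, cfg)
  last <- nrow(out$history)
  expect_identical(out$history$nonpositive_fwd[last], 0)
  expect_identical(out$history$nonpositive_rev[last], 0)
  # 5-iteration moving average of the counts is non-increasing
  cnt <- out$history$nonpositive_fwd
  if (length(cnt) >= 6) {
    ma <- stats::filter(cnt, rep(1 / 5, 5), sides = 1)
    ma <- ma[!is.na(ma)]
    expect_true(all(diff(ma) <= 1e-9))
  }
  # residual norms decrease too
  expect_lt(out$history$residual_l2_fwd[last], out$history$residual_l2_fwd[1])
})

test_that("histories serialize to CSV", {
  h <- data.frame(iteration = 0:2, nonpositive_fwd = c(4, 1, 0),
                  nonpositive_rev = c(3, 0, 0),
                  residual_l2_fwd = c(1, 0.5, 0.2),
                  residual_l2_rev = c(1, 0.4, 0.1))
  path <- tempfile(fileext = ".csv")
  write_history_csv(h, path)
  expect_equal(utils::read.csv(path), h)
})
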