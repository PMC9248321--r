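# Shared fixtures and brute-force oracles, all built in code.

# two 5x5 squares one voxel apart on a 20 x 10 grid
two_square_fixture <- function() {
  lab <- array(0L, c(20, 10))
  lab[4:8, 3:7] <- 1L
  lab[10:14, 3:7] <- 2L
  label_image(lg_grid(c(20, 10)), lab)
}

# brute-force binary dilation by a Euclidean ball SE (set arithmetic)
bf_dilate <- function(mask, radius) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  offs <- as.matrix(expand.grid(-radius:radius, -radius:radius))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) for (o in seq_len(nrow(offs))) {
    i <- idx[r, 1] + offs[o, 1]; j <- idx[r, 2] + offs[o, 2]
    if (i >= 1 && i <= dims[1] && j >= 1 && j <= dims[2]) out[i, j] <- TRUE
  }
  out
}

# brute-force Euclidean distance map (mm) to the TRUE set of a 2D mask
bf_distance <- function(mask, spacing = c(1, 1)) {
  dims <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(Inf, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    d2 <- ((i - src[, 1]) * spacing[1])^2 + ((j - src[, 2]) * spacing[2])^2
    out[i, j] <- sqrt(min(d2))
  }
  out
}

# direct voxelwise evaluation of the IDW weight formula from cores +
# distance maps (the 20-line oracle)
bf_idw_weights <- function(cores, dmaps, mu, eps = 1e-9) {
  m <- length(cores)
  dims <- dim(cores[[1]])
  ws <- lapply(seq_len(m), function(i) array(0, dims))
  for (v in seq_len(prod(dims))) {
    core_hits <- vapply(cores, function(cc) cc[v], logical(1))
    if (any(core_hits)) {
      for (i in seq_len(m)) ws[[i]][v] <- as.numeric(core_hits[i])
    } else {
      q <- vapply(dmaps, function(dd) 1 / max(dd[v], eps)^mu, numeric(1))
      for (i in seq_len(m)) ws[[i]][v] <- q[i] / sum(q)
    }
  }
  ws
}

# a smooth forward/reverse field pair with genuine folds in the forward
# field: a strong Gaussian bump squeezes columns onto each other
folded_field_pair <- function(n = 48, amp = 24, width = 4) {
  g <- lg_grid(c(n, n))
  pts <- grid_points(g)
  cx <- (n - 1) / 2
  bump <- -amp * (pts[, 1] - cx) / width^2 *
    exp(-((pts[, 1] - cx)^2 + (pts[, 2] - cx)^2) / (2 * width^2))
  vals <- cbind(bump, 0)
  u_sm <- displacement_field(g, array(vals, c(g$shape, 2)),
                             "subject", "forward")
  u_ms <- displacement_field(g, 0, "template", "reverse")
  list(u_sm = u_sm, u_ms = u_ms, grid = g)
}

# small phantom used where the full 128 x 128 run would be wasteful
small_phantom <- function(misaligned = FALSE) {
  gyrus_phantom(shape = c(64, 64), depth_moving = 20, depth_fixed = 23,
                span_moving = 40, span_fixed = 36, base_y = 12,
                misaligned = misaligned, offset_px = 8)
}

expect_fields_equal <- function(a, b, tol = 1e-12) {
  expect_true(grids_equal_for_test(a$grid, b$grid))
  expect_lt(max(abs(a$values - b$values)), tol)
}

grids_equal_for_test <- function(ga, gb) {
  identical(ga$shape, gb$shape) &&
    max(abs(ga$spacing - gb$spacing)) < 1e-12 &&
    max(abs(ga$origin - gb$origin)) < 1e-12
}
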