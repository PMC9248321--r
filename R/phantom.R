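# 2D folded-gyrus phantom: a cosine-arch ribbon of fixed width carrying
# three labeled sub-regions, with arc-length-matched boundary landmarks on
# both sides of the ribbon. Used for desk-scale validation of the whole
# normalization pipeline.

# dense centerline of a cosine-arch (sin^2 bump) ribbon
arch_centerline <- function(x0, span, y0, depth, n = 2048L) {
  u <- seq(0, 1, length.out = n)
  x <- x0 + u * span
  y <- y0 + depth * sin(pi * u)^2
  dx <- rep(span, n)
  dy <- depth * pi * sin(2 * pi * u)
  nrm <- sqrt(dx^2 + dy^2)
  seglen <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seglen))
  list(u = u, x = x, y = y,
       nx = -dy / nrm, ny = dx / nrm,   # unit normal (left of travel)
       cum = cum, total = cum[n])
}

# sample one side curve of one region at fixed arc-length fractions
sample_side <- function(cl, side_sign, half_width, u_lo, u_hi, fractions) {
  sel <- which(cl$u >= u_lo - 1e-12 & cl$u <= u_hi + 1e-12)
  px <- cl$x[sel] + side_sign * half_width * cl$nx[sel]
  py <- cl$y[sel] + side_sign * half_width * cl$ny[sel]
  cum <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  total <- cum[length(cum)]
  tx <- stats::approx(cum, px, xout = fractions * total, rule = 2)$y
  ty <- stats::approx(cum, py, xout = fractions * total, rule = 2)$y
  cbind(tx, ty)
}

# rasterize the ribbon: label = region of the nearest centerline sample if
# within half_width of the centerline polyline
rasterize_ribbon <- function(cl, region_of_u, grid, half_width,
                             chunk = 4096L) {
  pts <- grid_points(grid)
  n <- nrow(pts)
  lab <- integer(n)
  cxy <- cbind(cl$x, cl$y)
  c2 <- rowSums(cxy^2)
  for (b in seq(1, n, by = chunk)) {
    ix <- b:min(b + chunk - 1, n)
    p <- pts[ix, , drop = FALSE]
    d2 <- outer(rowSums(p^2), c2, "+") - 2 * tcrossprod(p, cxy)
    best <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_along(ix), best)]
    inside <- dmin <= half_width^2 + 1e-9
    lab[ix][inside] <- region_of_u[best[inside]]
  }
  label_image(grid, array(lab, grid$shape))
}

#' Generate the 2D folded-gyrus phantom
#'
#' Builds moving and fixed label images of a ribbon (default width 4 px,
#' emulating a 4 mm cortical ribbon) traced along a cosine-arch
#' centerline, split into three sub-regions by arc-length fractions, with
#' landmarks sampled at a fixed arc-length spacing on both sides of the
#' ribbon in every region. Moving and fixed landmarks are paired by
#' arc-length position, so the correspondence carries no positional
#' shortcut. The fixed variant uses a different fold depth and span;
#' `misaligned = TRUE` additionally translates the whole moving ribbon so
#' the folds no longer overlap.
#'
#' @param shape grid extents (default `c(128, 128)`, 1 mm spacing).
#' @param width_px ribbon width in px (default 4).
#' @param region_fracs arc-length fractions of the three regions
#'   (default `c(0.3, 0.4, 0.3)`).
#' @param depth_moving,depth_fixed fold depths in px (defaults 46 / 50:
#'   similar but clearly distinct folds).
#' @param span_moving,span_fixed fold spans in px (defaults 80 / 76).
#' @param base_y ribbon base height (default 28).
#' @param misaligned translate the moving ribbon by `offset_px`?
#' @param offset_px misalignment translation along x (default 12).
#' @param landmark_spacing boundary arc-length spacing between landmarks
#'   in px (default 2).
#' @param seed stored with the parameters; the construction itself is
#'   deterministic.
#' @return An object of class `lg_phantom`: `moving`, `fixed`
#'   ([label_image()]s), `moving_landmarks`, `fixed_landmarks` (lists of
#'   per-region point matrices with matching rows), `params`.
#' @export
gyrus_phantom <- function(shape = c(128, 128), width_px = 4,
                          region_fracs = c(0.3, 0.4, 0.3),
                          depth_moving = 46, depth_fixed = 50,
                          span_moving = 80, span_fixed = 76,
                          base_y = 28,
                          misaligned = FALSE, offset_px = 12,
                          landmark_spacing = 2, seed = 1L) {
  stopifnot(length(region_fracs) == 3, abs(sum(region_fracs) - 1) < 1e-9,
            width_px > 0, landmark_spacing > 0)
  grid <- lg_grid(shape)
  half <- width_px / 2
  off <- if (misaligned) offset_px else 0
  x0_m <- (shape[1] - 1 - span_moving) / 2 + off
  x0_f <- (shape[1] - 1 - span_fixed) / 2
  cl_m <- arch_centerline(x0_m, span_moving, base_y, depth_moving)
  cl_f <- arch_centerline(x0_f, span_fixed, base_y, depth_fixed)
  for (cl in list(cl_m, cl_f)) {
    lo <- c(min(cl$x), min(cl$y)) - half
    hi <- c(max(cl$x), max(cl$y)) + half
    if (any(lo < 0) || any(hi > (shape - 1)))
      stop("ribbon leaves the grid; enlarge the grid or shrink the fold")
  }
  cuts <- cumsum(region_fracs)[1:2]
  region_of <- function(cl) {
    fr <- cl$cum / cl$total
    1L + (fr > cuts[1]) + (fr > cuts[2])
  }
  reg_m <- region_of(cl_m)
  reg_f <- region_of(cl_f)
  moving <- rasterize_ribbon(cl_m, reg_m, grid, half)
  fixed <- rasterize_ribbon(cl_f, reg_f, grid, half)
  # u-interval of each region (by centerline arc fraction)
  u_bounds <- function(cl) {
    fr <- cl$cum / cl$total
    vapply(c(0, cuts, 1), function(f) cl$u[which.min(abs(fr - f))],
           numeric(1))
  }
  ub_m <- u_bounds(cl_m)
  ub_f <- u_bounds(cl_f)
  side_off <- half - 0.5       # landmark curves sit on boundary pixels
  lm_m <- lm_f <- vector("list", 3)
  for (r in 1:3) {
    pm <- pf <- NULL
    sides <- integer(0)
    for (s in c(1, -1)) {
      # count set by the fixed geometry's side length
      sel <- which(cl_f$u >= ub_f[r] & cl_f$u <= ub_f[r + 1])
      px <- cl_f$x[sel] + s * side_off * cl_f$nx[sel]
      py <- cl_f$y[sel] + s * side_off * cl_f$ny[sel]
      len <- sum(sqrt(diff(px)^2 + diff(py)^2))
      n_lm <- max(2L, floor(len / landmark_spacing))
      fracs <- (seq_len(n_lm) - 0.5) / n_lm
      pf <- rbind(pf, sample_side(cl_f, s, side_off, ub_f[r], ub_f[r + 1], fracs))
      pm <- rbind(pm, sample_side(cl_m, s, side_off, ub_m[r], ub_m[r + 1], fracs))
      sides <- c(sides, rep.int(s, n_lm))
    }
    colnames(pm) <- colnames(pf) <- c("x", "y")
    attr(pm, "side") <- attr(pf, "side") <- sides
    lm_m[[r]] <- pm
    lm_f[[r]] <- pf
  }
  structure(list(moving = moving, fixed = fixed,
                 moving_landmarks = lm_m, fixed_landmarks = lm_f,
                 params = list(shape = shape, width_px = width_px,
                               region_fracs = region_fracs,
                               depth_moving = depth_moving,
                               depth_fixed = depth_fixed,
                               span_moving = span_moving,
                               span_fixed = span_fixed, base_y = base_y,
                               misaligned = misaligned, offset_px = offset_px,
                               landmark_spacing = landmark_spacing,
                               seed = seed)),
            class = "lg_phantom")
}

#' @export
print.lg_phantom <- function(x, ...) {
  nlm <- sum(vapply(x$moving_landmarks, nrow, numeric(1)))
  cat("<lg_phantom> ", paste(x$params$shape, collapse = " x "),
      " grid, ribbon width ", x$params$width_px, " px, ",
      if (x$params$misaligned) "misaligned" else "aligned",
      " initial position; ", nlm, " landmark pairs over 3 regions\n",
      "  whole-mask Dice before registration: ",
      format(dice(x$moving, x$fixed), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Smooth fold-free random deformation
#'
#' Band-limited random displacement field (Gaussian-filtered white noise)
#' rescaled to a maximum displacement of `amplitude` and guaranteed
#' topology-preserving by construction: generation fails if the maximum
#' row sum of the displacement Jacobian reaches 1 (a sufficient condition
#' for a positive determinant everywhere).
#'
#' @param grid an [lg_grid()].
#' @param amplitude maximum displacement magnitude in mm (default 2).
#' @param smoothness Gaussian smoothing sigma in voxels (default 8).
#' @param seed RNG seed (the field is reproducible from it).
#' @return An [displacement_field()] with zero non-positive-Jacobian
#'   voxels.
#' @export
make_known_deformation <- function(grid, amplitude = 2, smoothness = 8,
                                   seed = 1L) {
  stopifnot(inherits(grid, "lg_grid"), amplitude >= 0, smoothness > 0)
  d <- grid$ndim
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  vals <- array(0, c(grid$shape, d))
  if (amplitude > 0) {
    comps <- lapply(seq_len(d), function(k)
      gaussian_smooth(array(stats::rnorm(prod(grid$shape)), grid$shape),
                      smoothness))
    mx <- sqrt(Reduce(`+`, lapply(comps, function(a) a^2)))
    scale <- amplitude / max(mx)
    for (k in seq_len(d)) {
      if (d == 2L) vals[, , k] <- comps[[k]] * scale
      else vals[, , , k] <- comps[[k]] * scale
    }
  }
  u <- displacement_field(grid, vals)
  rowsum_max <- 0
  for (i in seq_len(d)) {
    s <- array(0, grid$shape)
    for (j in seq_len(d))
      s <- s + abs(array_gradient_axis(field_component(u, i), j,
                                       grid$spacing[j]))
    rowsum_max <- max(rowsum_max, max(s))
  }
  if (rowsum_max >= 1)
    stop("deformation too steep to stay fold-free (max |du/dx| row sum = ",
         format(rowsum_max, digits = 3),
         "); reduce amplitude or increase smoothness")
  u
}

#' Replace a phantom's moving side with a known deformation of its fixed side
#'
#' Ground-truth fixture for recovery tests: the moving image becomes
#' `fixed(x + g(x))` and every moving landmark is the preimage of its
#' fixed counterpart under `x + g(x)` (solved by fixed-point iteration),
#' so the true forward subject-to-template field is exactly `g`.
#'
#' @param phantom an [gyrus_phantom()].
#' @param defo an [make_known_deformation()] field on the phantom grid.
#' @return A new `lg_phantom` whose `params$true_forward` stores `g`.
#' @export
deform_phantom <- function(phantom, defo) {
  stopifnot(inherits(phantom, "lg_phantom"), inherits(defo, "lg_field"))
  moving <- warp_image(phantom$fixed, defo, order = "nearest")
  lm_m <- lapply(phantom$fixed_landmarks, function(y) {
    x <- y
    for (i in 1:50) {
      x_new <- y - interp_field_at(defo, x, oob = "clamp")
      if (max(abs(x_new - x)) < 1e-10) { x <- x_new; break }
      x <- x_new
    }
    colnames(x) <- colnames(y)
    x
  })
  out <- phantom
  out$moving <- moving
  out$moving_landmarks <- lm_m
  out$params$true_forward <- defo
  out
}
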