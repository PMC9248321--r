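# Residual-compensation enforcement of bijectivity on a forward/reverse
# displacement-field pair, with demons velocities keeping the cortex mask
# and sub-cortical structures matched while the pair is regularized.

#' Configuration of the bijectivity loop
#'
#' @param w length-3 non-negative mixing weights for (residual, cortex-mask
#'   demons, structure demons); normalized to sum to one on
#'   construction. Default `c(0.4, 0.3, 0.3)`.
#' @param beta residual step scale (> 0, default 0.5).
#' @param alpha demons stabilizer (> 0, default 1).
#' @param sigma_cc Gaussian smoothing sigma (mm) applied to the
#'   cortex-mask demons velocity (default 1.5).
#' @param sigma_sub sigma (mm) for the per-structure demons velocity
#'   (default 1.5).
#' @param mask_presmooth sigma in voxels used to soften binary masks
#'   before demons gradients (default 0.7).
#' @param max_iter iteration budget (default 200).
#' @param target_nonpositive non-positive-Jacobian count both directions
#'   must reach (default 0); the loop stops once the count target is met
#'   *and* the pending update has converged (see
#'   [enforce_bijectivity()]).
#' @param update_tol maximal pending update (mm) below which the loop is
#'   considered converged (default 1e-4).
#' @return An object of class `lg_bijectivity_config`.
#' @export
bijectivity_config <- function(w = c(0.4, 0.3, 0.3), beta = 0.5, alpha = 1,
                               sigma_cc = 1.5, sigma_sub = 1.5,
                               mask_presmooth = 0.7,
                               max_iter = 200L, target_nonpositive = 0L,
                               update_tol = 1e-4) {
  stopifnot(length(w) == 3, all(w >= 0), sum(w) > 0, beta > 0, alpha > 0,
            sigma_cc > 0, sigma_sub > 0, max_iter >= 0,
            target_nonpositive >= 0, update_tol >= 0)
  structure(list(w = w / sum(w), beta = beta, alpha = alpha,
                 sigma_cc = sigma_cc, sigma_sub = sigma_sub,
                 mask_presmooth = mask_presmooth,
                 max_iter = as.integer(max_iter),
                 target_nonpositive = as.integer(target_nonpositive),
                 update_tol = update_tol),
            class = "lg_bijectivity_config")
}

#' Mask bundle for the bijectivity loop
#'
#' @param cc_subject,cc_template binary cortex masks ([label_image()]) on
#'   the subject and template grids.
#' @param subcortical_subject,subcortical_template aligned lists of binary
#'   masks for sub-cortical structures (may be empty).
#' @return An object of class `lg_mask_bundle`.
#' @export
mask_bundle <- function(cc_subject, cc_template,
                        subcortical_subject = list(),
                        subcortical_template = list()) {
  stopifnot(inherits(cc_subject, "lg_label"), inherits(cc_template, "lg_label"))
  if (length(subcortical_subject) != length(subcortical_template))
    stop("sub-cortical mask lists must have equal length")
  for (m in subcortical_subject)
    if (!grids_equal(m$grid, cc_subject$grid))
      stop("all subject masks must share the subject grid")
  for (m in subcortical_template)
    if (!grids_equal(m$grid, cc_template$grid))
      stop("all template masks must share the template grid")
  structure(list(cc_subject = cc_subject, cc_template = cc_template,
                 subcortical_subject = subcortical_subject,
                 subcortical_template = subcortical_template),
            class = "lg_mask_bundle")
}

# separable Gaussian smoothing of an array; sigma in voxels per axis
gaussian_smooth <- function(arr, sigma_vox) {
  dims <- dim(arr)
  nd <- length(dims)
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, nd)
  for (axis in seq_len(nd)) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- exp(-(-r:r)^2 / (2 * s^2))
    kern <- kern / sum(kern)
    arr <- apply_along_axis(arr, axis, function(line) {
      n <- length(line)
      padded <- c(rep(line[1], r), line, rep(line[n], r))
      as.numeric(stats::filter(padded, kern, sides = 2))[(r + 1):(r + n)]
    })
  }
  arr
}

# smoothed [0,1] image of a binary mask, for meaningful demons gradients
soften_mask <- function(mask, sigma_vox = 1) {
  arr <- gaussian_smooth(array(as.numeric(mask$labels > 0L), mask$grid$shape),
                         sigma_vox)
  structure(arr, grid = mask$grid)
}

#' Inverse-consistency residual of a field pair
#'
#' `r(x) = u_ab(x) + u_ba(x + u_ab(x))`: zero exactly when the two maps
#' are mutual inverses at grid resolution.
#'
#' @param u_ab,u_ba displacement fields of opposite direction on
#'   compatible grids.
#' @return An [displacement_field()] on `u_ab`'s grid.
#' @export
residual <- function(u_ab, u_ba) {
  stopifnot(inherits(u_ab, "lg_field"), inherits(u_ba, "lg_field"))
  if (u_ab$direction == u_ba$direction)
    stop("residual needs one forward and one reverse field")
  comp <- compose_field_with_map(u_ba, deformation_map(u_ab))
  displacement_field(u_ab$grid, u_ab$values + comp$values,
                     domain = u_ab$domain, direction = u_ab$direction)
}

#' Demons velocity matching two mask images
#'
#' `v(x) = (F(x) - M(U(x))) grad F(x) / (||grad F(x)||^2 +
#' alpha (F(x) - M(U(x)))^2)`, with `v = 0` wherever the denominator
#' falls below `1e-12`. `F` and `M` should be pre-smoothed continuous
#' `[0, 1]` images (see [mask_bundle()] handling in
#' [enforce_bijectivity()]); gradients are spacing-aware central
#' differences.
#'
#' @param mask_fixed,mask_moving smoothed mask arrays with a `grid`
#'   attribute (or [label_image()]s, softened internally).
#' @param U an [deformation_map()] on the fixed grid.
#' @param alpha stabilizer (> 0).
#' @return An [displacement_field()] on the fixed grid.
#' @export
demons_velocity <- function(mask_fixed, mask_moving, U, alpha = 1) {
  stopifnot(alpha > 0, inherits(U, "lg_map"))
  if (inherits(mask_fixed, "lg_label")) mask_fixed <- soften_mask(mask_fixed)
  if (inherits(mask_moving, "lg_label")) mask_moving <- soften_mask(mask_moving)
  gf <- attr(mask_fixed, "grid")
  gm <- attr(mask_moving, "grid")
  stopifnot(!is.null(gf), !is.null(gm))
  grid <- U$field$grid
  d <- grid$ndim
  pts <- map_points(U)
  mw <- array(interp_array(unclass(mask_moving), gm, pts,
                           mode = "linear", oob = "zero"), grid$shape)
  F_ <- unclass(mask_fixed)
  diffim <- F_ - mw
  grads <- lapply(seq_len(d), function(k)
    array_gradient_axis(F_, k, gf$spacing[k]))
  gnorm2 <- Reduce(`+`, lapply(grads, function(g) g^2))
  den <- gnorm2 + alpha * diffim^2
  vals <- array(0, dim = c(grid$shape, d))
  sel <- den >= 1e-12
  for (k in seq_len(d)) {
    vk <- array(0, grid$shape)
    vk[sel] <- diffim[sel] * grads[[k]][sel] / den[sel]
    if (d == 2L) vals[, , k] <- vk else vals[, , , k] <- vk
  }
  displacement_field(grid, vals, domain = U$field$domain,
                     direction = U$field$direction)
}

#' Summed demons velocity over a list of structures
#'
#' @param masks_fixed,masks_moving equal-length lists of masks.
#' @param U an [deformation_map()].
#' @param alpha stabilizer.
#' @return An [displacement_field()] (zero field for empty lists).
#' @export
demons_velocity_sum <- function(masks_fixed, masks_moving, U, alpha = 1) {
  if (length(masks_fixed) != length(masks_moving))
    stop("mask lists must have equal length")
  grid <- U$field$grid
  out <- displacement_field(grid, 0, domain = U$field$domain,
                            direction = U$field$direction)
  for (i in seq_along(masks_fixed)) {
    v <- demons_velocity(masks_fixed[[i]], masks_moving[[i]], U, alpha)
    out$values <- out$values + v$values
  }
  out
}

smooth_field <- function(u, sigma_mm) {
  sig_vox <- sigma_mm / u$grid$spacing
  d <- u$grid$ndim
  vals <- u$values
  for (k in seq_len(d)) {
    comp <- gaussian_smooth(field_component(u, k), sig_vox)
    if (d == 2L) vals[, , k] <- comp else vals[, , , k] <- comp
  }
  displacement_field(u$grid, vals, domain = u$domain, direction = u$direction)
}

# pre-soften every mask in the bundle once
soften_bundle <- function(bundle, sigma_vox) {
  list(cc_s = soften_mask(bundle$cc_subject, sigma_vox),
       cc_t = soften_mask(bundle$cc_template, sigma_vox),
       sub_s = lapply(bundle$subcortical_subject, soften_mask, sigma_vox),
       sub_t = lapply(bundle$subcortical_template, soften_mask, sigma_vox))
}

#' One residual-compensation / demons update of a field pair
#'
#' Updates `u_sm` by subtracting the weighted residual and adding the
#' Gaussian-smoothed demons velocities that keep the cortex mask and
#' sub-cortical structures matched, and symmetrically for `u_ms`:
#' `u_sm <- u_sm - w1 beta r_sm + w2 G_sigma * v_cc + w3 G_sigma' * v_sub`.
#' The residual term is applied unsmoothed; only the demons terms are
#' convolved. (The demons terms enter with the corrective sign, the
#' direction that reduces the mask mismatch.)
#'
#' @param u_sm,u_ms forward (subject-domain) and reverse (template-domain)
#'   fields.
#' @param bundle an [mask_bundle()] (or a pre-softened bundle).
#' @param cfg an [bijectivity_config()].
#' @return List with updated `u_sm` and `u_ms`.
#' @export
bijectivity_step <- function(u_sm, u_ms, bundle, cfg = bijectivity_config()) {
  d <- bijectivity_delta(u_sm, u_ms, bundle, cfg)
  list(u_sm = displacement_field(u_sm$grid, u_sm$values + d$d_sm,
                                 u_sm$domain, u_sm$direction),
       u_ms = displacement_field(u_ms$grid, u_ms$values + d$d_ms,
                                 u_ms$domain, u_ms$direction))
}

# the pending increments of one bijectivity_step, without applying them
bijectivity_delta <- function(u_sm, u_ms, bundle, cfg) {
  soft <- if (inherits(bundle, "lg_mask_bundle"))
    soften_bundle(bundle, cfg$mask_presmooth) else bundle
  w <- cfg$w
  r_sm <- residual(u_sm, u_ms)
  r_ms <- residual(u_ms, u_sm)
  d_sm <- -w[1] * cfg$beta * r_sm$values
  d_ms <- -w[1] * cfg$beta * r_ms$values
  U_sm <- deformation_map(u_sm)
  U_ms <- deformation_map(u_ms)
  if (w[2] > 0) {
    v_sm_cc <- demons_velocity(soft$cc_s, soft$cc_t, U_sm, cfg$alpha)
    v_ms_cc <- demons_velocity(soft$cc_t, soft$cc_s, U_ms, cfg$alpha)
    d_sm <- d_sm + w[2] * smooth_field(v_sm_cc, cfg$sigma_cc)$values
    d_ms <- d_ms + w[2] * smooth_field(v_ms_cc, cfg$sigma_cc)$values
  }
  if (w[3] > 0 && length(soft$sub_s) > 0) {
    v_sm_sub <- demons_velocity_sum(soft$sub_s, soft$sub_t, U_sm, cfg$alpha)
    v_ms_sub <- demons_velocity_sum(soft$sub_t, soft$sub_s, U_ms, cfg$alpha)
    d_sm <- d_sm + w[3] * smooth_field(v_sm_sub, cfg$sigma_sub)$values
    d_ms <- d_ms + w[3] * smooth_field(v_ms_sub, cfg$sigma_sub)$values
  }
  list(d_sm = d_sm, d_ms = d_ms,
       max_update = max(abs(d_sm), abs(d_ms)))
}

#' Iterate the bijectivity loop until the warp is topology-preserving
#'
#' Repeats [bijectivity_step()] recording, per iteration, the
#' non-positive-Jacobian counts of both directions and the residual L2
#' norms. The loop stops once both counts are at
#' `cfg$target_nonpositive` *and* the pending update has converged
#' (maximal increment below `cfg$update_tol`, so mask matching has also
#' settled), or when `cfg$max_iter` is exhausted. A field pair that is
#' already bijective with matched masks is returned unchanged at
#' iteration 0.
#'
#' @inheritParams bijectivity_step
#' @return List with `u_sm`, `u_ms` and `history` (data.frame with columns
#'   `iteration`, `nonpositive_fwd`, `nonpositive_rev`, `residual_l2_fwd`,
#'   `residual_l2_rev`).
#' @export
enforce_bijectivity <- function(u_sm, u_ms, bundle,
                                cfg = bijectivity_config()) {
  soft <- soften_bundle(bundle, cfg$mask_presmooth)
  measure <- function(a, b) {
    c(count_nonpositive_jacobian(deformation_map(a)),
      count_nonpositive_jacobian(deformation_map(b)),
      sqrt(mean(field_norms(residual(a, b))^2)),
      sqrt(mean(field_norms(residual(b, a))^2)))
  }
  hist <- matrix(NA_real_, cfg$max_iter + 1, 4)
  m <- measure(u_sm, u_ms)
  hist[1, ] <- m
  it <- 0L
  while (it < cfg$max_iter) {
    d <- bijectivity_delta(u_sm, u_ms, soft, cfg)
    if (m[1] <= cfg$target_nonpositive && m[2] <= cfg$target_nonpositive &&
        d$max_update < cfg$update_tol) break
    it <- it + 1L
    if (!is.finite(d$max_update))
      stop("bijectivity loop produced non-finite fields at iteration ", it)
    u_sm <- displacement_field(u_sm$grid, u_sm$values + d$d_sm,
                               u_sm$domain, u_sm$direction)
    u_ms <- displacement_field(u_ms$grid, u_ms$values + d$d_ms,
                               u_ms$domain, u_ms$direction)
    m <- measure(u_sm, u_ms)
    hist[it + 1, ] <- m
  }
  history <- data.frame(iteration = 0:it,
                        nonpositive_fwd = hist[1:(it + 1), 1],
                        nonpositive_rev = hist[1:(it + 1), 2],
                        residual_l2_fwd = hist[1:(it + 1), 3],
                        residual_l2_rev = hist[1:(it + 1), 4])
  list(u_sm = u_sm, u_ms = u_ms, history = history)
}

#' Write a bijectivity history as CSV
#'
#' @param history the `history` data.frame from [enforce_bijectivity()].
#' @param path output file.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
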