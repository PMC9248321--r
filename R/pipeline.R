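#' Pipeline configuration
#'
#' Collects every tunable of the normalization pipeline. Defaults are the
#' package's reference settings for the 2D phantom; 3D work typically
#' only changes `sigma` (kernel width, mm).
#'
#' @param sigma Gaussian kernel width of the shooting velocity field
#'   (default 5; mm == px on the phantom grid).
#' @param steps RK4 integration steps (default 20).
#' @param max_iter momentum-optimizer iteration budget (default 200).
#' @param step_size initial line-search step (default 1; `"gd"` only).
#' @param tol relative objective-decrease stopping tolerance (default 1e-6).
#' @param optimizer `"lbfgs"` (default) or `"gd"` (see
#'   [optimize_momentum()]).
#' @param covariance landmark matching covariance in mm^2 (default 0.01,
#'   i.e. a 0.1 mm soft-correspondence scale).
#' @param max_landmarks per-region landmark cap (default 2000).
#' @param se_radius structuring-element radius in voxels for region cores
#'   (default 2).
#' @param mu IDW exponent (default 4).
#' @param epsilon IDW distance floor in mm (default 1e-9).
#' @param bijectivity an [bijectivity_config()].
#' @param demons_structures `"regions"` (default) feeds every region's
#'   binary mask through the structure-demons term of the bijectivity
#'   loop (the phantom analogue of matching sub-cortical structures);
#'   `"none"` uses only the whole-mask term.
#' @param label_warp `"linear"` (default) or `"nearest"`: label
#'   resampling used for the warped output and the Dice metrics (see
#'   [warp_labels()]).
#' @param translation_from `"mask"` (region-mask centroids, default) or
#'   `"landmarks"` for the per-region translation fit.
#' @param affine optional externally supplied global [affine_transform()];
#'   when `NULL` it is fitted by least squares over all landmark pairs.
#' @param seed stored seed for any stochastic input generation.
#' @return An object of class `lgrbsn_config`.
#' @export
lgrbsn_config <- function(sigma = 5, steps = 20L, max_iter = 200L,
                          step_size = 1, tol = 1e-6, optimizer = "lbfgs",
                          covariance = 0.01, max_landmarks = 2000L,
                          se_radius = 2L, mu = 4, epsilon = 1e-9,
                          bijectivity = bijectivity_config(),
                          demons_structures = c("regions", "none"),
                          label_warp = c("linear", "nearest"),
                          translation_from = c("mask", "landmarks"),
                          affine = NULL, seed = 1L) {
  stopifnot(sigma > 0, steps >= 1, max_iter >= 1, covariance > 0,
            se_radius >= 0, mu > 1)
  structure(list(sigma = sigma, steps = as.integer(steps),
                 max_iter = as.integer(max_iter), step_size = step_size,
                 tol = tol, optimizer = optimizer, covariance = covariance,
                 max_landmarks = as.integer(max_landmarks),
                 se_radius = as.integer(se_radius), mu = mu,
                 epsilon = epsilon, bijectivity = bijectivity,
                 demons_structures = match.arg(demons_structures),
                 label_warp = match.arg(label_warp),
                 translation_from = match.arg(translation_from),
                 affine = affine, seed = as.integer(seed)),
            class = "lgrbsn_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg an [lgrbsn_config()].
#' @param path file path.
#' @return `read_config_yaml` returns an `lgrbsn_config`.
#' @export
write_config_yaml <- function(cfg, path) {
  x <- unclass(cfg)
  x$bijectivity <- unclass(x$bijectivity)
  x$affine <- if (is.null(cfg$affine)) NULL else
    list(matrix = as.vector(cfg$affine$matrix),
         dim = nrow(cfg$affine$matrix),
         translation = cfg$affine$translation)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  bij <- do.call(bijectivity_config,
                 x$bijectivity[setdiff(names(x$bijectivity), NULL)])
  aff <- if (is.null(x$affine)) NULL else
    affine_transform(matrix(x$affine$matrix, x$affine$dim, x$affine$dim),
                     x$affine$translation)
  args <- x[setdiff(names(x), c("bijectivity", "affine"))]
  do.call(lgrbsn_config, c(args, list(bijectivity = bij, affine = aff)))
}

#' Run the full landmark-guided region-based normalization pipeline
#'
#' End-to-end fit: global affine and per-region translation alignment,
#' per-region landmark geodesic shooting, inverse-distance-weighted
#' composition of the regional warps into global forward/reverse fields,
#' bijectivity enforcement, and evaluation (Dice overlap per region and
#' for the whole mask, non-positive-Jacobian counts in both directions).
#'
#' @param x an [gyrus_phantom()] or any list with elements `moving`,
#'   `fixed` ([label_image()]s with matching region ids) and
#'   `moving_landmarks`, `fixed_landmarks` (lists of per-region point
#'   matrices with matching rows).
#' @param config an [lgrbsn_config()].
#' @return An object of class `lgrbsn`; see [summary.lgrbsn()].
#'   Components include the fitted affines (`affine`, `translations`),
#'   regional warps (`regional`), the composed pre-enforcement fields
#'   (`composed`), the final fields (`u_sm`, `u_ms`), the bijectivity
#'   `history`, the `warped` moving labels on the template grid, and the
#'   `metrics` table.
#' @export
run_lgrbsn <- function(x, config = lgrbsn_config()) {
  stopifnot(inherits(config, "lgrbsn_config"))
  need <- c("moving", "fixed", "moving_landmarks", "fixed_landmarks")
  if (!all(need %in% names(x)))
    stop("input must provide: ", paste(need, collapse = ", "))
  moving <- x$moving; fixed <- x$fixed
  t0 <- proc.time()[["elapsed"]]
  ids <- label_ids(moving)
  if (!identical(ids, label_ids(fixed)))
    stop("moving and fixed label images carry different region sets")
  if (length(x$moving_landmarks) != length(ids))
    stop("need one landmark set per region")
  for (k in seq_along(ids))
    if (nrow(x$moving_landmarks[[k]]) != nrow(x$fixed_landmarks[[k]]))
      stop("stage 'correspondence' failed for region ", ids[k],
           ": moving and fixed landmark counts differ")

  stage <- function(name, region, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for region ", region, ": ",
           conditionMessage(e), call. = FALSE))
  }

  all_m <- do.call(rbind, x$moving_landmarks)
  all_f <- do.call(rbind, x$fixed_landmarks)
  A <- if (is.null(config$affine))
    fit_affine_landmarks(all_m, all_f) else config$affine

  grid_s <- moving$grid
  grid_t <- fixed$grid
  translations <- vector("list", length(ids))
  regional <- vector("list", length(ids))
  matches <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    i <- ids[k]
    lm_m <- x$moving_landmarks[[k]]
    lm_f <- x$fixed_landmarks[[k]]
    A_i <- stage("translation", i, {
      if (config$translation_from == "mask") {
        cm <- colMeans(grid_points(grid_s)[as.vector(moving$labels == i), ,
                                           drop = FALSE])
        cf <- colMeans(grid_points(grid_t)[as.vector(fixed$labels == i), ,
                                           drop = FALSE])
        fit_translation(apply_affine(matrix(cm, 1), A), matrix(cf, 1))
      } else {
        fit_translation(apply_affine(lm_m, A), lm_f)
      }
    })
    translations[[k]] <- A_i
    corr <- stage("correspondence", i, landmark_correspondence(
      apply_affine(apply_affine(lm_m, A), A_i), lm_f, config$covariance))
    reg <- stage("shooting", i, register_region(
      corr, config$sigma, grid_t, grid_t, steps = config$steps,
      max_iter = config$max_iter, step_size = config$step_size,
      tol = config$tol, method = config$optimizer,
      max_landmarks = config$max_landmarks))
    matches[[k]] <- reg$match
    regional[[k]] <- stage("concatenation", i, concatenate_regional(
      A, A_i, reg$forward, reg$reverse, grid_subject = grid_s,
      region_id = i))
  }

  part_s <- compute_cores(moving, config$se_radius)
  part_t <- compute_cores(fixed, config$se_radius)
  w_s <- idw_weights(part_s, config$mu, config$epsilon)
  w_t <- idw_weights(part_t, config$mu, config$epsilon)
  u_sm0 <- compose_global(regional, w_s, "forward")
  u_ms0 <- compose_global(regional, w_t, "reverse")

  sub_s <- sub_t <- list()
  if (config$demons_structures == "regions") {
    sub_s <- lapply(ids, function(i) label_mask(moving, i))
    sub_t <- lapply(ids, function(i) label_mask(fixed, i))
  }
  bundle <- mask_bundle(label_mask(moving, ids), label_mask(fixed, ids),
                        sub_s, sub_t)
  enf <- enforce_bijectivity(u_sm0, u_ms0, bundle, config$bijectivity)

  warped <- warp_labels(moving, enf$u_ms, method = config$label_warp)
  per_region <- vapply(ids, function(i) dice_label(warped, fixed, i),
                       numeric(1))
  metrics <- data.frame(
    region = c(as.character(ids), "whole"),
    dice = c(per_region, dice(warped, fixed)))
  npj_fwd <- count_nonpositive_jacobian(deformation_map(enf$u_sm))
  npj_rev <- count_nonpositive_jacobian(deformation_map(enf$u_ms))

  structure(list(input = x, config = config, affine = A,
                 translations = translations, regional = regional,
                 matches = matches,
                 partitions = list(subject = part_s, template = part_t),
                 composed = list(u_sm = u_sm0, u_ms = u_ms0),
                 u_sm = enf$u_sm, u_ms = enf$u_ms,
                 history = enf$history, warped = warped,
                 metrics = metrics,
                 nonpositive = c(forward = npj_fwd, reverse = npj_rev),
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "lgrbsn")
}

#' @export
print.lgrbsn <- function(x, ...) {
  cat("Landmark-guided region-based spatial normalization fit\n")
  cat("  regions:            ",
      nrow(x$metrics) - 1, "\n", sep = "")
  cat("  whole-mask Dice:    ",
      format(100 * x$metrics$dice[nrow(x$metrics)], digits = 5), " %\n",
      sep = "")
  cat("  mean regional Dice: ",
      format(100 * mean(x$metrics$dice[-nrow(x$metrics)]), digits = 5),
      " %\n", sep = "")
  cat("  non-positive Jacobian voxels (fwd/rev): ",
      x$nonpositive[["forward"]], " / ", x$nonpositive[["reverse"]], "\n",
      sep = "")
  cat("  bijectivity iterations: ", max(x$history$iteration),
      ", elapsed ", format(x$elapsed, digits = 3), " s\n", sep = "")
  invisible(x)
}

#' Summarize a normalization fit
#'
#' @param object an [run_lgrbsn()] result.
#' @param ... unused.
#' @return A list of class `summary.lgrbsn` with the metrics table,
#'   Jacobian counts before/after enforcement, landmark matching errors
#'   and timing.
#' @export
summary.lgrbsn <- function(object, ...) {
  pre_fwd <- count_nonpositive_jacobian(deformation_map(object$composed$u_sm))
  pre_rev <- count_nonpositive_jacobian(deformation_map(object$composed$u_ms))
  match_err <- vapply(object$matches, function(m) mean(m$matching_error),
                      numeric(1))
  out <- list(metrics = object$metrics,
              nonpositive_before = c(forward = pre_fwd, reverse = pre_rev),
              nonpositive_after = object$nonpositive,
              mean_matching_error = match_err,
              iterations = max(object$history$iteration),
              elapsed = object$elapsed)
  class(out) <- "summary.lgrbsn"
  out
}

#' @export
print.summary.lgrbsn <- function(x, ...) {
  cat("Dice overlap (warped moving vs fixed):\n")
  df <- x$metrics
  df$dice <- sprintf("%.2f %%", 100 * df$dice)
  print(df, row.names = FALSE)
  cat("non-positive Jacobian voxels before enforcement (fwd/rev): ",
      x$nonpositive_before[["forward"]], " / ",
      x$nonpositive_before[["reverse"]], "\n", sep = "")
  cat("non-positive Jacobian voxels after enforcement  (fwd/rev): ",
      x$nonpositive_after[["forward"]], " / ",
      x$nonpositive_after[["reverse"]], "\n", sep = "")
  cat("mean per-region Mahalanobis matching error: ",
      paste(format(x$mean_matching_error, digits = 3), collapse = ", "),
      "\n", sep = "")
  cat("bijectivity iterations: ", x$iterations, "; elapsed ",
      format(x$elapsed, digits = 3), " s\n", sep = "")
  invisible(x)
}

#' Apply a fitted normalization to new data
#'
#' @param object an [run_lgrbsn()] fit.
#' @param newdata an image ([label_image()] or gridded array) on the
#'   subject grid, or an `n x d` matrix of subject-space points (mm).
#' @param type `"image"` renders `newdata` on the template grid using the
#'   reverse field; `"points"` maps points forward into template space.
#' @param method label-resampling method for label images (defaults to the
#'   fit's configured `label_warp`); scalar images always use linear
#'   interpolation.
#' @param ... unused.
#' @return Warped image on the template grid, or mapped points.
#' @export
predict.lgrbsn <- function(object, newdata = NULL,
                           type = c("image", "points"),
                           method = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$input$moving
  if (type == "image") {
    if (inherits(newdata, "lg_label")) {
      if (is.null(method)) method <- object$config$label_warp
      warp_labels(newdata, object$u_ms, method = method)
    } else {
      warp_image(newdata, object$u_ms, order = "linear")
    }
  } else {
    newdata + interp_field_at(object$u_sm, as.matrix(newdata), oob = "clamp")
  }
}

#' Inverse-consistency residual of a fit
#'
#' @param object an [run_lgrbsn()] fit.
#' @param direction `"forward"` (subject-domain residual, default) or
#'   `"reverse"`.
#' @param ... unused.
#' @return An [displacement_field()].
#' @export
residuals.lgrbsn <- function(object, direction = c("forward", "reverse"), ...) {
  direction <- match.arg(direction)
  if (direction == "forward") residual(object$u_sm, object$u_ms)
  else residual(object$u_ms, object$u_sm)
}

#' Plot a normalization fit
#'
#' Panels: moving labels, fixed labels, warped moving labels, and the
#' non-positive-Jacobian count along the bijectivity iterations.
#'
#' @param x an [run_lgrbsn()] fit (2D inputs).
#' @param ... unused.
#' @export
plot.lgrbsn <- function(x, ...) {
  if (x$input$moving$grid$ndim != 2L)
    stop("plotting is implemented for 2D fits")
  op <- graphics::par(mfrow = c(2, 2), mar = c(2.5, 2.5, 2, 1))
  on.exit(graphics::par(op))
  cols <- c("white", grDevices::hcl.colors(
    max(x$input$moving$labels), "viridis"))
  show <- function(lab, main)
    graphics::image(lab$labels, col = cols, main = main, axes = FALSE,
                    useRaster = TRUE)
  show(x$input$moving, "moving")
  show(x$input$fixed, "fixed")
  show(x$warped, "warped moving")
  graphics::plot(x$history$iteration, pmax(x$history$nonpositive_fwd, 0.5),
                 log = "y", type = "l", xlab = "iteration",
                 ylab = "non-positive Jacobian voxels",
                 main = "bijectivity enforcement")
  graphics::lines(x$history$iteration,
                  pmax(x$history$nonpositive_rev, 0.5), lty = 2)
  invisible(x)
}
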