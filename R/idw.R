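# Morphological region cores, distance maps, and inverse-distance-weighted
# blending of per-region warps into one global displacement field.

# offsets of a discrete ball structuring element (voxel units)
ball_offsets <- function(radius, ndim) {
  if (radius == 0) return(matrix(0L, 1, ndim))
  r <- as.integer(radius)
  g <- as.matrix(expand.grid(rep(list(-r:r), ndim)))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

# binary dilation by shift-or over the SE offsets
binary_dilate <- function(mask, offsets) {
  dims <- dim(mask)
  nd <- length(dims)
  out <- array(FALSE, dims)
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    src <- dst <- vector("list", nd)
    ok <- TRUE
    for (k in seq_len(nd)) {
      o <- off[k]
      if (o >= 0) {
        if (o >= dims[k]) { ok <- FALSE; break }
        dst[[k]] <- (1 + o):dims[k]
        src[[k]] <- 1:(dims[k] - o)
      } else {
        if (-o >= dims[k]) { ok <- FALSE; break }
        dst[[k]] <- 1:(dims[k] + o)
        src[[k]] <- (1 - o):dims[k]
      }
    }
    if (!ok) next
    sub <- do.call(`[`, c(list(mask), src, list(drop = FALSE)))
    cur <- do.call(`[`, c(list(out), dst, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), dst, list(value = cur | sub)))
  }
  out
}

# exact squared Euclidean distance transform along one line (separable
# lower-envelope-of-parabolas pass, spacing-aware); f must be finite
edt_1d <- function(f, w) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  w2 <- w^2
  for (qi in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[qi] + qi^2 * w2) - (f[vk] + vk^2 * w2)) / (2 * w2 * (qi - vk))
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- qi
    z[k] <- s
    z[k + 1] <- Inf
  }
  k <- 1L
  for (qi in 1:n) {
    while (z[k + 1] < qi) k <- k + 1L
    d[qi] <- (qi - v[k])^2 * w2 + f[v[k]]
  }
  d
}

# Euclidean distance (mm) from every voxel to the TRUE set of `mask`
distance_transform <- function(mask, spacing) {
  dims <- dim(mask)
  nd <- length(dims)
  big <- 4 * sum((dims * spacing)^2) + 1   # dominates any true distance^2
  f <- array(ifelse(mask, 0, big), dims)
  for (axis in seq_len(nd)) {
    f <- apply_along_axis(f, axis, function(line) {
      if (all(line >= big)) return(line)
      edt_1d(line, spacing[axis])
    })
  }
  sqrt(f)
}

# apply a function to every 1D line along `axis` of an array
apply_along_axis <- function(arr, axis, fn) {
  dims <- dim(arr)
  nd <- length(dims)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dims[axis])
  m <- apply(m, 2, fn)
  a <- array(m, dim = dims[perm])
  aperm(a, order(perm))
}

#' Region partition with eroded cores and distance maps
#'
#' For each region `R_i` the morphological transition area with all other
#' regions is removed: the core is
#' `R_i* = R_i - (R_i (+) SE  intersect  U_j (R_j (+) SE))` with a discrete
#' ball structuring element `SE`. Euclidean distance maps `d_i(x)` to each
#' core (in mm) drive the inverse-distance weights.
#'
#' @param labels an [label_image()] with `m >= 1` regions.
#' @param radius SE radius in voxels (default 2).
#' @return An object of class `lg_partition`: `labels`, `region_ids`,
#'   `cores` (list of logical arrays), `distance_maps` (list of numeric
#'   arrays, mm), `structuring_radius`.
#' @export
compute_cores <- function(labels, radius = 2L) {
  stopifnot(inherits(labels, "lg_label"), radius >= 0)
  ids <- label_ids(labels)
  if (length(ids) < 1L) stop("label image has no regions")
  dims <- labels$grid$shape
  offsets <- ball_offsets(radius, labels$grid$ndim)
  masks <- lapply(ids, function(i) labels$labels == i)
  dils <- lapply(masks, binary_dilate, offsets = offsets)
  cores <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    others <- Reduce(`|`, dils[-i], array(FALSE, dims))
    core <- masks[[i]] & !(dils[[i]] & others)
    if (!any(core)) {
      warning("region ", ids[i],
              " has an empty eroded core; falling back to its full mask")
      core <- masks[[i]]
    }
    cores[[i]] <- core
  }
  dmaps <- lapply(cores, distance_transform, spacing = labels$grid$spacing)
  structure(list(labels = labels, region_ids = ids, cores = cores,
                 distance_maps = dmaps,
                 structuring_radius = as.integer(radius)),
            class = "lg_partition")
}

#' @export
print.lg_partition <- function(x, ...) {
  cat("<lg_partition> ", length(x$region_ids), " regions (",
      paste(x$region_ids, collapse = ", "), "), SE radius ",
      x$structuring_radius, " voxels; core sizes: ",
      paste(vapply(x$cores, sum, numeric(1)), collapse = ", "),
      " voxels\n", sep = "")
  invisible(x)
}

#' Inverse-distance weight images
#'
#' Shepard weights over the partition cores: weight 1 on a region's own
#' core, 0 on any other core, and otherwise
#' `q_i / sum_j q_j` with `q_i = 1 / max(d_i, eps)^mu`. The weights sum to
#' one at every voxel; `mu > 1` makes the blended field's first
#' derivative continuous.
#'
#' @param partition an [compute_cores()] result.
#' @param mu IDW exponent (> 1, default 4).
#' @param epsilon distance floor in mm avoiding division by zero
#'   (default 1e-9).
#' @return List of `m` numeric weight arrays.
#' @export
idw_weights <- function(partition, mu = 4, epsilon = 1e-9) {
  stopifnot(inherits(partition, "lg_partition"), mu > 1, epsilon > 0)
  m <- length(partition$region_ids)
  if (m == 1L) {
    return(list(array(1, dim(partition$cores[[1]]))))
  }
  qs <- lapply(partition$distance_maps,
               function(d) 1 / pmax(d, epsilon)^mu)
  total <- Reduce(`+`, qs)
  ws <- lapply(qs, function(q) q / total)
  any_core <- Reduce(`|`, partition$cores)
  for (i in seq_len(m)) {
    w <- ws[[i]]
    w[any_core] <- 0
    w[partition$cores[[i]]] <- 1
    ws[[i]] <- w
  }
  ws
}

#' Blend regional warps into one global displacement field
#'
#' Voxelwise convex combination `u(x) = sum_i w_i(x) T_i(x)` of the
#' regional displacement vectors; inside a region's core the global field
#' equals that region's warp exactly.
#'
#' @param warps list of [concatenate_regional()] results (or raw
#'   displacement fields) all on one common grid for the chosen direction.
#' @param weights list of weight arrays from [idw_weights()] on the same
#'   grid.
#' @param direction `"forward"` (uses each warp's forward field) or
#'   `"reverse"`.
#' @return An [displacement_field()].
#' @export
compose_global <- function(warps, weights, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (length(warps) != length(weights))
    stop("got ", length(warps), " warps but ", length(weights), " weight images")
  fields <- lapply(warps, function(w) {
    if (inherits(w, "lg_regional_warp")) w[[direction]] else w
  })
  grid <- fields[[1]]$grid
  for (f in fields) {
    if (!grids_equal(f$grid, grid))
      stop("all regional warps must share one grid for direction ", direction)
  }
  d <- grid$ndim
  acc <- array(0, dim = c(grid$shape, d))
  for (i in seq_along(fields)) {
    wrep <- array(rep(as.vector(weights[[i]]), d), dim = c(grid$shape, d))
    acc <- acc + wrep * fields[[i]]$values
  }
  displacement_field(grid, acc,
                     domain = fields[[1]]$domain, direction = direction)
}
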