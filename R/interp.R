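# Multilinear / nearest-neighbor sampling of gridded arrays at arbitrary
# physical positions. Two out-of-grid policies are used in the package:
#   "clamp" - positions are clamped to the grid hull (field composition,
#             keeps residuals finite), and
#   "zero"  - samples falling outside contribute 0 / background (image
#             warping).

interp_array <- function(arr, grid, pts, mode = c("linear", "nearest"),
                         oob = c("clamp", "zero")) {
  mode <- match.arg(mode)
  oob <- match.arg(oob)
  d <- grid$ndim
  stopifnot(ncol(pts) == d)
  tidx <- phys_to_index(grid, pts)          # continuous zero-based index
  n <- nrow(pts)
  shp <- grid$shape

  if (mode == "nearest") {
    idx <- round(tidx)
    if (oob == "zero") {
      valid <- rep(TRUE, n)
      for (k in seq_len(d)) valid <- valid & idx[, k] >= 0 & idx[, k] <= shp[k] - 1
    } else {
      for (k in seq_len(d)) idx[, k] <- pmin(pmax(idx[, k], 0), shp[k] - 1)
      valid <- rep(TRUE, n)
    }
    out <- numeric(n)
    if (any(valid)) {
      lin <- idx[valid, 1]
      mult <- 1
      for (k in seq_len(d - 1)) {
        mult <- mult * shp[k]
        lin <- lin + idx[valid, k + 1] * mult
      }
      out[valid] <- arr[lin + 1]
    }
    return(out)
  }

  if (oob == "clamp") {
    for (k in seq_len(d)) tidx[, k] <- pmin(pmax(tidx[, k], 0), shp[k] - 1)
  }
  i0 <- floor(tidx)
  frac <- tidx - i0
  out <- numeric(n)
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  for (ci in seq_len(nrow(corners))) {
    off <- corners[ci, ]
    idx <- sweep(i0, 2, off, "+")
    w <- rep(1, n)
    for (k in seq_len(d)) {
      wk <- if (off[k] == 1) frac[, k] else 1 - frac[, k]
      w <- w * wk
    }
    if (oob == "zero") {
      valid <- rep(TRUE, n)
      for (k in seq_len(d)) valid <- valid & idx[, k] >= 0 & idx[, k] <= shp[k] - 1
    } else {
      for (k in seq_len(d)) idx[, k] <- pmin(pmax(idx[, k], 0), shp[k] - 1)
      valid <- rep(TRUE, n)
    }
    sel <- valid & w > 0
    if (any(sel)) {
      lin <- idx[sel, 1]
      mult <- 1
      for (k in seq_len(d - 1)) {
        mult <- mult * shp[k]
        lin <- lin + idx[sel, k + 1] * mult
      }
      out[sel] <- out[sel] + w[sel] * arr[lin + 1]
    }
  }
  out
}

# sample a displacement field (all components) at physical points -> n x d
interp_field_at <- function(u, pts, oob = "clamp") {
  d <- u$grid$ndim
  out <- matrix(0, nrow(pts), d)
  for (k in seq_len(d))
    out[, k] <- interp_array(field_component(u, k), u$grid, pts,
                             mode = "linear", oob = oob)
  out
}
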