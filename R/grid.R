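#' Regular image grid
#'
#' A grid of voxel centers in physical (mm) coordinates: the voxel with
#' zero-based index `i` along each axis sits at `origin + i * spacing`.
#' Grids with 2 or 3 axes are supported; all displacement fields, label
#' images and deformation maps in the package live on such a grid.
#'
#' @param shape integer extents per axis (length 2 or 3, each >= 2).
#' @param spacing physical voxel size per axis in mm (default 1).
#' @param origin physical coordinate of voxel index 0 per axis (default 0).
#' @return An object of class `lg_grid`.
#' @examples
#' g <- lg_grid(c(64, 64))
#' g$shape
#' @export
lg_grid <- function(shape, spacing = rep(1, length(shape)),
                    origin = rep(0, length(shape))) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (nd < 2L || nd > 3L)
    stop("grid must have 2 or 3 axes, got ", nd)
  if (any(shape < 2L))
    stop("all grid extents must be >= 2")
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  if (length(origin) == 1L) origin <- rep(origin, nd)
  if (length(spacing) != nd || length(origin) != nd)
    stop("spacing/origin dimensionality must equal the number of axes")
  if (any(spacing <= 0))
    stop("all spacings must be > 0")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), ndim = nd),
            class = "lg_grid")
}

#' @export
print.lg_grid <- function(x, ...) {
  cat("<lg_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$ndim == b$ndim && all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

grids_compatible <- function(a, b, tol = 1e-9) {
  # same axes and spacing; extents/origin may differ (subject vs template)
  a$ndim == b$ndim && all(abs(a$spacing - b$spacing) < tol)
}

#' Physical coordinates of every voxel center
#'
#' @param grid an [lg_grid()].
#' @return An `n x d` matrix of voxel-center coordinates in mm, in R array
#'   (column-major, first axis fastest) order.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "lg_grid"))
  idx <- lapply(seq_len(grid$ndim), function(k) seq_len(grid$shape[k]) - 1)
  g <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
  sweep(sweep(g, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

# physical -> continuous zero-based voxel index
phys_to_index <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' Dense displacement field
#'
#' One displacement vector (in mm) per voxel of a grid. The `domain` tag
#' records which space the field is defined on (`subject` or `template`)
#' and `direction` whether it maps toward the other space (`forward`,
#' subject -> template) or back (`reverse`).
#'
#' @param grid an [lg_grid()].
#' @param values numeric array of dim `c(grid$shape, d)` with `d = grid$ndim`
#'   displacement components, or a single vector recycled to every voxel.
#' @param domain `"subject"` or `"template"`.
#' @param direction `"forward"` or `"reverse"`.
#' @return An object of class `lg_field`.
#' @export
displacement_field <- function(grid, values = 0,
                               domain = c("subject", "template"),
                               direction = c("forward", "reverse")) {
  stopifnot(inherits(grid, "lg_grid"))
  domain <- match.arg(domain)
  direction <- match.arg(direction)
  d <- grid$ndim
  full_dim <- c(grid$shape, d)
  if (is.null(dim(values))) {
    if (length(values) == 1L) values <- rep(values, d)
    if (length(values) != d)
      stop("constant displacement must have one component per axis")
    values <- array(rep(values, each = prod(grid$shape)), dim = full_dim)
  }
  if (!identical(as.integer(dim(values)), as.integer(full_dim)))
    stop("values must have dim c(", paste(full_dim, collapse = ", "), ")")
  if (!all(is.finite(values)))
    stop("displacement components must all be finite")
  structure(list(grid = grid, values = values, domain = domain,
                 direction = direction),
            class = "lg_field")
}

#' @export
print.lg_field <- function(x, ...) {
  mx <- field_norms(x)
  cat("<lg_field> ", x$domain, "-domain ", x$direction, " field on ",
      paste(x$grid$shape, collapse = " x "), " grid; max |u| = ",
      format(max(mx), digits = 4), " mm\n", sep = "")
  invisible(x)
}

# per-voxel Euclidean norm of the displacement, as an array on the grid
field_norms <- function(u) {
  d <- u$grid$ndim
  v <- array(0, dim = u$grid$shape)
  for (k in seq_len(d)) v <- v + field_component(u, k)^2
  sqrt(v)
}

# displacement values as an n x d matrix in grid_points order
field_matrix <- function(u) {
  d <- u$grid$ndim
  n <- prod(u$grid$shape)
  matrix(u$values, nrow = n, ncol = d)
}

field_component <- function(u, k) {
  d <- u$grid$ndim
  if (u$grid$ndim == 2L) u$values[, , k] else u$values[, , , k]
}

matrix_to_field_values <- function(grid, m) {
  array(m, dim = c(grid$shape, grid$ndim))
}

#' Deformation map
#'
#' The map `U(x) = x + u(x)` induced by a displacement field, realized
#' lazily: evaluation simply adds the voxel coordinate to the stored
#' displacement.
#'
#' @param field an [displacement_field()].
#' @return An object of class `lg_map`.
#' @export
deformation_map <- function(field) {
  stopifnot(inherits(field, "lg_field"))
  structure(list(field = field), class = "lg_map")
}

#' @export
print.lg_map <- function(x, ...) {
  cat("<lg_map> U(x) = x + u(x) over:\n")
  print(x$field)
  invisible(x)
}

# U evaluated at every grid point, n x d (physical mm)
map_points <- function(U) {
  grid_points(U$field$grid) + field_matrix(U$field)
}

#' Integer label image
#'
#' Non-negative integer labels per voxel; 0 is background.
#'
#' @param grid an [lg_grid()].
#' @param labels integer array of dim `grid$shape` (or vector of matching
#'   length).
#' @return An object of class `lg_label`.
#' @export
label_image <- function(grid, labels) {
  stopifnot(inherits(grid, "lg_grid"))
  if (is.null(dim(labels))) {
    if (length(labels) != prod(grid$shape))
      stop("labels length does not match grid")
    labels <- array(labels, dim = grid$shape)
  }
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("labels must have dim c(", paste(grid$shape, collapse = ", "), ")")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE) || anyNA(labels))
    stop("labels must be non-negative integers")
  structure(list(grid = grid, labels = labels), class = "lg_label")
}

#' @export
print.lg_label <- function(x, ...) {
  tab <- table(x$labels)
  cat("<lg_label> ", paste(x$grid$shape, collapse = " x "), " labels: ",
      paste(names(tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

label_ids <- function(x) sort(setdiff(unique(as.vector(x$labels)), 0L))

# binary mask (lg_label with labels in {0,1}) for one or more label values
label_mask <- function(x, ids) {
  label_image(x$grid, array(as.integer(x$labels %in% ids), dim = x$grid$shape))
}
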