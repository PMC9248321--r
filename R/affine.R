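#' Affine transform
#'
#' `A(x) = M x + t` in physical (mm) coordinates.
#'
#' @param matrix `d x d` linear part (invertible).
#' @param translation length-`d` translation in mm.
#' @return An object of class `lg_affine`.
#' @export
affine_transform <- function(matrix = diag(2), translation = rep(0, nrow(matrix))) {
  matrix <- as.matrix(matrix)
  d <- nrow(matrix)
  stopifnot(ncol(matrix) == d, length(translation) == d)
  if (abs(det(matrix)) <= 1e-12)
    stop("affine linear part is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "lg_affine")
}

#' @export
print.lg_affine <- function(x, ...) {
  cat("<lg_affine> M =\n")
  print(x$matrix)
  cat("t = (", paste(format(x$translation), collapse = ", "), ") mm\n")
  invisible(x)
}

#' Invert an affine transform
#' @param A an [affine_transform()].
#' @return The inverse `lg_affine`.
#' @export
affine_inverse <- function(A) {
  Minv <- solve(A$matrix)
  affine_transform(Minv, -as.numeric(Minv %*% A$translation))
}

#' Compose two affine transforms
#'
#' Returns `outer o inner`, i.e. the transform applying `inner` first.
#' @param outer,inner [affine_transform()] objects of equal dimension.
#' @export
affine_compose <- function(outer, inner) {
  affine_transform(outer$matrix %*% inner$matrix,
                   as.numeric(outer$matrix %*% inner$translation) +
                     outer$translation)
}

#' Least-squares affine fit from corresponding landmarks
#'
#' Minimizes `sum || M x_n + t - y_n ||^2` over all pairs; recovers the
#' exact transform when `fixed` is an affine image of `moving`.
#'
#' @param moving,fixed `n x d` matrices of corresponding points (mm).
#' @return An [affine_transform()] mapping moving to fixed coordinates.
#' @export
fit_affine_landmarks <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  d <- ncol(moving)
  stopifnot(ncol(fixed) == d, nrow(moving) == nrow(fixed))
  if (nrow(moving) < d + 1)
    stop("need at least dim + 1 point pairs for an affine fit")
  X <- cbind(moving, 1)
  qrX <- qr(X)
  if (qrX$rank < d + 1)
    stop("degenerate landmark configuration: affine fit is rank-deficient")
  B <- qr.coef(qrX, fixed)            # (d+1) x d, rows = coefficients
  affine_transform(t(B[seq_len(d), , drop = FALSE]), B[d + 1, ])
}

#' Translation-only fit from points or masks
#'
#' Identity linear part with `t = centroid(fixed) - centroid(moving)`, the
#' per-region initial alignment: region masks are aligned by their
#' centroids without any scaling, which avoids over-fitting before the
#' nonlinear stage.
#'
#' @param moving,fixed point matrices (`n x d`, mm) or [label_image()]
#'   masks (centroid of non-zero voxels, in mm).
#' @return An [affine_transform()].
#' @export
fit_translation <- function(moving, fixed) {
  cen <- function(x) {
    if (inherits(x, "lg_label")) {
      sel <- x$labels > 0L
      if (!any(sel)) stop("empty mask in fit_translation")
      colMeans(grid_points(x$grid)[as.vector(sel), , drop = FALSE])
    } else {
      x <- as.matrix(x)
      if (nrow(x) == 0L) stop("empty point set in fit_translation")
      colMeans(x)
    }
  }
  cm <- cen(moving); cf <- cen(fixed)
  affine_transform(diag(length(cm)), cf - cm)
}

#' Apply an affine transform to points or an image
#'
#' Points are mapped exactly. Images are resampled onto their own grid by
#' [warp_image()] with the induced fixed-to-moving field `A^{-1}(x) - x`,
#' so the image content moves by `A`.
#'
#' @param x `n x d` point matrix, [label_image()], or gridded numeric array.
#' @param A an [affine_transform()].
#' @param order resampling order for images.
#' @return Same kind as `x`.
#' @export
apply_affine <- function(x, A, order = c("nearest", "linear")) {
  stopifnot(inherits(A, "lg_affine"))
  if (is.matrix(x) && !inherits(x, "lg_label")) {
    return(sweep(x %*% t(A$matrix), 2, A$translation, "+"))
  }
  grid <- if (inherits(x, "lg_label")) x$grid else attr(x, "grid")
  if (is.null(grid)) stop("apply_affine on an image needs an lg_label or a grid attribute")
  Ainv <- affine_inverse(A)
  pts <- grid_points(grid)
  disp <- apply_affine(pts, Ainv) - pts
  u <- displacement_field(grid, matrix_to_field_values(grid, disp))
  warp_image(x, u, order = match.arg(order))
}

#' Write / read an affine transform as a plain-text homogeneous matrix
#'
#' `(d+1) x (d+1)` row-major homogeneous matrix in world (mm) coordinates,
#' last row `0 ... 0 1`, whitespace-delimited text -- the common exchange
#' dialect of registration tools.
#'
#' @param A an [affine_transform()].
#' @param path file path.
#' @return `read_affine` returns an [affine_transform()].
#' @export
write_affine <- function(A, path) {
  d <- nrow(A$matrix)
  H <- rbind(cbind(A$matrix, A$translation), c(rep(0, d), 1))
  utils::write.table(format(H, digits = 17), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  H <- unname(as.matrix(utils::read.table(path, header = FALSE)))
  d <- nrow(H) - 1
  affine_transform(H[seq_len(d), seq_len(d), drop = FALSE],
                   H[seq_len(d), d + 1])
}
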