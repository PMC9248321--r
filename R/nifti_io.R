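# NIfTI-1 readers/writers for label images, scalar images and
# displacement fields. Fields are stored as vector-valued volumes with
# the component count in the 5th dimension; voxel sizes carry the grid
# spacing, and units are mm throughout.

grid_from_nifti <- function(img, ndim) {
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- rep(1, ndim)
  lg_grid(dim(img)[seq_len(ndim)], spacing = pd[seq_len(ndim)])
}

#' Read / write a label image as NIfTI
#'
#' @param label an [label_image()].
#' @param path `.nii` or `.nii.gz` file path.
#' @return `read_label_nifti` returns an [label_image()].
#' @export
write_label_nifti <- function(label, path) {
  stopifnot(inherits(label, "lg_label"))
  img <- RNifti::asNifti(structure(label$labels,
                                   pixdim = label$grid$spacing))
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_label_nifti
#' @export
read_label_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  dims <- dim(arr)
  dims <- dims[dims > 1 | seq_along(dims) <= 2]
  arr <- array(as.integer(round(arr)), dims)
  label_image(grid_from_nifti(img, length(dims)), arr)
}

#' Read / write a displacement field as NIfTI
#'
#' The field is written as a 5D volume `x * y * z * 1 * d` (NIfTI vector
#' convention); the `domain`/`direction` tags are carried in the
#' description header field as `"lgrbsn:<domain>:<direction>"` and
#' restored on read (arguments override the header).
#'
#' @param field an [displacement_field()].
#' @param path `.nii` or `.nii.gz` file path.
#' @param domain,direction optional tag overrides on read.
#' @return `read_field_nifti` returns an [displacement_field()].
#' @export
write_field_nifti <- function(field, path) {
  stopifnot(inherits(field, "lg_field"))
  g <- field$grid
  d <- g$ndim
  shp3 <- c(g$shape, rep(1L, 3 - d))
  arr <- array(field$values, dim = c(shp3, 1L, d))
  img <- RNifti::asNifti(structure(arr,
                                   pixdim = c(g$spacing, rep(1, 3 - d))))
  img <- RNifti::asNifti(img, list(
    descrip = paste("lgrbsn", field$domain, field$direction, sep = ":"),
    intent_code = 1007L))   # NIFTI_INTENT_VECTOR
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_field_nifti
#' @export
read_field_nifti <- function(path, domain = NULL, direction = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  dims <- dim(arr)
  d <- dims[length(dims)]
  shape <- dims[seq_len(3)]
  ndim <- if (shape[3] == 1L) 2L else 3L
  stopifnot(d == ndim)
  desc <- RNifti::niftiHeader(img)$descrip
  tags <- strsplit(desc, ":", fixed = TRUE)[[1]]
  if (is.null(domain))
    domain <- if (length(tags) >= 2 && tags[2] %in% c("subject", "template"))
      tags[2] else "subject"
  if (is.null(direction))
    direction <- if (length(tags) >= 3 && tags[3] %in% c("forward", "reverse"))
      tags[3] else "forward"
  grid <- grid_from_nifti(img, ndim)
  vals <- array(arr, dim = c(grid$shape, d))
  displacement_field(grid, vals, domain = domain, direction = direction)
}

#' Read / write a scalar image as NIfTI
#'
#' @param image numeric array with a `grid` attribute ([lg_grid()]).
#' @param path file path.
#' @return `read_scalar_nifti` returns a gridded numeric array.
#' @export
write_scalar_nifti <- function(image, path) {
  g <- attr(image, "grid")
  stopifnot(inherits(g, "lg_grid"))
  arr <- unclass(image)
  attr(arr, "grid") <- NULL
  img <- RNifti::asNifti(structure(arr, pixdim = g$spacing))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_scalar_nifti
#' @export
read_scalar_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  dims <- dim(arr)
  dims <- dims[dims > 1 | seq_along(dims) <= 2]
  arr <- array(as.numeric(arr), dims)
  structure(arr, grid = grid_from_nifti(img, length(dims)))
}

#' Read / write a region-label sidecar JSON
#'
#' Maps integer label values to region names (FreeSurfer aparc+aseg
#' integer conventions are accepted as-is; the JSON is a flat
#' `{"<int>": "<name>"}` object).
#'
#' @param names named character vector (names = label integers).
#' @param path `.json` path.
#' @return `read_label_names` returns a named character vector.
#' @export
write_label_names <- function(names, path) {
  jsonlite::write_json(as.list(names), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_label_names
#' @export
read_label_names <- function(path) {
  unlist(jsonlite::read_json(path))
}

#' Read / write landmark point sets as CSV
#'
#' One point per row; the header names the coordinate columns
#' (`x,y[,z]`).
#'
#' @param points `n x d` matrix.
#' @param path `.csv` path.
#' @return `read_landmarks_csv` returns a point matrix.
#' @export
write_landmarks_csv <- function(points, path) {
  pts <- as.matrix(points)
  colnames(pts) <- c("x", "y", "z")[seq_len(ncol(pts))]
  utils::write.csv(pts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}
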