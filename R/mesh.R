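# Labeled surface meshes and per-region pseudo-landmark extraction:
# vertices of the WM/pial boundary meshes are the landmarks, regions come
# from a per-vertex parcellation, and subject/template matching runs
# through a precomputed spherical correspondence.

#' Labeled triangular surface mesh
#'
#' @param vertices `V x 3` vertex coordinates (mm).
#' @param faces `F x 3` triangles as 1-based vertex indices.
#' @param labels integer region id per vertex (0 = unlabeled).
#' @param sphere optional `V x 3` coordinates on the registration sphere;
#'   rows are normalized to unit length (must already be within 1e-6).
#' @return An object of class `lg_mesh`.
#' @export
surface_mesh <- function(vertices, faces, labels = integer(nrow(vertices)),
                         sphere = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of vertex range")
  labels <- as.integer(labels)
  if (length(labels) != nrow(vertices))
    stop("need one region label per vertex")
  if (!is.null(sphere)) {
    sphere <- as.matrix(sphere)
    stopifnot(nrow(sphere) == nrow(vertices), ncol(sphere) == 3)
    nrm <- sqrt(rowSums(sphere^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("sphere coordinates must have unit norm (within 1e-6)")
    sphere <- sphere / nrm
  }
  structure(list(vertices = vertices, faces = faces, labels = labels,
                 sphere = sphere),
            class = "lg_mesh")
}

#' @export
print.lg_mesh <- function(x, ...) {
  cat("<lg_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, ", length(setdiff(unique(x$labels), 0L)), " labeled regions",
      if (!is.null(x$sphere)) ", with sphere coordinates" else "", "\n",
      sep = "")
  invisible(x)
}

#' Extract a region's vertices as pseudo-landmarks
#'
#' All and only the vertices carrying the region label, in ascending
#' vertex-id order.
#'
#' @param mesh an [surface_mesh()].
#' @param region_id integer label present in the mesh.
#' @param source `"wm"` or `"pial"`, recorded with the landmarks.
#' @return An object of class `lg_region_landmarks` with fields
#'   `region_id`, `points`, `vertex_ids`, `source`.
#' @export
extract_region_landmarks <- function(mesh, region_id, source = c("wm", "pial")) {
  stopifnot(inherits(mesh, "lg_mesh"))
  source <- match.arg(source)
  ids <- which(mesh$labels == region_id)
  if (length(ids) == 0L)
    stop("region ", region_id, " is absent from the mesh labels")
  structure(list(region_id = as.integer(region_id),
                 points = mesh$vertices[ids, , drop = FALSE],
                 vertex_ids = ids, source = source),
            class = "lg_region_landmarks")
}

#' @export
print.lg_region_landmarks <- function(x, ...) {
  cat("<lg_region_landmarks> region ", x$region_id, " (", x$source, "): ",
      length(x$vertex_ids), " vertices\n", sep = "")
  invisible(x)
}

# deterministic farthest-point sampling: start at the lowest vertex id,
# then repeatedly take the point farthest from the selected set
farthest_point_sample <- function(coords, m) {
  n <- nrow(coords)
  if (m >= n) return(seq_len(n))
  sel <- integer(m)
  sel[1] <- 1L
  d2 <- rowSums(sweep(coords, 2, coords[1, ], "-")^2)
  for (k in 2:m) {
    nxt <- which.max(d2)
    sel[k] <- nxt
    nd <- rowSums(sweep(coords, 2, coords[nxt, ], "-")^2)
    d2 <- pmin(d2, nd)
  }
  sort(sel)
}

#' Downsample regional landmarks with snap-back to mesh vertices
#'
#' Keeps `ceiling(rate * N)` vertices chosen by farthest-point sampling
#' on the sphere coordinates (falling back to 3D Euclidean coordinates
#' when the mesh has no sphere), so the retained landmarks stay spread
#' over the region. The selection is a subset of the original vertex
#' ids, so every retained point coincides exactly with a mesh vertex.
#'
#' @param landmarks an [extract_region_landmarks()] result.
#' @param rate fraction in `(0, 1]`.
#' @param mesh the parent [surface_mesh()].
#' @return An `lg_region_landmarks` with the reduced vertex set.
#' @export
downsample_snap <- function(landmarks, rate, mesh) {
  stopifnot(inherits(landmarks, "lg_region_landmarks"),
            rate > 0, rate <= 1, inherits(mesh, "lg_mesh"))
  n <- length(landmarks$vertex_ids)
  m <- ceiling(rate * n)
  if (m >= n) return(landmarks)
  coords <- if (!is.null(mesh$sphere))
    mesh$sphere[landmarks$vertex_ids, , drop = FALSE]
  else landmarks$points
  keep <- farthest_point_sample(coords, m)
  structure(list(region_id = landmarks$region_id,
                 points = landmarks$points[keep, , drop = FALSE],
                 vertex_ids = landmarks$vertex_ids[keep],
                 source = landmarks$source),
            class = "lg_region_landmarks")
}

#' Match template landmarks to subject vertices through the sphere
#'
#' Each template landmark, given its projection into the subject's
#' spherical space, is matched to the nearest subject vertex carrying the
#' same region label. Nearest is by chord (3D Euclidean) distance on the
#' unit sphere -- order-equivalent to great-circle distance -- with ties
#' broken by the lowest vertex id.
#'
#' @param subject an [surface_mesh()] with sphere coordinates.
#' @param template_landmarks an [extract_region_landmarks()] result from
#'   the template mesh.
#' @param template_sphere_coords `n x 3` projections of the template
#'   landmarks onto the subject's sphere (rows match
#'   `template_landmarks`).
#' @param covariance passed to [landmark_correspondence()].
#' @return An [landmark_correspondence()] with subject vertices as moving
#'   and template landmark positions as fixed points; the matched subject
#'   vertex ids are attached as attribute `"subject_vertex_ids"`.
#' @export
match_via_sphere <- function(subject, template_landmarks,
                             template_sphere_coords, covariance = 0.25) {
  stopifnot(inherits(subject, "lg_mesh"),
            inherits(template_landmarks, "lg_region_landmarks"))
  if (is.null(subject$sphere))
    stop("subject mesh has no sphere coordinates")
  proj <- as.matrix(template_sphere_coords)
  if (nrow(proj) != nrow(template_landmarks$points))
    stop("one projected sphere coordinate per template landmark required")
  cand <- which(subject$labels == template_landmarks$region_id)
  if (length(cand) == 0L)
    stop("subject mesh has no vertices labeled ", template_landmarks$region_id)
  sc <- subject$sphere[cand, , drop = FALSE]
  d2 <- outer(rowSums(proj^2), rowSums(sc^2), "+") - 2 * tcrossprod(proj, sc)
  nearest <- max.col(-d2, ties.method = "first")   # lowest id wins ties
  sub_ids <- cand[nearest]
  corr <- landmark_correspondence(subject$vertices[sub_ids, , drop = FALSE],
                                  template_landmarks$points, covariance)
  attr(corr, "subject_vertex_ids") <- sub_ids
  corr
}

#' Write / read a mesh as ASCII PLY (+ label CSV)
#'
#' Plain `ply` / `format ascii 1.0` with vertex properties `x y z` (and
#' `nx ny nz` holding the sphere coordinates when present) and triangle
#' face lists. Labels travel in a separate one-column CSV
#' (`read_labels_csv`/`write_labels_csv`) so the mesh stays readable by
#' any PLY tool.
#'
#' @param mesh an [surface_mesh()].
#' @param path `.ply` file path.
#' @return `read_ply` returns an [surface_mesh()] (labels all zero; attach
#'   via [surface_mesh()] if needed).
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "lg_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  has_sphere <- !is.null(mesh$sphere)
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               if (has_sphere) c("property float nx", "property float ny",
                                 "property float nz"),
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vm <- if (has_sphere) cbind(mesh$vertices, mesh$sphere) else mesh$vertices
  writeLines(apply(format(vm, digits = 17, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  if (nrow(mesh$faces) > 0)
    writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                     mesh$faces[, 3] - 1), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  vprops <- sub("^property \\S+ ", "",
                grep("^property (float|double)", hdr, value = TRUE))
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  vm <- matrix(scan(text = vl, quiet = TRUE), nrow = nv, byrow = TRUE)
  colnames(vm) <- vprops
  verts <- vm[, c("x", "y", "z"), drop = FALSE]
  sphere <- if (all(c("nx", "ny", "nz") %in% vprops))
    vm[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  faces <- matrix(integer(0), 0, 3)
  if (nf > 0) {
    fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
    fm <- matrix(scan(text = fl, quiet = TRUE), nrow = nf, byrow = TRUE)
    stopifnot(all(fm[, 1] == 3))
    faces <- fm[, 2:4, drop = FALSE] + 1L
  }
  surface_mesh(verts, faces, sphere = sphere)
}

#' Write / read per-vertex labels as a one-column CSV
#'
#' @param labels integer vector.
#' @param path `.csv` file path.
#' @return `read_labels_csv` returns an integer vector.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(data.frame(label = as.integer(labels)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  as.integer(utils::read.csv(path)$label)
}

#' Read a FreeSurfer binary triangle surface
#'
#' Optional adapter for FreeSurfer `lh.white`/`lh.pial`-style files:
#' big-endian, magic `16777214` (three `0xFF 0xFF 0xFE` bytes), a
#' newline-terminated creation comment, vertex/face counts as int32,
#' then `V x 3` float32 coordinates and `F x 3` int32 (0-based) faces.
#'
#' @param path surface file path.
#' @return An [surface_mesh()] (unlabeled).
#' @export
read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  val <- magic[1] * 65536 + magic[2] * 256 + magic[3]
  if (val != 16777214L)
    stop("not a FreeSurfer triangle surface (magic ", val, ")")
  # creation comment: terminated by two consecutive newlines
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) stop("truncated surface file")
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  verts <- matrix(readBin(con, "numeric", nv * 3, size = 4, endian = "big"),
                  ncol = 3, byrow = TRUE)
  faces <- matrix(readBin(con, "integer", nf * 3, size = 4, endian = "big"),
                  ncol = 3, byrow = TRUE) + 1L
  surface_mesh(verts, faces)
}

#' Read a FreeSurfer annotation (parcellation) file
#'
#' Optional adapter: big-endian int32 vertex count, then (vertex id,
#' packed RGB annotation) pairs. Returns the raw annotation codes per
#' vertex; mapping codes to region ids is left to the caller's lookup
#' table.
#'
#' @param path `.annot` file path.
#' @return Integer vector of annotation codes indexed by vertex.
#' @export
read_fs_annot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  data <- readBin(con, "integer", 2 * n, size = 4, endian = "big")
  idx <- data[seq(1, 2 * n, by = 2)] + 1L
  ann <- data[seq(2, 2 * n, by = 2)]
  out <- integer(max(idx))
  out[idx] <- ann
  out
}
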