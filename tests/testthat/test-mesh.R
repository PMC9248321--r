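# synthetic labeled sphere mesh: latitude-longitude triangulation with
# labels split at the equator, sphere coords equal to the unit vertices
lat_long_sphere <- function(n_lat = 9, n_lon = 12, radius = 10) {
  th <- seq(0.15, pi - 0.15, length.out = n_lat)
  ph <- seq(0, 2 * pi, length.out = n_lon + 1)[seq_len(n_lon)]
  g <- expand.grid(th = th, ph = ph)
  unitv <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  faces <- NULL
  at <- function(i, j) (j - 1) * n_lat + i
  for (j in seq_len(n_lon)) {
    jn <- if (j == n_lon) 1 else j + 1
    for (i in seq_len(n_lat - 1)) {
      faces <- rbind(faces,
                     c(at(i, j), at(i + 1, j), at(i, jn)),
                     c(at(i + 1, j), at(i + 1, jn), at(i, jn)))
    }
  }
  labels <- ifelse(unitv[, 3] >= 0, 1L, 2L)
  surface_mesh(unitv * radius, faces, labels, sphere = unitv)
}

test_that("mesh construction validates faces, labels and sphere", {
  m <- lat_long_sphere()
  expect_s3_class(m, "lg_mesh")
  expect_error(surface_mesh(m$vertices, m$faces + 10000L, m$labels),
               "out of vertex range")
  expect_error(surface_mesh(m$vertices, m$faces, m$labels[-1]),
               "one region label per vertex")
  expect_error(surface_mesh(m$vertices, m$faces, m$labels,
                            sphere = m$sphere * 2), "unit norm")
})

test_that("region extraction returns all and only the labeled vertices", {
  m <- lat_long_sphere()
  for (r in 1:2) {
    lm <- extract_region_landmarks(m, r)
    scan <- which(m$labels == r)           # direct label scan oracle
    expect_identical(lm$vertex_ids, scan)
    expect_identical(lm$points, m$vertices[scan, , drop = FALSE])
    expect_true(all(diff(lm$vertex_ids) > 0))
  }
  all1 <- surface_mesh(m$vertices, m$faces, rep(1L, nrow(m$vertices)))
  expect_identical(length(extract_region_landmarks(all1, 1)$vertex_ids),
                   nrow(m$vertices))
  expect_error(extract_region_landmarks(m, 99), "absent")
})

test_that("downsampling keeps a well-spread exact subset", {
  m <- lat_long_sphere()
  lm <- extract_region_landmarks(m, 1)
  expect_identical(downsample_snap(lm, 1, m)$vertex_ids, lm$vertex_ids)

  half <- downsample_snap(lm, 0.5, m)
  expect_identical(length(half$vertex_ids), as.integer(ceiling(0.5 * length(lm$vertex_ids))))
  expect_true(all(half$vertex_ids %in% lm$vertex_ids))
  expect_identical(half$points, m$vertices[half$vertex_ids, , drop = FALSE])
  # monotone in count; idempotent at rate 1 afterwards
  expect_lte(length(downsample_snap(lm, 0.2, m)$vertex_ids),
             length(half$vertex_ids))
  expect_identical(downsample_snap(half, 1, m)$vertex_ids, half$vertex_ids)
})

test_that("farthest-point sampling of a decagon stays nearly uniform", {
  ang <- 2 * pi * (0:9) / 10
  circ <- surface_mesh(cbind(cos(ang), sin(ang), 0) * 5,
                       matrix(c(1L, 2L, 3L), 1), rep(1L, 10))
  lm <- extract_region_landmarks(circ, 1)
  sel <- downsample_snap(lm, 0.5, circ)
  a <- sort(ang[sel$vertex_ids])
  gaps <- diff(c(a, a[1] + 2 * pi))
  expect_identical(length(a), 5L)
  expect_lte(max(gaps), 2 * (2 * pi / 10) * 2)
})

test_that("sphere matching is exact on self, label-consistent, tie-broken low", {
  m <- lat_long_sphere()
  lm <- extract_region_landmarks(m, 1)
  corr <- match_via_sphere(m, lm, m$sphere[lm$vertex_ids, , drop = FALSE])
  expect_equal(corr$moving, corr$fixed, ignore_attr = TRUE)
  expect_identical(attr(corr, "subject_vertex_ids"), lm$vertex_ids)

  # matched subject vertices always carry the template region label
  lm2 <- extract_region_landmarks(m, 2)
  corr2 <- match_via_sphere(m, lm2, m$sphere[lm2$vertex_ids, , drop = FALSE])
  expect_true(all(m$labels[attr(corr2, "subject_vertex_ids")] == 2L))

  # a projection exactly midway between subject vertices 1 and 2 picks 1
  mid <- m$sphere[1, ] + m$sphere[2, ]
  mid <- mid / sqrt(sum(mid^2))
  stopifnot(m$labels[1] == m$labels[2])
  single <- structure(list(region_id = m$labels[1], points = matrix(0, 1, 3),
                           vertex_ids = 1L, source = "pial"),
                      class = "lg_region_landmarks")
  got <- match_via_sphere(m, single, matrix(mid, 1))
  expect_identical(attr(got, "subject_vertex_ids"), 1L)

  expect_error(match_via_sphere(m, structure(list(region_id = 99L,
    points = matrix(0, 1, 3), vertex_ids = 1L, source = "pial"),
    class = "lg_region_landmarks"), matrix(mid, 1)), "no vertices labeled")
})

test_that("sphere matching is invariant to a joint rotation", {
  m <- lat_long_sphere()
  lm <- extract_region_landmarks(m, 1)
  proj <- m$sphere[lm$vertex_ids, , drop = FALSE]
  # jitter the projections so matches are nontrivial
  set.seed(21)
  proj <- proj + matrix(rnorm(length(proj), sd = 0.05), nrow(proj))
  proj <- proj / sqrt(rowSums(proj^2))
  base <- attr(match_via_sphere(m, lm, proj), "subject_vertex_ids")

  th <- 0.7; ax <- c(1, 2, 2) / 3
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  mr <- surface_mesh(m$vertices, m$faces, m$labels, sphere = m$sphere %*% t(R))
  rot <- attr(match_via_sphere(mr, lm, proj %*% t(R)), "subject_vertex_ids")
  expect_identical(base, rot)
})

test_that("ASCII PLY and label CSV round-trip a labeled sphere", {
  m <- lat_long_sphere()
  ply <- tempfile(fileext = ".ply")
  csv <- tempfile(fileext = ".csv")
  write_ply(m, ply)
  write_labels_csv(m$labels, csv)
  back <- read_ply(ply)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$faces, m$faces)
  expect_equal(back$sphere, m$sphere, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(read_labels_csv(csv), m$labels)
  relabeled <- surface_mesh(back$vertices, back$faces, read_labels_csv(csv),
                            sphere = back$sphere)
  expect_identical(relabeled$labels, m$labels)
})

test_that("FreeSurfer binary surface and annot adapters read synthetic files", {
  m <- lat_long_sphere()
  surf <- tempfile()
  con <- file(surf, "wb")
  writeBin(as.raw(c(0xff, 0xff, 0xfe)), con)
  writeBin(charToRaw("created synthetically\n\n"), con)
  writeBin(c(nrow(m$vertices), nrow(m$faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(m$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(m$faces) - 1L), con, size = 4, endian = "big")
  close(con)
  got <- read_fs_surface(surf)
  expect_equal(got$vertices, m$vertices, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(got$faces, m$faces)

  ann <- tempfile(fileext = ".annot")
  codes <- as.integer(c(101, 202, 101, 303))
  con <- file(ann, "wb")
  writeBin(4L, con, size = 4, endian = "big")
  writeBin(as.integer(rbind(0:3, codes)), con, size = 4, endian = "big")
  close(con)
  expect_identical(read_fs_annot(ann), codes)

  bad <- tempfile()
  writeBin(as.raw(c(0x00, 0x01, 0x02, 0x03)), bad)
  expect_error(read_fs_surface(bad), "magic")
})
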