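#' Concatenate the linear alignments and the nonlinear regional field
#'
#' Builds a region's full warp `T_i(x) = D_i(A'_i(A(x)))` as a forward
#' displacement on the subject grid and its counterpart
#' `T_i^{-1}(x) = A^{-1}(A'_i^{-1}(x + D_i^{-1}(x)))` as a reverse
#' displacement on the template grid. `A` is the global affine, `A_i` the
#' per-region translation, and `D_fwd`/`D_rev` the regional shooting
#' fields in the initially aligned frame.
#'
#' @param A global [affine_transform()] (subject to template).
#' @param A_i per-region [affine_transform()] applied after `A`.
#' @param D_fwd forward [displacement_field()] on the aligned-frame grid.
#' @param D_rev reverse [displacement_field()] on the template grid.
#' @param grid_subject grid on which the forward warp is expressed
#'   (default: `D_fwd`'s grid).
#' @param region_id integer id stored with the warp.
#' @return An object of class `lg_regional_warp` with fields `region_id`,
#'   `forward` and `reverse`.
#' @export
concatenate_regional <- function(A, A_i, D_fwd, D_rev,
                                 grid_subject = D_fwd$grid, region_id = 1L) {
  stopifnot(inherits(A, "lg_affine"), inherits(A_i, "lg_affine"),
            inherits(D_fwd, "lg_field"), inherits(D_rev, "lg_field"))
  if (!grids_compatible(grid_subject, D_fwd$grid) ||
      !grids_compatible(D_fwd$grid, D_rev$grid))
    stop("regional field grids have mismatched axes/spacing")
  lin <- affine_compose(A_i, A)
  # forward: subject grid point x -> aligned frame y -> y + D(y)
  xs <- grid_points(grid_subject)
  y <- apply_affine(xs, lin)
  Ty <- y + interp_field_at(D_fwd, y, oob = "clamp")
  fwd <- displacement_field(grid_subject,
                            matrix_to_field_values(grid_subject, Ty - xs),
                            domain = "subject", direction = "forward")
  # reverse: template grid point x -> x + D^{-1}(x) -> back through linears
  gt <- D_rev$grid
  xt <- grid_points(gt)
  z <- xt + field_matrix(D_rev)
  back <- apply_affine(z, affine_inverse(lin))
  rev <- displacement_field(gt, matrix_to_field_values(gt, back - xt),
                            domain = "template", direction = "reverse")
  structure(list(region_id = as.integer(region_id), forward = fwd,
                 reverse = rev),
            class = "lg_regional_warp")
}

#' @export
print.lg_regional_warp <- function(x, ...) {
  cat("<lg_regional_warp> region", x$region_id, "\n  forward: ")
  print(x$forward)
  cat("  reverse: ")
  print(x$reverse)
  invisible(x)
}
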