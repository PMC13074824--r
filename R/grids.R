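#' Regular sampling grids centred on the beam axis
#'
#' All fields in fusmark live on regular grids centred on the transducer's
#' natural focus, with the z axis along the direction of propagation.
#' `grid2d()` describes a transverse measurement plane (a hydrophone scan
#' raster), `grid3d()` a reconstruction volume. Coordinates are in metres;
#' for odd sample counts the axis passes through a sample.
#'
#' @param nx,ny,nz number of samples along each axis.
#' @param dx,dy,dz sample spacing in metres.
#' @return An object of class `fus_grid2d` or `fus_grid3d` holding the
#'   sample counts, spacings and centred coordinate vectors.
#' @examples
#' g <- grid2d(41, 41, 0.5e-3, 0.5e-3)  # a 2 x 2 cm, 0.5 mm scan raster
#' range(g$x)
#' @export
grid2d <- function(nx, ny, dx, dy = dx) {
  stopifnot(nx >= 1, ny >= 1, dx > 0, dy > 0)
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy,
    x = (seq_len(nx) - (nx + 1) / 2) * dx,
    y = (seq_len(ny) - (ny + 1) / 2) * dy
  ), class = "fus_grid2d")
}

#' @rdname grid2d
#' @export
grid3d <- function(nx, ny, nz, dx, dy = dx, dz = dx) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, dx > 0, dy > 0, dz > 0)
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    dx = dx, dy = dy, dz = dz,
    x = (seq_len(nx) - (nx + 1) / 2) * dx,
    y = (seq_len(ny) - (ny + 1) / 2) * dy,
    z = (seq_len(nz) - (nz + 1) / 2) * dz
  ), class = "fus_grid3d")
}

#' @export
print.fus_grid2d <- function(x, ...) {
  cat(sprintf("<fus_grid2d> %d x %d samples, %.3g x %.3g mm spacing\n",
              x$nx, x$ny, x$dx * 1e3, x$dy * 1e3))
  invisible(x)
}

#' @export
print.fus_grid3d <- function(x, ...) {
  cat(sprintf("<fus_grid3d> %d x %d x %d samples, %.3g x %.3g x %.3g mm spacing\n",
              x$nx, x$ny, x$nz, x$dx * 1e3, x$dy * 1e3, x$dz * 1e3))
  invisible(x)
}

voxel_volume <- function(grid) grid$dx * grid$dy * grid$dz

same_grid <- function(a, b, tol = 1e-9) {
  all(
    a$nx == b$nx, a$ny == b$ny, isTRUE(a$nz == b$nz) || (is.null(a$nz) && is.null(b$nz)),
    abs(a$dx - b$dx) < tol, abs(a$dy - b$dy) < tol,
    is.null(a$dz) || abs(a$dz - b$dz) < tol
  )
}
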