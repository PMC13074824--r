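#' Complex pressure on a transverse scan plane
#'
#' The basic acoustic measurement container: complex pressure samples on a
#' regular 2D grid at a known signed axial offset from the natural focus,
#' together with the drive frequency and medium sound speed needed to
#' propagate it. Mirrors a calibrated hydrophone raster scan.
#'
#' @param field complex matrix (nx x ny) of pressure samples; rows index x.
#' @param spacing length-2 numeric, sample spacing (dx, dy) in metres; must
#'   be below half the acoustic wavelength.
#' @param z_offset signed axial position of the plane relative to the
#'   natural focus, metres.
#' @param frequency acoustic frequency, Hz.
#' @param sound_speed medium sound speed, m/s.
#' @return An object of class `pressure_plane`.
#' @seealso [simulate_bowl_plane()], [project_plane()],
#'   [write_pressure_plane()]
#' @export
pressure_plane <- function(field, spacing, z_offset = 0,
                           frequency = 1e6, sound_speed = 1482) {
  if (!is.matrix(field)) stop("field must be a matrix")
  if (!is.complex(field)) field <- field + 0i
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  stopifnot(length(spacing) == 2, all(spacing > 0),
            frequency > 0, sound_speed > 0)
  lam <- sound_speed / frequency
  if (max(spacing) >= lam / 2)
    stop("plane spacing must be below lambda/2 = ", format(lam / 2 * 1e3), " mm")
  structure(list(
    field = field,
    grid = grid2d(nrow(field), ncol(field), spacing[1], spacing[2]),
    z_offset = z_offset,
    frequency = frequency,
    sound_speed = sound_speed
  ), class = "pressure_plane")
}

#' @export
print.pressure_plane <- function(x, ...) {
  cat(sprintf(
    "<pressure_plane> %d x %d @ %.3g x %.3g mm, z = %+.3g mm, f = %.3g MHz\n",
    x$grid$nx, x$grid$ny, x$grid$dx * 1e3, x$grid$dy * 1e3,
    x$z_offset * 1e3, x$frequency / 1e6))
  cat(sprintf("  peak |p| = %.4g\n", max(Mod(x$field))))
  invisible(x)
}

#' Read and write pressure-plane containers
#'
#' Planes are stored as a single JSON document holding the grid geometry,
#' acoustic constants and the real and imaginary sample arrays at full
#' double precision — a self-describing plain-text container.
#' `export_plane_magnitude_csv()` additionally writes a plain
#' magnitude table (x, y, magnitude) for quick inspection in any tool.
#'
#' @param plane a [pressure_plane()].
#' @param path file path to write to / read from.
#' @return `read_pressure_plane()` returns a [pressure_plane()];
#'   the writers return `path` invisibly.
#' @export
write_pressure_plane <- function(plane, path) {
  stopifnot(inherits(plane, "pressure_plane"))
  obj <- list(
    format = "fusmark-pressure-plane-v1",
    nx = plane$grid$nx, ny = plane$grid$ny,
    dx = plane$grid$dx, dy = plane$grid$dy,
    z_offset = plane$z_offset,
    frequency = plane$frequency,
    sound_speed = plane$sound_speed,
    real = as.vector(Re(plane$field)),
    imag = as.vector(Im(plane$field))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pressure_plane
#' @export
read_pressure_plane <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fusmark-pressure-plane-v1"))
    stop("not a fusmark pressure-plane container: ", path)
  field <- matrix(complex(real = as.numeric(obj$real),
                          imaginary = as.numeric(obj$imag)),
                  obj$nx, obj$ny)
  pressure_plane(field, spacing = as.numeric(c(obj$dx, obj$dy)),
                 z_offset = as.numeric(obj$z_offset),
                 frequency = as.numeric(obj$frequency),
                 sound_speed = as.numeric(obj$sound_speed))
}

#' @rdname write_pressure_plane
#' @export
export_plane_magnitude_csv <- function(plane, path) {
  stopifnot(inherits(plane, "pressure_plane"))
  df <- data.frame(
    x_mm = rep(plane$grid$x, times = plane$grid$ny) * 1e3,
    y_mm = rep(plane$grid$y, each = plane$grid$nx) * 1e3,
    magnitude = as.vector(Mod(plane$field))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Tidy a pressure plane into a long tibble
#'
#' One row per sample with coordinates in millimetres, for plotting and
#' dplyr-style summaries.
#'
#' @param x a [pressure_plane()].
#' @param ... unused.
#' @return A tibble with columns `x_mm`, `y_mm`, `magnitude`, `phase`.
#' @export
tidy.pressure_plane <- function(x, ...) {
  tibble::tibble(
    x_mm = rep(x$grid$x, times = x$grid$ny) * 1e3,
    y_mm = rep(x$grid$y, each = x$grid$nx) * 1e3,
    magnitude = as.vector(Mod(x$field)),
    phase = as.vector(Arg(x$field))
  )
}

#' @export
autoplot.pressure_plane <- function(object, ...) {
  df <- tidy.pressure_plane(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|p| (a.u.)") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)",
      title = sprintf("Pressure magnitude at z = %+.1f mm", object$z_offset * 1e3)
    )
}
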