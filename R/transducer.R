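#' Spherically focused transducer geometry
#'
#' Describes a spherically curved (bowl) source by its focal length (radius
#' of curvature), aperture diameter, drive frequency and the sound speed of
#' the coupling medium. The default values describe a 1 MHz bowl with a
#' 13 cm focal length and 15.4 cm aperture operating in 20 degC water
#' (c = 1482 m/s). `source_discretization` sets the number of surface
#' patches used for the Rayleigh-integral forward model; the equal-area
#' ring scheme makes patch areas sum exactly to the spherical-cap area at
#' any count.
#'
#' @param focal_length radius of curvature of the bowl in metres.
#' @param aperture_diameter aperture (chord) diameter in metres; must be
#'   smaller than `2 * focal_length`.
#' @param frequency drive frequency in Hz.
#' @param sound_speed medium sound speed in m/s.
#' @param source_discretization target number of surface patches for
#'   numerical integration (default 40000).
#' @return An object of class `transducer_geometry`.
#' @examples
#' geom <- transducer_geometry()
#' geom$wavelength * 1e3  # ~1.48 mm in water at 1 MHz
#' @export
transducer_geometry <- function(focal_length = 0.13,
                                aperture_diameter = 0.154,
                                frequency = 1e6,
                                sound_speed = 1482,
                                source_discretization = 40000) {
  stopifnot(focal_length > 0, aperture_diameter > 0, frequency > 0,
            sound_speed > 0, source_discretization >= 100)
  if (focal_length <= aperture_diameter / 2)
    stop("focal_length must exceed the aperture radius")
  structure(list(
    focal_length = focal_length,
    aperture_diameter = aperture_diameter,
    frequency = frequency,
    sound_speed = sound_speed,
    source_discretization = as.integer(source_discretization),
    wavelength = sound_speed / frequency,
    wavenumber = 2 * pi * frequency / sound_speed
  ), class = "transducer_geometry")
}

#' @export
print.transducer_geometry <- function(x, ...) {
  cat(sprintf(
    "<transducer_geometry> F = %.3g cm, D = %.3g cm, f = %.3g MHz, c = %g m/s\n",
    x$focal_length * 1e2, x$aperture_diameter * 1e2, x$frequency / 1e6,
    x$sound_speed))
  invisible(x)
}

#' Thin complex-transmission occlusion screen
#'
#' Models a biopsy marker (or any beam obstruction) as a thin circular
#' screen that multiplies the incident complex pressure by
#' `amplitude_transmission * exp(i * phase_shift)` inside its radius and by
#' 1 outside. The screen sits in a transverse plane at a signed axial
#' offset from the natural focus (negative = towards the transducer,
#' "near-field"; positive = beyond the focus, "far-field") and may be
#' displaced laterally.
#'
#' @param plane_offset signed axial offset of the screen plane from the
#'   natural focus, metres.
#' @param center_offset length-2 numeric, lateral (x, y) displacement of
#'   the screen centre from the beam axis, metres.
#' @param radius screen radius, metres.
#' @param amplitude_transmission amplitude transmission factor in \[0, 1\]
#'   (0 = opaque, 1 = transparent).
#' @param phase_shift phase delay imparted inside the screen, radians.
#' @return An object of class `occlusion_screen`.
#' @examples
#' # an opaque 1.5 mm-radius marker 7 mm beyond the focus
#' occlusion_screen(plane_offset = 7e-3, radius = 1.5e-3,
#'                  amplitude_transmission = 0)
#' @export
occlusion_screen <- function(plane_offset = 0,
                             center_offset = c(0, 0),
                             radius = 1.5e-3,
                             amplitude_transmission = 0,
                             phase_shift = 0) {
  stopifnot(radius >= 0, length(center_offset) == 2,
            amplitude_transmission >= 0, amplitude_transmission <= 1)
  structure(list(
    plane_offset = plane_offset,
    center_offset = as.numeric(center_offset),
    radius = radius,
    amplitude_transmission = amplitude_transmission,
    phase_shift = phase_shift
  ), class = "occlusion_screen")
}

# Equal-area ring discretization of the bowl surface.  Focus at the
# origin, propagation towards +z, bowl apex at (0, 0, -F).  Patch areas
# sum exactly to the spherical-cap area 2*pi*F*h.
discretize_bowl <- function(geom, n_points = geom$source_discretization) {
  F <- geom$focal_length
  a <- geom$aperture_diameter / 2
  theta_max <- asin(a / F)
  cap_area <- 2 * pi * F^2 * (1 - cos(theta_max))
  # ring angular width chosen so point count ~ n_points
  dtheta <- sqrt(cap_area / F^2 / n_points)
  n_rings <- max(4L, ceiling(theta_max / dtheta))
  dtheta <- theta_max / n_rings
  theta <- (seq_len(n_rings) - 0.5) * dtheta
  n_per_ring <- pmax(1L, round(2 * pi * sin(theta) / dtheta))
  ring_area <- 2 * pi * F^2 * (cos(theta - dtheta / 2) - cos(theta + dtheta / 2))
  xs <- ys <- zs <- ws <- vector("list", n_rings)
  for (i in seq_len(n_rings)) {
    m <- n_per_ring[i]
    phi <- (seq_len(m) - 0.5) * 2 * pi / m
    xs[[i]] <- F * sin(theta[i]) * cos(phi)
    ys[[i]] <- F * sin(theta[i]) * sin(phi)
    zs[[i]] <- rep(-F * cos(theta[i]), m)
    ws[[i]] <- rep(ring_area[i] / m, m)
  }
  list(x = unlist(xs), y = unlist(ys), z = unlist(zs), w = unlist(ws))
}

# Rayleigh field of the bowl at arbitrary field points (units rho*c*u0)
bowl_field_at <- function(geom, fx, fy, fz, n_points = geom$source_discretization) {
  src <- discretize_bowl(geom, n_points)
  rayleigh_sum(src$x, src$y, src$z, src$w, fx, fy, fz, geom$wavenumber)
}

#' Simulate a hydrophone scan plane of a focused bowl source
#'
#' Computes the complex pressure of a spherically focused source on a
#' regular transverse grid by direct Rayleigh integration over the
#' discretized bowl surface. An optional thin occlusion screen models a
#' biopsy marker in the beam path: the field is first evaluated on the
#' screen plane, multiplied by the screen's complex transmission inside
#' its radius, then propagated to the measurement plane with the angular
#' spectrum method. Optional measurement noise is independent complex
#' circular Gaussian per sample.
#'
#' Pressure is reported in units of `rho * c * u0` (unit normal velocity on
#' the source); only relative quantities are used downstream.
#'
#' @param geom a [transducer_geometry()].
#' @param grid a [grid2d()] scan raster; its spacing must satisfy the
#'   sampling condition `spacing < lambda / 2`.
#' @param z_offset signed axial position of the measurement plane relative
#'   to the natural focus, metres (|z_offset| <= 0.05 m).
#' @param screen optional [occlusion_screen()]; its plane must not lie
#'   beyond the measurement plane.
#' @param noise_sd standard deviation of the additive complex Gaussian
#'   noise per real/imaginary channel, in pressure units (default 0).
#' @param seed integer seed controlling the noise draw; with a fixed seed
#'   the output is bit-reproducible.
#' @param pad_factor zero-padding factor for the screen-to-plane angular
#'   spectrum step (see [project_plane()]).
#' @return A [pressure_plane()] with the complex field on `grid`.
#' @examples
#' geom <- transducer_geometry(source_discretization = 5000)
#' pl <- simulate_bowl_plane(geom, grid2d(21, 21, 0.5e-3), z_offset = 0)
#' max(Mod(pl$field))  # on-axis focal amplitude ~ k * h
#' @export
simulate_bowl_plane <- function(geom, grid, z_offset = 0, screen = NULL,
                                noise_sd = 0, seed = 1L, pad_factor = 2L) {
  stopifnot(inherits(geom, "transducer_geometry"), inherits(grid, "fus_grid2d"))
  lam <- geom$wavelength
  if (max(grid$dx, grid$dy) >= lam / 2)
    stop("grid spacing must be below lambda/2 (", format(lam / 2 * 1e3),
         " mm) to avoid aliasing")
  if (abs(z_offset) > 0.05)
    stop("z_offset must lie within +/-0.05 m of the natural focus")

  if (is.null(screen)) {
    pts <- expand.grid(x = grid$x, y = grid$y, KEEP.OUT.ATTRS = FALSE)
    f <- bowl_field_at(geom, pts$x, pts$y, rep(z_offset, nrow(pts)))
    field <- matrix(f, grid$nx, grid$ny)
  } else {
    stopifnot(inherits(screen, "occlusion_screen"))
    if (screen$plane_offset > z_offset)
      stop("screen plane lies beyond the measurement plane; ",
           "the screen must sit between source and measurement plane")
    field <- screened_bowl_plane(geom, grid, z_offset, screen, pad_factor)
  }

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    n <- length(field)
    field <- field + complex(real = stats::rnorm(n, 0, noise_sd),
                             imaginary = stats::rnorm(n, 0, noise_sd))
  }
  pressure_plane(field, spacing = c(grid$dx, grid$dy), z_offset = z_offset,
                 frequency = geom$frequency, sound_speed = geom$sound_speed)
}

# Field with a thin screen: Rayleigh to the screen plane on an enlarged
# grid (covering the aperture cone and the screen), complex transmission,
# angular spectrum to the measurement plane, crop to the requested grid.
screened_bowl_plane <- function(geom, grid, z_offset, screen, pad_factor) {
  F <- geom$focal_length
  a <- geom$aperture_diameter / 2
  zs <- screen$plane_offset
  # the screen-plane window must cover the beam cone (plus a diffraction
  # margin) and the requested grid; field outside the cone is negligible,
  # so screen area beyond it needs no sampling
  cone <- a * abs(zs) / F
  need <- max(max(abs(grid$x)), max(abs(grid$y)), cone + 5e-3)
  extra_x <- max(0L, ceiling((need - max(abs(grid$x))) / grid$dx))
  extra_y <- max(0L, ceiling((need - max(abs(grid$y))) / grid$dy))
  big <- grid2d(grid$nx + 2L * extra_x, grid$ny + 2L * extra_y, grid$dx, grid$dy)

  r2 <- outer((big$x - screen$center_offset[1])^2,
              (big$y - screen$center_offset[2])^2, `+`)
  inside <- r2 <= screen$radius^2
  trans <- screen$amplitude_transmission * exp(1i * screen$phase_shift)

  pts <- expand.grid(x = big$x, y = big$y, KEEP.OUT.ATTRS = FALSE)
  field <- matrix(0i, big$nx, big$ny)
  # an opaque screen zeroes the field inside its radius; skip those points
  keep <- if (trans == 0i) !as.vector(inside) else rep(TRUE, nrow(pts))
  if (any(keep))
    field[keep] <- bowl_field_at(geom, pts$x[keep], pts$y[keep],
                                 rep(zs, sum(keep)))
  field[inside] <- field[inside] * trans

  prop <- if (z_offset == zs) field else
    angular_spectrum_step(field, big$dx, big$dy,
                          k = geom$wavenumber,
                          dz = z_offset - zs,
                          pad_factor = pad_factor)
  prop[extra_x + seq_len(grid$nx), extra_y + seq_len(grid$ny)]
}
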