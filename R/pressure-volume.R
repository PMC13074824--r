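#' Volumetric pressure field around the natural focus
#'
#' A 3D pressure field on a regular grid, usually produced by
#' [project_plane()]. The field may be complex (projection output) or a
#' plain magnitude array; all focus metrics operate on the magnitude.
#'
#' @param field 3D array, complex or numeric; dimensions (nx, ny, nz).
#' @param spacing length-3 numeric, voxel spacing (dx, dy, dz) in metres.
#' @param z_positions optional numeric vector of slab axial positions
#'   relative to the natural focus (metres); defaults to a grid centred
#'   on zero.
#' @param frequency,sound_speed acoustic constants carried for provenance.
#' @return An object of class `pressure_volume`.
#' @export
pressure_volume <- function(field, spacing, z_positions = NULL,
                            frequency = NA_real_, sound_speed = NA_real_) {
  stopifnot(is.array(field), length(dim(field)) == 3,
            length(spacing) == 3, all(spacing > 0))
  d <- dim(field)
  if (is.null(z_positions))
    z_positions <- (seq_len(d[3]) - (d[3] + 1) / 2) * spacing[3]
  stopifnot(length(z_positions) == d[3])
  g <- grid3d(d[1], d[2], d[3], spacing[1], spacing[2], spacing[3])
  g$z <- z_positions
  structure(list(
    field = field, grid = g,
    frequency = frequency, sound_speed = sound_speed
  ), class = "pressure_volume")
}

#' @export
print.pressure_volume <- function(x, ...) {
  d <- dim(x$field)
  cat(sprintf(
    "<pressure_volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$grid$dx * 1e3, x$grid$dy * 1e3, x$grid$dz * 1e3))
  cat(sprintf("  z range %+.3g to %+.3g mm, peak |p| = %.4g\n",
              min(x$grid$z) * 1e3, max(x$grid$z) * 1e3, max(Mod(x$field))))
  invisible(x)
}

volume_magnitude <- function(vol) {
  if (is.complex(vol$field)) Mod(vol$field) else vol$field
}

#' Normalized RMS difference between two pressure volumes
#'
#' Compares the magnitude of a reconstructed field against a reference on
#' the same grid:
#' `sqrt(mean((|test| - |ref|)^2)) / norm`,
#' where the normalization `norm` is by default the spatial peak of the
#' reference magnitude. This is the volumetric field-validation statistic
#' of the pipeline: projections of the same physical field measured at
#' different scan offsets should agree to a few percent.
#'
#' The statistic is symmetric in its arguments except through the
#' normalization: swapping `test` and `reference` changes only the
#' denominator (and not at all for `normalization = "joint_peak"`).
#'
#' @param test,reference [pressure_volume()] objects on identical grids.
#' @param normalization `"reference_peak"` (default), `"reference_rms"`,
#'   or `"joint_peak"` (peak over both volumes).
#' @return A single nonnegative number; 0 iff the magnitudes are identical.
#' @export
rmsd_volumes <- function(test, reference,
                         normalization = c("reference_peak", "reference_rms",
                                           "joint_peak")) {
  stopifnot(inherits(test, "pressure_volume"),
            inherits(reference, "pressure_volume"))
  normalization <- match.arg(normalization)
  if (!identical(dim(test$field), dim(reference$field)))
    stop("volumes are on different grids")
  if (!same_grid(test$grid, reference$grid))
    stop("volumes are on different grids")
  a <- volume_magnitude(test)
  b <- volume_magnitude(reference)
  num <- sqrt(mean((a - b)^2))
  den <- switch(normalization,
    reference_peak = max(b),
    reference_rms = sqrt(mean(b^2)),
    joint_peak = max(a, b))
  if (den == 0) stop("reference volume is identically zero")
  num / den
}
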