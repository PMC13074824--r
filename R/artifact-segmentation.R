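#' Simulate a phantom image with a spherical signal void
#'
#' Generates a scalar 3D magnitude image of a cylindrical phantom (axis
#' along z) containing a spherical signal void: background voxels sit at
#' the noise floor, phantom voxels at `signal_level`, void voxels back at
#' the noise floor. The defaults emulate the study's 6 cm diameter, 7 cm
#' tall gelatin cylinders. Optional Gaussian texture noise is added on
#' top. The auxiliary masks needed by segmentation — the phantom mask and
#' a background noise-region mask — are returned with the image.
#'
#' @param grid a [grid3d()].
#' @param cylinder_radius,cylinder_height phantom dimensions, m.
#' @param void_center length-3 void centre, m; must place the void
#'   strictly inside the phantom (unless the radius is 0).
#' @param void_radius void radius, m (0 = no void).
#' @param signal_level phantom signal, arbitrary units; must exceed
#'   `2 * noise_mean`.
#' @param noise_mean mean intensity of background and void, a.u.
#' @param noise_sd additive Gaussian noise sd (0 = noiseless, piecewise
#'   constant image).
#' @param seed integer seed.
#' @return A list: `image` (3D array), `phantom_mask`, `noise_region`
#'   (both logical arrays), `grid`, and the generating parameters.
#' @export
simulate_phantom_image <- function(grid,
                                   cylinder_radius = 0.03,
                                   cylinder_height = 0.07,
                                   void_center = c(0, 0, 0),
                                   void_radius = 5e-3,
                                   signal_level = 100,
                                   noise_mean = 10,
                                   noise_sd = 0,
                                   seed = 1L) {
  stopifnot(inherits(grid, "fus_grid3d"), cylinder_radius > 0,
            cylinder_height > 0, void_radius >= 0, noise_sd >= 0)
  if (signal_level <= 2 * noise_mean)
    stop("signal_level must exceed twice the noise mean")
  if (void_radius > 0) {
    rin <- sqrt(sum(void_center[1:2]^2)) + void_radius
    zin <- abs(void_center[3]) + void_radius
    if (rin >= cylinder_radius || zin >= cylinder_height / 2)
      stop("void must lie strictly inside the phantom")
  }
  r2xy <- outer(grid$x^2, grid$y^2, `+`)
  in_cyl2d <- r2xy <= cylinder_radius^2
  in_z <- abs(grid$z) <= cylinder_height / 2
  phantom <- array(in_cyl2d, c(grid$nx, grid$ny, grid$nz)) &
    array(rep(in_z, each = grid$nx * grid$ny), c(grid$nx, grid$ny, grid$nz))

  dx2 <- (grid$x - void_center[1])^2
  dy2 <- (grid$y - void_center[2])^2
  dz2 <- (grid$z - void_center[3])^2
  r2 <- array(outer(dx2, dy2, `+`), c(grid$nx, grid$ny, grid$nz)) +
    array(rep(dz2, each = grid$nx * grid$ny), c(grid$nx, grid$ny, grid$nz))
  void <- void_radius > 0 & r2 <= void_radius^2

  img <- array(noise_mean, dim = c(grid$nx, grid$ny, grid$nz))
  img[phantom] <- signal_level
  img[void & phantom] <- noise_mean
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
  }
  list(image = img, phantom_mask = phantom, noise_region = !phantom,
       grid = grid, void_radius = void_radius, void_center = void_center,
       signal_level = signal_level, noise_mean = noise_mean)
}

#' Segment a marker signal-void artifact
#'
#' Implements the noise-referenced threshold rule for signal-void
#' segmentation: the threshold is 125% of the mean intensity of a
#' user-identified no-signal region; candidate voxels are those strictly
#' below the threshold and inside the phantom mask; the returned void is
#' the largest connected component of the candidates (or the component
#' containing `seed_point`, for images with several voids). Because the
#' threshold scales with the noise mean, the segmentation is invariant
#' under positive rescaling of the image.
#'
#' @param image numeric 3D array.
#' @param noise_region logical array, nonempty, marking a no-signal
#'   region in or near the phantom.
#' @param phantom_mask logical array restricting candidates to the
#'   phantom.
#' @param spacing length-3 voxel spacing, metres.
#' @param connectivity 6 (default), 18 or 26.
#' @param threshold_factor multiple of the noise mean (default 1.25).
#' @param seed_point optional length-3 voxel index; selects the connected
#'   component containing it instead of the largest.
#' @return An object of class `artifact_segmentation`: `mask`,
#'   `extent_mm` (per-axis maximum run length x spacing, mm),
#'   `volume_mm3`, `threshold_used`, `spacing`. An empty candidate set
#'   yields an empty mask with volume 0 (a valid result, messaged).
#' @export
segment_signal_void <- function(image, noise_region, phantom_mask, spacing,
                                connectivity = 6L, threshold_factor = 1.25,
                                seed_point = NULL) {
  stopifnot(is.array(image), length(dim(image)) == 3,
            length(spacing) == 3, all(spacing > 0))
  if (!any(noise_region)) stop("noise region is empty")
  if (!any(phantom_mask)) stop("phantom mask is empty")
  threshold <- threshold_factor * mean(image[noise_region])
  candidates <- (image < threshold) & phantom_mask
  empty <- structure(list(
    mask = array(FALSE, dim(image)), extent_mm = c(0, 0, 0),
    volume_mm3 = 0, n_voxels = 0L, threshold_used = threshold,
    spacing = spacing), class = "artifact_segmentation")
  if (!any(candidates)) {
    message("no sub-threshold voxels inside the phantom; empty segmentation")
    return(empty)
  }
  lab <- label_components(candidates, connectivity)
  if (!is.null(seed_point)) {
    sel <- lab[seed_point[1], seed_point[2], seed_point[3]]
    if (sel == 0L) {
      message("seed point is not a candidate voxel; empty segmentation")
      return(empty)
    }
  } else {
    sel <- which.max(tabulate(lab[lab > 0L]))
  }
  mask <- lab == sel
  structure(list(
    mask = mask,
    extent_mm = artifact_extent(mask, spacing),
    volume_mm3 = sum(mask) * prod(spacing) * 1e9,
    n_voxels = sum(mask),
    threshold_used = threshold,
    spacing = spacing
  ), class = "artifact_segmentation")
}

#' @export
print.artifact_segmentation <- function(x, ...) {
  cat(sprintf(
    "<artifact_segmentation> %d voxels, %.1f mm^3, extent %.1f x %.1f x %.1f mm (threshold %.3g)\n",
    x$n_voxels, x$volume_mm3, x$extent_mm[1], x$extent_mm[2], x$extent_mm[3],
    x$threshold_used))
  invisible(x)
}

#' Per-axis extent of a voxel mask
#'
#' For each imaging axis, the extent is the maximum number of mask voxels
#' on any line parallel to that axis, multiplied by the sample spacing —
#' the longest run count per line, not the bounding-box width (a
#' C-shaped mask reports the arm length, not the outer span). Set
#' `mode = "bounding_box"` for the bounding-box reading.
#'
#' @param mask logical 3D array.
#' @param spacing length-3 voxel spacing, metres.
#' @param mode `"line_count"` (default) or `"bounding_box"`.
#' @return Numeric length-3 vector of extents in millimetres; zeros for
#'   an empty mask.
#' @export
artifact_extent <- function(mask, spacing, mode = c("line_count", "bounding_box")) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, length(spacing) == 3)
  mode <- match.arg(mode)
  if (!any(mask)) return(c(0, 0, 0))
  if (mode == "bounding_box") {
    co <- which(mask, arr.ind = TRUE)
    return(vapply(1:3, function(a)
      (max(co[, a]) - min(co[, a]) + 1L) * spacing[a], numeric(1)) * 1e3)
  }
  counts <- vapply(1:3, function(a) max(apply(mask, setdiff(1:3, a), sum)),
                   numeric(1))
  counts * spacing * 1e3
}

#' Tidy an artifact segmentation into a one-row tibble
#'
#' @param x an `artifact_segmentation`.
#' @param ... unused.
#' @return A tibble with extents (mm), volume (mm^3), voxel count and the
#'   threshold used.
#' @export
tidy.artifact_segmentation <- function(x, ...) {
  tibble::tibble(
    extent_x_mm = x$extent_mm[1],
    extent_y_mm = x$extent_mm[2],
    extent_z_mm = x$extent_mm[3],
    volume_mm3 = x$volume_mm3,
    n_voxels = x$n_voxels,
    threshold = x$threshold_used
  )
}
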