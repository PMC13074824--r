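#' Simulate a serial gross-pathology slice stack
#'
#' Emulates serial slicing of an ablated (ellipsoidal) region at
#' approximately constant thickness: slice thicknesses are drawn around
#' `slice_thickness_mean` (default 1.5 mm, a deli-slicer setting), each
#' slice's ablated-region mask is the ellipsoid cross-section at the
#' mid-depth of its slab rasterized at `pixel_scale`, and per-slice area
#' noise emulates annotation spread by jittering the cross-section size.
#' The true ellipsoid volume `4/3 pi a b c` is returned as ground truth.
#'
#' Lengths are in millimetres throughout this module (the working units
#' of bench pathology); areas in cm^2 and volumes in cm^3.
#'
#' @param semi_axes length-3 ellipsoid semi-axes (a, b, c), mm; c is
#'   along the slicing direction.
#' @param slice_thickness_mean mean slice thickness, mm (default 1.5).
#' @param slice_thickness_sd per-slice thickness spread, mm (default 0.1,
#'   a caliper repeat-measurement scale).
#' @param pixel_scale photograph scale, mm per pixel (default 0.1).
#' @param area_noise_fraction fractional per-slice area jitter (default
#'   0.05, an annotation-spread scale).
#' @param n_slices number of slices; default covers the ellipsoid plus one
#'   spare slice each side.
#' @param center_depth depth of the ellipsoid centre below the first cut,
#'   mm; default centres it in the sliced block.
#' @param seed integer seed; stacks are reproducible for a fixed seed.
#' @return An object of class `slice_stack`: a tibble `slices` (slice id,
#'   thickness_mm, thickness_sd_mm, area_sd_cm2, mask list-column),
#'   `pixel_scale_mm`, and ground truth `true_volume_cm3`.
#' @export
simulate_slice_stack <- function(semi_axes = c(6, 5, 7),
                                 slice_thickness_mean = 1.5,
                                 slice_thickness_sd = 0.1,
                                 pixel_scale = 0.1,
                                 area_noise_fraction = 0.05,
                                 n_slices = NULL,
                                 center_depth = NULL,
                                 seed = 1L) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            slice_thickness_mean > 0, pixel_scale > 0,
            area_noise_fraction >= 0)
  if (slice_thickness_sd < 0) stop("thickness sd must be nonnegative")
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  if (is.null(n_slices))
    n_slices <- ceiling(2 * cc / slice_thickness_mean) + 2L
  if (is.null(center_depth))
    center_depth <- n_slices * slice_thickness_mean / 2

  set.seed(as.integer(seed))
  thick <- if (slice_thickness_sd > 0)
    pmax(0.1 * slice_thickness_mean,
         stats::rnorm(n_slices, slice_thickness_mean, slice_thickness_sd))
  else rep(slice_thickness_mean, n_slices)
  bounds <- c(0, cumsum(thick))
  mid <- (bounds[-1] + bounds[-length(bounds)]) / 2

  # raster window sized to the ellipsoid footprint plus margin
  half_px <- ceiling((c(a, b) * 1.2 + 2) / pixel_scale)
  px <- (seq_len(2 * half_px[1] + 1) - half_px[1] - 1) * pixel_scale
  py <- (seq_len(2 * half_px[2] + 1) - half_px[2] - 1) * pixel_scale

  area_jitter <- if (area_noise_fraction > 0)
    stats::rnorm(n_slices, 0, area_noise_fraction) else rep(0, n_slices)

  masks <- vector("list", n_slices)
  area_sd <- numeric(n_slices)
  for (i in seq_len(n_slices)) {
    dz <- mid[i] - center_depth
    if (abs(dz) < cc) {
      shrink <- sqrt(1 - (dz / cc)^2)
      # area noise scales the section linearly in area: semi-axes by sqrt
      s <- shrink * sqrt(pmax(0, 1 + area_jitter[i]))
      ai <- a * s; bi <- b * s
      masks[[i]] <- outer(px^2 / ai^2, py^2 / bi^2, `+`) <= 1
      area_sd[i] <- area_noise_fraction * pi * (a * shrink) * (b * shrink) / 100
    } else {
      masks[[i]] <- matrix(FALSE, length(px), length(py))
      area_sd[i] <- 0
    }
  }

  structure(list(
    slices = tibble::tibble(
      slice = seq_len(n_slices),
      thickness_mm = thick,
      thickness_sd_mm = slice_thickness_sd,
      area_sd_cm2 = area_sd,
      mask = masks
    ),
    pixel_scale_mm = pixel_scale,
    true_volume_cm3 = 4 / 3 * pi * a * b * cc / 1000,
    semi_axes_mm = semi_axes,
    seed = as.integer(seed)
  ), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf(
    "<slice_stack> %d slices @ %.2f mm/px; true volume %.3f cm^3\n",
    nrow(x$slices), x$pixel_scale_mm, x$true_volume_cm3))
  invisible(x)
}

#' Ablated area of one slice mask
#'
#' Area of a binary annotation mask: pixel count times squared pixel
#' scale, reported in cm^2.
#'
#' @param mask logical (or 0/1) matrix.
#' @param pixel_scale mm per pixel.
#' @return Area in cm^2.
#' @export
slice_area <- function(mask, pixel_scale) {
  stopifnot(pixel_scale > 0)
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
    mask <- mask > 0
  }
  stopifnot(is.logical(mask))
  sum(mask) * pixel_scale^2 / 100
}

# Annotation-uncertainty heuristic: boundary pixels (mask pixels with a
# 4-neighbour outside the mask or on the image edge) x pixel area / sqrt(12)
# -- uncertainty concentrates in a one-pixel band at the boundary.
boundary_area_sd <- function(mask, pixel_scale) {
  if (!any(mask)) return(0)
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  core <- pad[2:(n + 1), 2:(m + 1)]
  nb <- pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)] &
    pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)]
  n_boundary <- sum(core & !nb)
  n_boundary * pixel_scale^2 / 100 / sqrt(12)
}

#' Ablated volume with combined standard uncertainty
#'
#' Estimates the ablated volume of a serial slice stack as
#' `V = sum_i A_i * t_i` (slice area x thickness) and propagates the
#' per-component uncertainties to first order assuming independence:
#' `u(V)^2 = sum_i ( t_i^2 u(A_i)^2 + A_i^2 u(t_i)^2 )` — the GUM
#' combined standard uncertainty. Slices with zero ablated area
#' contribute nothing to either sum. When a slice carries no repeat-based
#' area uncertainty, a boundary-pixel heuristic is used:
#' `u(A) = n_boundary * pixel_area / sqrt(12)`.
#'
#' @param stack a `slice_stack` (from [simulate_slice_stack()] or
#'   [read_slice_stack()]).
#' @return An object of class `volume_estimate` with `volume_cm3` and
#'   `uncertainty_cm3`; see [tidy.volume_estimate()].
#' @export
ablated_volume <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  sl <- stack$slices
  if (nrow(sl) < 1) stop("slice stack is empty")
  ps <- stack$pixel_scale_mm
  A <- vapply(sl$mask, slice_area, numeric(1), pixel_scale = ps)   # cm^2
  nonzero <- A > 0
  if (any(nonzero & (is.na(sl$thickness_mm) | sl$thickness_mm <= 0)))
    stop("missing thickness for a slice with nonzero ablated area")
  uA <- sl$area_sd_cm2
  if (is.null(uA)) uA <- rep(NA_real_, nrow(sl))
  fallback <- is.na(uA)
  if (any(fallback & nonzero))
    uA[fallback] <- vapply(sl$mask[fallback], boundary_area_sd, numeric(1),
                           pixel_scale = ps)
  uA[!nonzero] <- 0
  ut <- sl$thickness_sd_mm
  t_cm <- sl$thickness_mm / 10
  ut_cm <- ut / 10

  V <- sum(A[nonzero] * t_cm[nonzero])
  u2 <- sum(t_cm[nonzero]^2 * uA[nonzero]^2 + A[nonzero]^2 * ut_cm[nonzero]^2)
  structure(list(
    volume_cm3 = V,
    uncertainty_cm3 = sqrt(u2),
    n_slices = nrow(sl),
    n_ablated_slices = sum(nonzero),
    areas_cm2 = A
  ), class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("<volume_estimate> %.3f +/- %.3f cm^3 (%d of %d slices ablated)\n",
              x$volume_cm3, x$uncertainty_cm3, x$n_ablated_slices, x$n_slices))
  invisible(x)
}

#' Tidy / summarize a gross-pathology volume estimate
#'
#' `tidy()` returns the estimate as a one-row tibble; `glance()` is an
#' alias carrying the slice counts.
#'
#' @param x a `volume_estimate`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.volume_estimate <- function(x, ...) {
  tibble::tibble(volume_cm3 = x$volume_cm3,
                 uncertainty_cm3 = x$uncertainty_cm3)
}

#' @rdname tidy.volume_estimate
#' @export
glance.volume_estimate <- function(x, ...) {
  tibble::tibble(volume_cm3 = x$volume_cm3,
                 uncertainty_cm3 = x$uncertainty_cm3,
                 n_slices = x$n_slices,
                 n_ablated_slices = x$n_ablated_slices)
}

#' @export
autoplot.slice_stack <- function(object, ...) {
  sl <- object$slices
  df <- tibble::tibble(
    slice = sl$slice,
    depth_mm = cumsum(sl$thickness_mm) - sl$thickness_mm / 2,
    area_cm2 = vapply(sl$mask, slice_area, numeric(1),
                      pixel_scale = object$pixel_scale_mm)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_mm, y = .data$area_cm2)) +
    ggplot2::geom_col(width = min(sl$thickness_mm) * 0.9, fill = "firebrick") +
    ggplot2::labs(x = "depth below first cut (mm)", y = "ablated area (cm²)",
                  title = "Serial-slice ablated area profile")
}
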