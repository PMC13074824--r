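# 3D connected-component labelling by breadth-first frontier expansion.
# Pure R, vectorized over the frontier; adequate for the supra-threshold
# sets this package meets (10^3..10^5 voxels).
neighbor_steps <- function(connectivity) {
  st <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  st <- st[!(st$dx == 0 & st$dy == 0 & st$dz == 0), ]
  r <- abs(st$dx) + abs(st$dy) + abs(st$dz)
  switch(as.character(connectivity),
         "6" = st[r == 1, ],
         "18" = st[r <= 2, ],
         "26" = st,
         stop("connectivity must be 6, 18 or 26"))
}

label_components <- function(mask, connectivity = 6L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, is.logical(mask))
  d <- dim(mask); n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  lab <- array(0L, d)
  seeds <- which(mask)
  if (!length(seeds)) return(lab)
  st <- neighbor_steps(connectivity)
  unvisited <- mask
  cur <- 0L
  for (seed in seeds) {
    if (!unvisited[seed]) next
    cur <- cur + 1L
    unvisited[seed] <- FALSE
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      i0 <- frontier - 1L
      cx <- i0 %% n1
      cy <- (i0 %/% n1) %% n2
      cz <- i0 %/% (n1 * n2)
      nxt <- integer(0)
      for (s in seq_len(nrow(st))) {
        px <- cx + st$dx[s]; py <- cy + st$dy[s]; pz <- cz + st$dz[s]
        ok <- px >= 0L & px < n1 & py >= 0L & py < n2 & pz >= 0L & pz < n3
        if (!any(ok)) next
        lin <- px[ok] + n1 * (py[ok] + n2 * pz[ok]) + 1L
        lin <- lin[unvisited[lin]]
        if (length(lin)) {
          lin <- unique(lin)
          unvisited[lin] <- FALSE
          lab[lin] <- cur
          nxt <- c(nxt, lin)
        }
      }
      frontier <- nxt
    }
  }
  lab
}

#' Largest contiguous supra-threshold region of a 3D field
#'
#' Thresholds a scalar 3D field and returns the connected component
#' (6-, 18- or 26-connected) with the most voxels, together with its
#' volume. This is the shared contiguity rule of the pipeline: the
#' half-maximum focal spot of a pressure volume and the 240 CEM43
#' ablation volume of a dose map are both "the largest contiguous volume"
#' above their thresholds.
#'
#' @param field numeric 3D array.
#' @param threshold scalar threshold.
#' @param spacing length-3 voxel spacing in metres (defines voxel volume).
#' @param connectivity 6 (face, default), 18 or 26.
#' @param inclusive if `FALSE` (default) voxels qualify when strictly
#'   above the threshold ("greater than"); if `TRUE` when at or above it
#'   ("at least").
#' @return A list with `mask` (logical array, one component or empty),
#'   `volume` (m^3, voxel count times voxel volume) and `n_voxels`.
#'   An empty result (nothing above threshold) is valid and returns
#'   volume 0.
#' @export
largest_contiguous_region <- function(field, threshold, spacing,
                                      connectivity = 6L, inclusive = FALSE) {
  stopifnot(is.array(field), length(dim(field)) == 3, is.finite(threshold),
            length(spacing) == 3, all(spacing > 0))
  above <- if (inclusive) field >= threshold else field > threshold
  above[is.na(above)] <- FALSE
  vox <- prod(spacing)
  if (!any(above))
    return(list(mask = above, volume = 0, n_voxels = 0L))
  lab <- label_components(above, connectivity)
  counts <- tabulate(lab[lab > 0L])
  best <- which.max(counts)
  mask <- lab == best
  list(mask = mask, volume = counts[best] * vox, n_voxels = counts[best])
}

# raster-order argmax (column-major; first occurrence breaks ties),
# optionally refined per axis by a 3-point parabola through log-safe values
peak_position <- function(mag, grid, refine = FALSE) {
  i <- which.max(mag)
  d <- dim(mag)
  co <- arrayInd(i, d)
  pos <- c(grid$x[co[1]], grid$y[co[2]], grid$z[co[3]])
  if (refine) {
    sp <- c(grid$dx, grid$dy, grid$dz)
    for (a in 1:3) {
      if (co[a] > 1 && co[a] < d[a]) {
        im <- co; ip <- co
        im[a] <- co[a] - 1L; ip[a] <- co[a] + 1L
        y0 <- mag[im]; y1 <- mag[co]; y2 <- mag[ip]
        den <- y0 - 2 * y1 + y2
        if (den < 0) pos[a] <- pos[a] + 0.5 * (y0 - y2) / den * sp[a]
      }
    }
  }
  pos
}

#' Focal-spot metrics of a test field against its control
#'
#' Characterizes how an obstruction changes the focus by comparing a test
#' pressure volume against a control volume on the same grid:
#' * `peak_change` — fractional change of the spatial peak magnitude,
#'   `peak(test)/peak(control) - 1`.
#' * `focus_volume` — the largest contiguous region with amplitude above
#'   half that volume's own maximum (each volume uses its own half-maximum
#'   threshold), in m^3; `focus_volume_change` is the fractional change.
#' * `displacement_vector` — position of the test peak minus position of
#'   the control peak (voxel argmax, raster-order ties; optional 3-point
#'   parabolic sub-voxel refinement), metres.
#' * `insertion_loss_db` — `-20 log10(peak(test)/peak(control))`; by
#'   default peaks over the volume, or over the central (z = 0) plane
#'   with `insertion_loss_mode = "plane"`.
#'
#' @param test,control [pressure_volume()] objects on identical grids;
#'   the control must be nonzero.
#' @param connectivity contiguity neighbourhood for the focus volume
#'   (default 6).
#' @param refine_peak logical; sub-voxel parabolic refinement of the peak
#'   positions (default `FALSE`).
#' @param insertion_loss_mode `"volume"` (default) or `"plane"`.
#' @return An object of class `focus_metrics`; see [tidy.focus_metrics()].
#' @export
focus_metrics <- function(test, control, connectivity = 6L,
                          refine_peak = FALSE,
                          insertion_loss_mode = c("volume", "plane")) {
  stopifnot(inherits(test, "pressure_volume"),
            inherits(control, "pressure_volume"))
  insertion_loss_mode <- match.arg(insertion_loss_mode)
  if (!identical(dim(test$field), dim(control$field)) ||
      !same_grid(test$grid, control$grid))
    stop("test and control volumes are on different grids")
  mt <- volume_magnitude(test)
  mc <- volume_magnitude(control)
  if (max(mc) == 0) stop("control volume is identically zero")
  if (max(mt) == 0) stop("test volume is identically zero")

  sp <- c(test$grid$dx, test$grid$dy, test$grid$dz)
  pk_t <- max(mt); pk_c <- max(mc)
  fv_t <- largest_contiguous_region(mt, pk_t / 2, sp, connectivity)
  fv_c <- largest_contiguous_region(mc, pk_c / 2, sp, connectivity)
  pos_t <- peak_position(mt, test$grid, refine_peak)
  pos_c <- peak_position(mc, control$grid, refine_peak)
  disp <- pos_t - pos_c

  ratio <- if (insertion_loss_mode == "plane") {
    iz <- which.min(abs(test$grid$z))
    max(mt[, , iz]) / max(mc[, , iz])
  } else pk_t / pk_c

  structure(list(
    peak_test = pk_t,
    peak_control = pk_c,
    peak_change = pk_t / pk_c - 1,
    focus_volume = fv_t$volume,
    focus_volume_control = fv_c$volume,
    focus_volume_change = fv_t$volume / fv_c$volume - 1,
    displacement_vector = disp,
    displacement_total = sqrt(sum(disp^2)),
    insertion_loss_db = -20 * log10(ratio),
    insertion_loss_mode = insertion_loss_mode,
    focus_mask = fv_t$mask
  ), class = "focus_metrics")
}

#' @export
print.focus_metrics <- function(x, ...) {
  cat("<focus_metrics>\n")
  cat(sprintf("  peak change        %+.1f %%\n", x$peak_change * 100))
  cat(sprintf("  focus volume       %.2f mm^3 (%+.1f %% vs control)\n",
              x$focus_volume * 1e9, x$focus_volume_change * 100))
  cat(sprintf("  displacement       %.2f mm (%.2f, %.2f, %.2f)\n",
              x$displacement_total * 1e3, x$displacement_vector[1] * 1e3,
              x$displacement_vector[2] * 1e3, x$displacement_vector[3] * 1e3))
  cat(sprintf("  insertion loss     %.2f dB [%s]\n",
              x$insertion_loss_db, x$insertion_loss_mode))
  invisible(x)
}

#' Tidy focal-spot metrics into a one-row tibble
#'
#' @param x a [focus_metrics()] result.
#' @param ... unused.
#' @return A tibble with one row: fractional changes, volumes in mm^3,
#'   displacements in mm, insertion loss in dB.
#' @export
tidy.focus_metrics <- function(x, ...) {
  tibble::tibble(
    peak_test = x$peak_test,
    peak_control = x$peak_control,
    peak_change = x$peak_change,
    focus_volume_mm3 = x$focus_volume * 1e9,
    focus_volume_control_mm3 = x$focus_volume_control * 1e9,
    focus_volume_change = x$focus_volume_change,
    disp_x_mm = x$displacement_vector[1] * 1e3,
    disp_y_mm = x$displacement_vector[2] * 1e3,
    disp_z_mm = x$displacement_vector[3] * 1e3,
    displacement_mm = x$displacement_total * 1e3,
    insertion_loss_db = x$insertion_loss_db
  )
}
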