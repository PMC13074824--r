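#' Phase change of an MR series against a complex baseline
#'
#' For each frame, computes the principal-value phase difference against
#' the complex average of the baseline frames:
#' `Arg(frame * Conj(mean(baseline)))`, per voxel, in (-pi, pi].
#' Complex averaging of the baseline is the standard PRF practice — it
#' weights by magnitude and avoids phase-wrap averaging artifacts.
#'
#' Changes beyond pi alias back into the principal interval (an injected
#' `pi + 0.1` is recovered as `-(pi - 0.1)`); the expected per-frame
#' change at the study's 2.16 s dynamic time is far below pi, so no
#' temporal unwrapping is applied. A warning is issued when any voxel's
#' frame-to-frame phase step within the validity of the data exceeds
#' pi/2, the symptom of unwrap-risk heating rates.
#'
#' @param series an MRTI series ([simulate_mrti_series()]) (or a list of complex 3D frames).
#' @param baseline_frames integer indices of the baseline frames
#'   (default 1).
#' @return List of numeric 3D arrays, one per frame, radians.
#' @export
phase_change <- function(series, baseline_frames = 1L) {
  frames <- if (inherits(series, "mrti_series")) series$frames else series
  stopifnot(is.list(frames), length(frames) >= 1)
  if (length(baseline_frames) == 0) stop("baseline frame set is empty")
  if (any(baseline_frames < 1 | baseline_frames > length(frames)))
    stop("baseline frame indices out of range")
  base <- Reduce(`+`, frames[baseline_frames]) / length(baseline_frames)
  dphi <- lapply(frames, function(f) Arg(f * Conj(base)))
  steps <- vapply(seq_along(dphi)[-1], function(i) {
    max(abs(dphi[[i]] - dphi[[i - 1]]), na.rm = TRUE)
  }, numeric(1))
  if (length(steps) && any(steps > pi / 2))
    warning("frame-to-frame phase step exceeds pi/2; ",
            "temperature changes may be at phase-wrap risk")
  dphi
}

#' Convert PRF phase changes to a temperature series
#'
#' Applies the proton-resonance-frequency shift relation
#' `dT = dphi / (2 pi gamma alpha B0 TE)` voxelwise (alpha in ppm/degC,
#' so heating lowers phase for the default alpha = -0.01), yielding one
#' temperature-rise map per frame plus the absolute baseline temperature.
#'
#' @param phase_maps list of phase-difference arrays (radians), as from
#'   [phase_change()].
#' @param seq a [sequence_constants()]; `alpha` must be nonzero.
#' @param baseline_temperature absolute starting temperature, degC.
#' @param grid a [grid3d()] voxel geometry.
#' @param mask optional validity mask (from [snr_mask()]); masked-out
#'   voxels carry `NA` temperature.
#' @return An object of class `temperature_series`: per-frame `delta_T`
#'   arrays (degC), `baseline_temperature`, `mask`, `grid`,
#'   `frame_interval`.
#' @export
prf_temperature <- function(phase_maps, seq = sequence_constants(),
                            baseline_temperature = 20,
                            grid = NULL, mask = NULL) {
  stopifnot(inherits(seq, "sequence_constants"), is.list(phase_maps))
  if (seq$alpha == 0) stop("PRF coefficient alpha must be nonzero")
  coef <- prf_phase_per_degC(seq)
  delta_T <- lapply(phase_maps, function(p) {
    dT <- p / coef
    if (!is.null(mask)) dT[!mask] <- NA_real_
    dT
  })
  structure(list(
    delta_T = delta_T,
    baseline_temperature = baseline_temperature,
    mask = mask, grid = grid,
    frame_interval = seq$frame_interval
  ), class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  pk <- max(vapply(x$delta_T, function(m) max(m, -Inf, na.rm = TRUE),
                   numeric(1)))
  cat(sprintf(
    "<temperature_series> %d frames, baseline %.1f degC, peak rise %.2f degC\n",
    length(x$delta_T), x$baseline_temperature, pk))
  invisible(x)
}

#' SNR validity mask for an MR image series
#'
#' Estimates the per-channel noise standard deviation from the real and
#' imaginary parts of a signal-free region and keeps the voxels whose
#' time-mean magnitude strictly exceeds `k` times that estimate. Applied
#' before any thermometry evaluation so that noise-only voxels never
#' enter temperature or dose statistics.
#'
#' @param series an MRTI series ([simulate_mrti_series()]) or list of complex 3D frames.
#' @param k threshold multiple (default 5).
#' @param noise_region logical array marking the estimation region: with
#'   `method = "spatial"` it must be signal-free; with `"temporal"` any
#'   static region works.
#' @param method `"spatial"` (default): sigma is the sd of the real and
#'   imaginary samples in `noise_region`. `"temporal"`: sigma is
#'   estimated from frame-to-frame complex differences in `noise_region`
#'   (static signal cancels), for data without a signal-free region;
#'   needs at least two frames.
#' @return Logical array: `TRUE` where the voxel is valid. A voxel at
#'   exactly `k * sigma` is excluded (strict inequality).
#' @export
snr_mask <- function(series, k = 5, noise_region,
                     method = c("spatial", "temporal")) {
  frames <- if (inherits(series, "mrti_series")) series$frames else series
  method <- match.arg(method)
  stopifnot(is.list(frames), length(frames) >= 1, k > 0)
  if (!any(noise_region)) stop("noise region is empty")
  if (method == "spatial") {
    vals <- unlist(lapply(frames, function(f)
      c(Re(f[noise_region]), Im(f[noise_region]))))
  } else {
    if (length(frames) < 2)
      stop("temporal noise estimation needs at least two frames")
    vals <- unlist(lapply(seq_along(frames)[-1], function(i) {
      d <- (frames[[i]] - frames[[i - 1]])[noise_region] / sqrt(2)
      c(Re(d), Im(d))
    }))
  }
  sigma <- stats::sd(vals)
  if (sigma == 0) stop("noise region has zero variance; not a noise region")
  mean_mag <- Reduce(`+`, lapply(frames, Mod)) / length(frames)
  mean_mag > k * sigma
}

#' Accumulate CEM43 thermal dose
#'
#' Cumulative equivalent minutes at 43 degC:
#' `CEM43 = sum_t R^(43 - T_t) * dt_min`, with `R = 0.5` for
#' `T >= 43` degC and `R = 0.25` below, integrated rectangularly at the
#' frame interval. Absolute temperature is `baseline + delta_T`. The dose
#' is additive over sonications: pass a `prior` dose map to continue
#' accumulation across concatenated series.
#'
#' @param temps a temperature series ([prf_temperature()]).
#' @param prior optional dose map from an earlier sonication (class
#'   `dose_map`) on the same grid.
#' @param frames which frames to accumulate (default all).
#' @return An object of class `dose_map`: `dose` (3D array of minutes;
#'   `NA` at masked-out voxels), `grid`, `mask`.
#' @export
cem43 <- function(temps, prior = NULL, frames = seq_along(temps$delta_T)) {
  stopifnot(inherits(temps, "temperature_series"))
  dt_min <- temps$frame_interval / 60
  mask <- temps$mask
  dose <- if (is.null(prior)) NULL else {
    stopifnot(inherits(prior, "dose_map"))
    prior$dose
  }
  for (i in frames) {
    T_abs <- temps$baseline_temperature + temps$delta_T[[i]]
    bad <- is.na(T_abs)
    if (!is.null(mask) && any(bad & mask))
      stop("NaN temperature at unmasked voxels in frame ", i)
    if (is.null(mask) && any(bad))
      stop("NaN temperature with no validity mask in frame ", i)
    R <- ifelse(T_abs >= 43, 0.5, 0.25)
    inc <- R^(43 - T_abs) * dt_min
    dose <- if (is.null(dose)) inc else dose + inc
  }
  structure(list(dose = dose, grid = temps$grid, mask = mask),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> peak %.3g CEM43 over %s voxels\n",
              max(x$dose, na.rm = TRUE),
              format(length(x$dose), big.mark = ",")))
  invisible(x)
}

#' Ablation volume from a thermal-dose map
#'
#' The largest contiguous volume with a thermal dose of at least
#' `threshold` CEM43 (inclusive), the standard ablation criterion at the
#' default 240 CEM43. Contiguity uses the shared
#' [largest_contiguous_region()] rule; masked-out (`NA`) voxels never
#' qualify.
#'
#' @param dose a `dose_map` from [cem43()].
#' @param threshold dose threshold in minutes (default 240).
#' @param connectivity 6 (default), 18 or 26.
#' @return A list: `mask`, `volume_cm3`, `n_voxels`.
#' @export
dose_volume <- function(dose, threshold = 240, connectivity = 6L) {
  stopifnot(inherits(dose, "dose_map"))
  sp <- c(dose$grid$dx, dose$grid$dy, dose$grid$dz)
  reg <- largest_contiguous_region(dose$dose, threshold, sp,
                                   connectivity, inclusive = TRUE)
  list(mask = reg$mask, volume_cm3 = reg$volume * 1e6, n_voxels = reg$n_voxels)
}

#' Treatment-volume proxy from temperature rise
#'
#' Total volume of all voxels inside the region of interest whose
#' temperature rise exceeds `delta_threshold` (strictly, "greater
#' than") — by default the maximum rise over time against a 10 degC
#' threshold. Unlike [dose_volume()], this volume is deliberately
#' permitted to be noncontiguous: every qualifying voxel counts.
#'
#' @param temps a temperature series ([prf_temperature()]).
#' @param delta_threshold temperature-rise threshold, degC (default 10).
#' @param roi logical array restricting the count (e.g. the phantom
#'   mask); required.
#' @param statistic `"max"` (default; maximum rise over frames) or
#'   `"per_frame"` (a volume per frame).
#' @return Volume in cm^3 (`statistic = "max"`), or a numeric vector of
#'   per-frame volumes.
#' @export
hot_volume <- function(temps, delta_threshold = 10, roi,
                       statistic = c("max", "per_frame")) {
  stopifnot(inherits(temps, "temperature_series"), !missing(roi))
  statistic <- match.arg(statistic)
  vox_cm3 <- voxel_volume(temps$grid) * 1e6
  qualify <- function(dT) {
    q <- dT > delta_threshold & roi
    if (!is.null(temps$mask)) q <- q & temps$mask
    q[is.na(q)] <- FALSE
    q
  }
  if (statistic == "per_frame")
    return(vapply(temps$delta_T, function(dT) sum(qualify(dT)) * vox_cm3,
                  numeric(1)))
  peak <- Reduce(pmax, temps$delta_T)
  sum(qualify(peak)) * vox_cm3
}
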