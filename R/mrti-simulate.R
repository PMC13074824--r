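#' MR sequence constants for PRF thermometry
#'
#' The constants that convert a phase difference to a temperature change:
#' echo time TE, main field B0, gyromagnetic ratio gamma and the PRF
#' thermal coefficient alpha. Defaults match the study's 3 T scanner and
#' segmented-EPI thermometry readout (TE = 12 ms, 2.16 s per dynamic) with
#' the standard water PRF coefficient alpha = -0.01 ppm/degC. With this
#' (negative-alpha) convention heating lowers the phase; set
#' `phase_sign = -1` for scanners with the opposite phase convention.
#'
#' @param TE echo time, seconds.
#' @param B0 main magnetic field, tesla.
#' @param gamma gyromagnetic ratio, Hz/T.
#' @param alpha PRF thermal coefficient, ppm per degC (signed).
#' @param frame_interval time per dynamic, seconds.
#' @param phase_sign +1 (default) or -1; multiplies the phase-to-
#'   temperature conversion.
#' @return An object of class `sequence_constants`.
#' @export
sequence_constants <- function(TE = 12e-3, B0 = 3, gamma = 42.577e6,
                               alpha = -0.01, frame_interval = 2.16,
                               phase_sign = 1) {
  stopifnot(TE > 0, B0 > 0, gamma > 0, frame_interval > 0,
            phase_sign %in% c(-1, 1))
  structure(list(TE = TE, B0 = B0, gamma = gamma, alpha = alpha,
                 frame_interval = frame_interval, phase_sign = phase_sign),
            class = "sequence_constants")
}

# rad per degC: d(phase)/d(T) = 2 pi gamma alpha B0 TE  (alpha in ppm)
prf_phase_per_degC <- function(seq) {
  2 * pi * seq$gamma * (seq$alpha * 1e-6) * seq$B0 * seq$TE * seq$phase_sign
}

#' Gaussian heat deposit with diffusive evolution
#'
#' An instantaneous anisotropic Gaussian temperature deposit that then
#' spreads by heat diffusion. At time t after the deposit the exact
#' kernel-convolution solution is
#' `dT(r,t) = peak * prod_a sqrt(sigma_a^2/(sigma_a^2 + 2 D t)) *
#'  exp(-sum_a r_a^2 / (2 (sigma_a^2 + 2 D t)))`,
#' which conserves the spatially integrated heat. The default diffusivity
#' is the gelatin phantom value 0.143 mm^2/s.
#'
#' @param peak_delta_T peak temperature rise at deposit time, degC.
#' @param gaussian_sigma length-3 standard deviations of the deposit, m.
#' @param deposit_time time of the deposit relative to the first frame, s.
#' @param thermal_diffusivity m^2/s (default 0.143e-6).
#' @param center length-3 deposit centre, m (grid-centred coordinates).
#' @return An object of class `heating_model`.
#' @export
heating_model <- function(peak_delta_T = 15,
                          gaussian_sigma = c(1e-3, 1e-3, 3e-3),
                          deposit_time = 0,
                          thermal_diffusivity = 0.143e-6,
                          center = c(0, 0, 0)) {
  if (length(gaussian_sigma) == 1) gaussian_sigma <- rep(gaussian_sigma, 3)
  stopifnot(peak_delta_T >= 0, all(gaussian_sigma > 0),
            thermal_diffusivity >= 0, length(center) == 3)
  structure(list(peak_delta_T = peak_delta_T,
                 gaussian_sigma = gaussian_sigma,
                 deposit_time = deposit_time,
                 thermal_diffusivity = thermal_diffusivity,
                 center = as.numeric(center)),
            class = "heating_model")
}

#' Evaluate the evolved temperature field of a heating model
#'
#' Closed-form temperature rise of a [heating_model()] on a [grid3d()] at
#' time `t` (seconds, same clock as `deposit_time`). Zero before the
#' deposit.
#'
#' @param heating a [heating_model()].
#' @param grid a [grid3d()].
#' @param t time, seconds.
#' @return Numeric 3D array of temperature rise, degC.
#' @export
heating_delta_T <- function(heating, grid, t) {
  stopifnot(inherits(heating, "heating_model"), inherits(grid, "fus_grid3d"))
  if (t < heating$deposit_time)
    return(array(0, dim = c(grid$nx, grid$ny, grid$nz)))
  tau <- t - heating$deposit_time
  s2 <- heating$gaussian_sigma^2 + 2 * heating$thermal_diffusivity * tau
  amp <- heating$peak_delta_T * prod(sqrt(heating$gaussian_sigma^2 / s2))
  ex <- function(v, c0, s) exp(-(v - c0)^2 / (2 * s))
  gx <- ex(grid$x, heating$center[1], s2[1])
  gy <- ex(grid$y, heating$center[2], s2[2])
  gz <- ex(grid$z, heating$center[3], s2[3])
  amp * outer(outer(gx, gy), gz)
}

#' Point-dipole susceptibility marker model
#'
#' Models the static field perturbation of a small metallic marker as a
#' far-field point dipole: the phase offset at displacement r from the
#' marker is `A * (3 cos^2(theta) - 1) / |r|^3`, with theta the angle from
#' the main-field (B0) axis and `A = dipole_moment_scale` (rad m^3) a
#' single amplitude constant. Signal magnitude is zeroed within
#' `void_radius` of the marker with a one-voxel smooth roll-off,
#' emulating the susceptibility signal void. If
#' `susceptibility_temp_coefficient` is nonzero, the dipole amplitude
#' scales with the marker-adjacent temperature rise as
#' `A * (1 + coefficient * dT_marker)`, emulating temperature-dependent
#' marker susceptibility.
#'
#' @param dipole_moment_scale phase-field amplitude, rad m^3.
#' @param position length-3 marker position, m.
#' @param b0_axis unit 3-vector of the main field direction (normalized
#'   internally).
#' @param void_radius signal-void radius, m.
#' @param susceptibility_temp_coefficient fractional change of the dipole
#'   amplitude per degC of marker-adjacent temperature rise.
#' @return An object of class `marker_field_model`.
#' @export
marker_field_model <- function(dipole_moment_scale = 1e-9,
                               position = c(0, 0, 0),
                               b0_axis = c(0, 0, 1),
                               void_radius = 3e-3,
                               susceptibility_temp_coefficient = 0) {
  stopifnot(void_radius >= 0, length(position) == 3, length(b0_axis) == 3)
  nb <- sqrt(sum(b0_axis^2))
  if (nb == 0) stop("b0_axis must be nonzero")
  structure(list(dipole_moment_scale = dipole_moment_scale,
                 position = as.numeric(position),
                 b0_axis = as.numeric(b0_axis) / nb,
                 void_radius = void_radius,
                 susceptibility_temp_coefficient = susceptibility_temp_coefficient),
            class = "marker_field_model")
}

# static dipole phase pattern and void attenuation on a grid
marker_phase_pattern <- function(marker, grid) {
  dx <- outer(grid$x - marker$position[1], rep(1, grid$ny))
  dy <- outer(rep(1, grid$nx), grid$y - marker$position[2])
  r2xy <- array(dx^2 + dy^2, c(grid$nx, grid$ny, grid$nz))
  dotxy <- array(dx * marker$b0_axis[1] + dy * marker$b0_axis[2],
                 c(grid$nx, grid$ny, grid$nz))
  dzv <- grid$z - marker$position[3]
  r2 <- r2xy + array(rep(dzv^2, each = grid$nx * grid$ny),
                     c(grid$nx, grid$ny, grid$nz))
  dot <- dotxy + array(rep(dzv * marker$b0_axis[3], each = grid$nx * grid$ny),
                       c(grid$nx, grid$ny, grid$nz))
  # clip |r| at half the smallest spacing to bound the on-site singularity
  rmin <- min(grid$dx, grid$dy, grid$dz) / 2
  r2 <- pmax(r2, rmin^2)
  cos2 <- dot^2 / r2
  phase <- marker$dipole_moment_scale * (3 * cos2 - 1) / r2^1.5
  r <- sqrt(r2)
  vox <- min(grid$dx, grid$dy, grid$dz)
  atten <- pmin(1, pmax(0, (r - marker$void_radius) / vox))
  list(phase = phase, atten = atten, r = r)
}

#' Simulate a complex MR thermometry image series
#'
#' Forward model for 3D PRF thermometry of a heated phantom with an
#' optional metallic-marker artifact. Each frame is a complex 3D image:
#' magnitude is a uniform phantom (with the marker's signal void carved
#' out), phase is the static dipole term plus the PRF term
#' `dphi = 2 pi gamma alpha B0 TE dT` from the diffusively evolved
#' temperature field. Complex circular Gaussian noise is added per
#' channel with standard deviation `mean(|signal|) / snr`. Ground-truth
#' temperature frames are returned alongside the images.
#'
#' Frames are acquired at times `(0, 1, ..., n_frames - 1) *
#' frame_interval`; a heating deposit at `deposit_time > 0` leaves
#' earlier frames as baselines.
#'
#' @param grid a [grid3d()] voxel geometry.
#' @param n_frames number of dynamics (>= 2).
#' @param heating optional [heating_model()].
#' @param marker optional [marker_field_model()].
#' @param snr signal-to-noise ratio (mean phantom magnitude over per-
#'   channel noise sd); `Inf` (default) for noiseless.
#' @param seq a [sequence_constants()]; its `frame_interval` sets the
#'   dynamic time.
#' @param baseline_temperature starting phantom temperature, degC
#'   (default 20, room temperature).
#' @param seed integer seed; output is reproducible for a fixed seed.
#' @return An object of class `mrti_series`: list of complex frames
#'   (`frames`), ground-truth temperature-rise frames (`truth_delta_T`),
#'   frame times, the grid, constants and baseline temperature.
#' @export
simulate_mrti_series <- function(grid, n_frames = 16,
                                 heating = NULL, marker = NULL,
                                 snr = Inf, seq = sequence_constants(),
                                 baseline_temperature = 20, seed = 1L) {
  stopifnot(inherits(grid, "fus_grid3d"), n_frames >= 2,
            inherits(seq, "sequence_constants"))
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive (or Inf)")
  if (!is.null(marker) &&
      marker$void_radius > max(abs(c(grid$x, grid$y, grid$z))))
    stop("marker void_radius exceeds the grid extent")

  times <- (seq_len(n_frames) - 1) * seq$frame_interval
  mag0 <- array(1, dim = c(grid$nx, grid$ny, grid$nz))
  static_phase <- array(0, dim = dim(mag0))
  mk <- NULL
  if (!is.null(marker)) {
    stopifnot(inherits(marker, "marker_field_model"))
    mk <- marker_phase_pattern(marker, grid)
    mag0 <- mag0 * mk$atten
    static_phase <- mk$phase
  }
  coef <- prf_phase_per_degC(seq)

  set.seed(as.integer(seed))
  frames <- truth <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    dT <- if (is.null(heating)) array(0, dim = dim(mag0)) else
      heating_delta_T(heating, grid, times[i])
    truth[[i]] <- dT
    ph <- static_phase + coef * dT
    if (!is.null(marker) && marker$susceptibility_temp_coefficient != 0) {
      # marker-adjacent temperature rescales the dipole amplitude
      dT_marker <- if (is.null(heating)) 0 else {
        ii <- c(which.min(abs(grid$x - marker$position[1])),
                which.min(abs(grid$y - marker$position[2])),
                which.min(abs(grid$z - marker$position[3])))
        dT[ii[1], ii[2], ii[3]]
      }
      ph <- mk$phase * (1 + marker$susceptibility_temp_coefficient * dT_marker) +
        coef * dT
    }
    img <- mag0 * exp(1i * ph)
    if (is.finite(snr)) {
      nsd <- mean(mag0) / snr
      img <- img + complex(real = stats::rnorm(length(img), 0, nsd),
                           imaginary = stats::rnorm(length(img), 0, nsd))
      img <- array(img, dim = dim(mag0))
    }
    frames[[i]] <- img
  }
  structure(list(
    frames = frames, truth_delta_T = truth, times = times, grid = grid,
    seq = seq, baseline_temperature = baseline_temperature,
    heating = heating, marker = marker, snr = snr, seed = as.integer(seed)
  ), class = "mrti_series")
}

#' @export
print.mrti_series <- function(x, ...) {
  cat(sprintf(
    "<mrti_series> %d frames of %d x %d x %d voxels, %.3g s/dynamic, SNR %s\n",
    length(x$frames), x$grid$nx, x$grid$ny, x$grid$nz,
    x$seq$frame_interval, ifelse(is.finite(x$snr), format(x$snr), "Inf")))
  invisible(x)
}
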