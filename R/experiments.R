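#' Configuration for a synthetic marker-vs-control experiment
#'
#' Bundles everything the end-to-end drivers need: the transducer, the
#' scan/reconstruction grids, the marker model, the sonication schedule
#' and explicit seeds. Lengths are given in millimetres here (the bench
#' working unit) and converted to SI at this boundary. Defaults mirror
#' the study design: a 1 MHz / 13 cm bowl scanned on 41 x 41, 0.5 mm
#' planes projected over a 2 x 2 x 4 cm volume; markers tested in the
#' focal plane and 7 mm far-field, centred and 3 mm lateral along each
#' transverse axis; two 21 s point sonications per condition at 2.16 s
#' per dynamic.
#'
#' @param kind `"acoustic"` or `"thermometry"`.
#' @param geom a [transducer_geometry()].
#' @param scan_n,scan_dx_mm hydrophone raster samples per axis and
#'   spacing (mm).
#' @param scan_z_mm axial position of the scan plane relative to the
#'   natural focus (mm). As on the bench — where the hydrophone scans
#'   just past the phantom and the volume is reconstructed by
#'   back-projection — it must lie downstream of every marker plane
#'   (default 12).
#' @param z_range_mm,z_step_mm reconstruction range (+/-) and axial step
#'   (mm).
#' @param marker_planes_mm axial marker-plane offsets to test (mm).
#' @param lateral_offsets_mm lateral marker displacements to test (mm);
#'   each is applied along x and along y.
#' @param screen_radius_mm,screen_transmission,screen_phase_shift marker
#'   screen model parameters.
#' @param pad_factor angular-spectrum padding.
#' @param noise_sd hydrophone noise per channel (pressure units).
#' @param mrti_grid a [grid3d()] for thermometry experiments.
#' @param n_frames,n_baseline frames per sonication and baseline count.
#' @param sonications number of point sonications.
#' @param peak_delta_T_per_W degC of peak deposit per acoustic watt — the
#'   power proxy (no acoustic-thermal coupling model is implied).
#' @param power_W,duration_s sonication power and duration; duration sets
#'   the deposit width in time via the frame schedule.
#' @param heating_sigma_mm deposit Gaussian sigmas (mm).
#' @param marker_model a [marker_field_model()] or `NULL`.
#' @param snr MR magnitude SNR.
#' @param seq a [sequence_constants()].
#' @param seed integer master seed (explicit; all stages derive from it).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(kind = c("acoustic", "thermometry"),
                              geom = transducer_geometry(),
                              scan_n = 41L, scan_dx_mm = 0.5,
                              scan_z_mm = 12,
                              z_range_mm = 20, z_step_mm = 0.5,
                              marker_planes_mm = c(0, 7),
                              lateral_offsets_mm = c(0, 3),
                              screen_radius_mm = 1.5,
                              screen_transmission = 0.3,
                              screen_phase_shift = 0,
                              pad_factor = 2L,
                              noise_sd = 0,
                              mrti_grid = grid3d(33, 33, 17, 1e-3, 1e-3, 3e-3),
                              n_frames = 16L, n_baseline = 2L,
                              sonications = 2L,
                              peak_delta_T_per_W = 0.625,
                              power_W = 24, duration_s = 21,
                              heating_sigma_mm = c(1, 1, 3),
                              marker_model = marker_field_model(),
                              snr = 50,
                              seq = sequence_constants(),
                              seed = 1L) {
  kind <- match.arg(kind)
  structure(as.list(environment()), class = "experiment_config")
}

config_positions <- function(config) {
  # the study's six positions: for each axial plane, centred plus each
  # nonzero lateral offset along x and along y
  lat <- setdiff(config$lateral_offsets_mm, 0)
  pos <- list()
  for (zp in config$marker_planes_mm) {
    pos <- c(pos, list(c(0, 0, zp)))
    for (l in lat) pos <- c(pos, list(c(l, 0, zp)), list(c(0, l, zp)))
  }
  pos
}

#' Run the acoustic marker-vs-control experiment
#'
#' For every marker position in the design, simulates a hydrophone scan
#' plane with the marker's occlusion screen in place, projects it (and
#' the shared no-marker control plane) through the reconstruction volume,
#' and tabulates the focal-spot metrics against the control. One row per
#' position; fully reproducible for a fixed config seed.
#'
#' @param config an [experiment_config()] of kind `"acoustic"`.
#' @param out_dir optional directory; when given, the metrics table is
#'   written as `acoustic_metrics.csv` alongside a reproducibility
#'   manifest.
#' @return A tibble: marker position (mm), [tidy.focus_metrics()]
#'   columns, and the volumetric RMSD against the control.
#' @export
run_acoustic_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"), config$kind == "acoustic")
  g <- grid2d(config$scan_n, config$scan_n, config$scan_dx_mm * 1e-3)
  scan_z <- config$scan_z_mm * 1e-3
  if (any(config$marker_planes_mm * 1e-3 > scan_z))
    stop("scan_z_mm must lie downstream of every marker plane")
  z_targets <- seq(-config$z_range_mm, config$z_range_mm,
                   by = config$z_step_mm) * 1e-3
  control_plane <- simulate_bowl_plane(config$geom, g, z_offset = scan_z,
                                       noise_sd = config$noise_sd,
                                       seed = config$seed,
                                       pad_factor = config$pad_factor)
  control_vol <- project_plane(control_plane, z_targets, config$pad_factor)

  noop_screen <- config$screen_radius_mm <= 0 ||
    (config$screen_transmission == 1 && config$screen_phase_shift == 0)
  rows <- list()
  positions <- config_positions(config)
  for (i in seq_along(positions)) {
    p <- positions[[i]]
    screen <- occlusion_screen(
      plane_offset = p[3] * 1e-3,
      center_offset = p[1:2] * 1e-3,
      radius = config$screen_radius_mm * 1e-3,
      amplitude_transmission = config$screen_transmission,
      phase_shift = config$screen_phase_shift)
    # a no-op marker (zero radius or full transparent transmission) IS
    # the control scan; reuse it so the no-marker design sits exactly at
    # the metrics' zero element
    marker_plane <- if (noop_screen) control_plane else
      simulate_bowl_plane(config$geom, g, z_offset = scan_z,
                          screen = screen,
                          noise_sd = config$noise_sd,
                          seed = config$seed + i,
                          pad_factor = config$pad_factor)
    marker_vol <- project_plane(marker_plane, z_targets, config$pad_factor)
    fm <- focus_metrics(marker_vol, control_vol)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(pos_x_mm = p[1], pos_y_mm = p[2], pos_z_mm = p[3]),
      tidy.focus_metrics(fm),
      tibble::tibble(rmsd_vs_control = rmsd_volumes(marker_vol, control_vol))
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_csv(out, file.path(out_dir, "acoustic_metrics.csv"))
    write_manifest(config, out_dir)
  }
  out
}

#' Run the thermometry marker-vs-control experiment
#'
#' Simulates the study's paired-arm design: for each point sonication,
#' an MR thermometry series is generated for the marker arm (dipole
#' phase, signal void, optional temperature-dependent susceptibility)
#' and for a control arm without the marker, sharing the heating and the
#' noise seed. Each series is processed with the full measurement chain
#' — SNR mask, baseline phase change, PRF conversion, CEM43 — and the
#' per-sonication summary statistics are tabulated.
#'
#' @param config an [experiment_config()] of kind `"thermometry"`.
#' @param out_dir optional output directory (CSV + manifest), as in
#'   [run_acoustic_experiment()].
#' @return A tibble with one row per sonication x arm: peak measured
#'   temperature rise (degC), hot volume (> 10 degC proxy, cm^3) and
#'   cumulative 240 CEM43 dose volume (cm^3).
#' @export
run_thermometry_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"), config$kind == "thermometry")
  grid <- config$mrti_grid
  n_b <- config$n_baseline
  deposit_t <- n_b * config$seq$frame_interval
  heating <- heating_model(
    peak_delta_T = config$peak_delta_T_per_W * config$power_W,
    gaussian_sigma = config$heating_sigma_mm * 1e-3,
    deposit_time = deposit_t)
  roi <- array(TRUE, c(grid$nx, grid$ny, grid$nz))

  arms <- list(control = NULL, marker = config$marker_model)
  rows <- list()
  dose_prior <- list(control = NULL, marker = NULL)
  for (s in seq_len(config$sonications)) {
    for (arm in names(arms)) {
      series <- simulate_mrti_series(
        grid, n_frames = config$n_frames, heating = heating,
        marker = arms[[arm]], snr = config$snr, seq = config$seq,
        seed = config$seed + 1000L * s)
      noise_bg <- noise_corner_mask(grid)
      # the synthetic phantom fills the grid, so noise is estimated from
      # frame-to-frame differences in a static corner region
      mask <- if (is.finite(config$snr))
        snr_mask(series, k = 5, noise_region = noise_bg,
                 method = "temporal") else NULL
      dphi <- suppressWarnings(phase_change(series, seq_len(n_b)))
      temps <- prf_temperature(dphi, config$seq,
                               baseline_temperature = series$baseline_temperature,
                               grid = grid, mask = mask)
      dm <- cem43(temps, prior = dose_prior[[arm]])
      dose_prior[[arm]] <- dm
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sonication = s,
        arm = arm,
        peak_delta_T = max(unlist(lapply(temps$delta_T, max, na.rm = TRUE))),
        hot_volume_cm3 = hot_volume(temps, 10, roi),
        dose_volume_cm3 = dose_volume(dm)$volume_cm3
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics_csv(out, file.path(out_dir, "thermometry_metrics.csv"))
    write_manifest(config, out_dir)
  }
  out
}

# deterministic corner block used as the static region for temporal
# noise estimation in synthetic experiments
noise_corner_mask <- function(grid, n = 4L) {
  m <- array(FALSE, c(grid$nx, grid$ny, grid$nz))
  m[seq_len(min(n, grid$nx)), seq_len(min(n, grid$ny)),
    seq_len(min(n, grid$nz))] <- TRUE
  m
}

# CSV writer with deterministic formatting (byte-identical across runs)
write_metrics_csv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Serializes the configuration to YAML and records its MD5 hash, the
#' master seed and the package version — enough to reproduce a pipeline
#' run bit-for-bit.
#'
#' @param config an [experiment_config()].
#' @param out_dir directory receiving `config.yaml` and `manifest.yaml`.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, out_dir) {
  cfg <- config
  cfg$geom <- unclass(cfg$geom)[c("focal_length", "aperture_diameter",
                                  "frequency", "sound_speed",
                                  "source_discretization")]
  cfg$seq <- unclass(cfg$seq)
  cfg$marker_model <- if (is.null(cfg$marker_model)) NULL else
    unclass(cfg$marker_model)
  cfg$mrti_grid <- if (is.null(cfg$mrti_grid)) NULL else
    list(n = c(cfg$mrti_grid$nx, cfg$mrti_grid$ny, cfg$mrti_grid$nz),
         spacing_mm = c(cfg$mrti_grid$dx, cfg$mrti_grid$dy,
                        cfg$mrti_grid$dz) * 1e3)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package = "fusmark",
    version = as.character(utils::packageVersion("fusmark"))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
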