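#' Write a pressure volume or scalar 3D map as NIfTI
#'
#' Writes the magnitude of a [pressure_volume()] (or any scalar 3D array
#' with a voxel spacing) as a NIfTI volume with the voxel dimensions in
#' millimetres in the header.
#'
#' @param vol a [pressure_volume()], a `dose_map`, or a numeric 3D array.
#' @param path output file path (`.nii` / `.nii.gz`).
#' @param spacing voxel spacing in metres (only needed for bare arrays).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "pressure_volume")) {
    arr <- volume_magnitude(vol)
    spacing <- c(vol$grid$dx, vol$grid$dy, vol$grid$dz)
  } else if (inherits(vol, "dose_map")) {
    arr <- vol$dose
    spacing <- c(vol$grid$dx, vol$grid$dy, vol$grid$dz)
  } else {
    stopifnot(is.array(vol), length(dim(vol)) == 3, !is.null(spacing))
    arr <- vol
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing * 1e3
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3] / 1e3
  pressure_volume(arr, spacing = sp)
}

#' Write / read an MR complex image series
#'
#' The series is stored as paired 4D NIfTI files (magnitude and phase,
#' frames along the 4th dimension) plus a YAML sidecar holding the
#' sequence constants (TE, B0, gamma, alpha, frame interval) and baseline
#' temperature; ground-truth temperature frames, when present, go to a
#' third NIfTI. `path_prefix` names the triplet
#' `<prefix>_mag.nii.gz`, `<prefix>_phs.nii.gz`, `<prefix>.yaml`.
#'
#' @param series an MRTI series ([simulate_mrti_series()]).
#' @param path_prefix file-path prefix for the triplet.
#' @return `read_mrti_series()` returns an MRTI series (without the
#'   generator models); the writer returns `path_prefix` invisibly.
#' @export
write_mrti_series <- function(series, path_prefix) {
  stopifnot(inherits(series, "mrti_series"))
  g <- series$grid
  nf <- length(series$frames)
  mag <- array(0, c(g$nx, g$ny, g$nz, nf))
  phs <- array(0, c(g$nx, g$ny, g$nz, nf))
  for (i in seq_len(nf)) {
    mag[, , , i] <- Mod(series$frames[[i]])
    phs[, , , i] <- Arg(series$frames[[i]])
  }
  sp <- c(g$dx, g$dy, g$dz) * 1e3
  write4d <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(sp, series$seq$frame_interval)
    RNifti::writeNifti(img, path)
  }
  write4d(mag, paste0(path_prefix, "_mag.nii.gz"))
  write4d(phs, paste0(path_prefix, "_phs.nii.gz"))
  if (!is.null(series$truth_delta_T)) {
    tr <- array(0, c(g$nx, g$ny, g$nz, nf))
    for (i in seq_len(nf)) tr[, , , i] <- series$truth_delta_T[[i]]
    write4d(tr, paste0(path_prefix, "_truth.nii.gz"))
  }
  meta <- list(
    format = "fusmark-mrti-series-v1",
    TE = series$seq$TE, B0 = series$seq$B0, gamma = series$seq$gamma,
    alpha = series$seq$alpha, frame_interval = series$seq$frame_interval,
    phase_sign = series$seq$phase_sign,
    baseline_temperature = series$baseline_temperature,
    n_frames = nf,
    spacing_mm = as.numeric(sp)
  )
  yaml::write_yaml(meta, paste0(path_prefix, ".yaml"))
  invisible(path_prefix)
}

#' @rdname write_mrti_series
#' @export
read_mrti_series <- function(path_prefix) {
  meta <- yaml::read_yaml(paste0(path_prefix, ".yaml"))
  if (!identical(meta$format, "fusmark-mrti-series-v1"))
    stop("not a fusmark MRTI series: ", path_prefix)
  mag <- RNifti::readNifti(paste0(path_prefix, "_mag.nii.gz"))
  phs <- RNifti::readNifti(paste0(path_prefix, "_phs.nii.gz"))
  d <- dim(mag)
  sp <- meta$spacing_mm / 1e3
  g <- grid3d(d[1], d[2], d[3], sp[1], sp[2], sp[3])
  nf <- d[4]
  frames <- lapply(seq_len(nf), function(i)
    array(complex(modulus = as.numeric(mag[, , , i]),
                  argument = as.numeric(phs[, , , i])), dim = d[1:3]))
  truth <- NULL
  tp <- paste0(path_prefix, "_truth.nii.gz")
  if (file.exists(tp)) {
    tr <- RNifti::readNifti(tp)
    truth <- lapply(seq_len(nf), function(i)
      array(as.numeric(tr[, , , i]), dim = d[1:3]))
  }
  sq <- sequence_constants(TE = meta$TE, B0 = meta$B0, gamma = meta$gamma,
                           alpha = meta$alpha,
                           frame_interval = meta$frame_interval,
                           phase_sign = meta$phase_sign)
  structure(list(
    frames = frames, truth_delta_T = truth,
    times = (seq_len(nf) - 1) * meta$frame_interval,
    grid = g, seq = sq,
    baseline_temperature = meta$baseline_temperature,
    heating = NULL, marker = NULL, snr = NA_real_, seed = NA_integer_
  ), class = "mrti_series")
}

#' Write / read a gross-pathology slice stack
#'
#' Slices are written as per-slice PNG mask images
#' (`<dir>/slice_###.png`) plus `<dir>/slices.csv` with columns
#' `slice, file, pixel_scale_mm, thickness_mm, thickness_sd_mm,
#' area_sd_cm2`. This is the exchange format for real data: annotation
#' masks exported from an image-analysis tool plus a caliper log.
#'
#' @param stack a `slice_stack`.
#' @param dir directory to write into (created if needed).
#' @return `read_slice_stack()` returns a `slice_stack`; the writer
#'   returns `dir` invisibly.
#' @export
write_slice_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "slice_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sl <- stack$slices
  files <- sprintf("slice_%03d.png", sl$slice)
  for (i in seq_len(nrow(sl)))
    png::writePNG(t(matrix(as.numeric(sl$mask[[i]]),
                           nrow(sl$mask[[i]]), ncol(sl$mask[[i]]))),
                  file.path(dir, files[i]))
  utils::write.csv(
    data.frame(slice = sl$slice, file = files,
               pixel_scale_mm = stack$pixel_scale_mm,
               thickness_mm = sl$thickness_mm,
               thickness_sd_mm = sl$thickness_sd_mm,
               area_sd_cm2 = sl$area_sd_cm2),
    file.path(dir, "slices.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_slice_stack
#' @export
read_slice_stack <- function(dir) {
  csv <- utils::read.csv(file.path(dir, "slices.csv"))
  need <- c("slice", "file", "pixel_scale_mm", "thickness_mm")
  if (!all(need %in% names(csv)))
    stop("slices.csv must have columns: ", paste(need, collapse = ", "))
  csv <- csv[order(csv$slice), ]
  masks <- lapply(csv$file, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 3) img <- img[, , 1]
    t(img) > 0.5
  })
  structure(list(
    slices = tibble::tibble(
      slice = csv$slice,
      thickness_mm = csv$thickness_mm,
      thickness_sd_mm = if ("thickness_sd_mm" %in% names(csv))
        csv$thickness_sd_mm else 0,
      area_sd_cm2 = if ("area_sd_cm2" %in% names(csv))
        csv$area_sd_cm2 else NA_real_,
      mask = masks
    ),
    pixel_scale_mm = csv$pixel_scale_mm[1],
    true_volume_cm3 = NA_real_,
    semi_axes_mm = NULL,
    seed = NA_integer_
  ), class = "slice_stack")
}
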