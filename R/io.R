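# File interfaces: RadialKSpace to/from HDF5, velocity series to/from
# NIfTI, flow curves to CSV, metrics to JSON.

#' Write radial k-space data to HDF5
#'
#' Layout: `/data_real` and `/data_imag` (samples x spokes x coils),
#' `/angles` (deg), `/times` (s), `/enc_sign`, `/aqueduct_mask` and
#' `/support_mask` (0/1, when present), and an `/attrs` group holding the
#' scalar acquisition fields.
#'
#' @param ks a `radial_kspace` object.
#' @param path output file (overwritten).
#' @return `path`, invisibly.
#' @export
write_kspace <- function(ks, path) {
  stopifnot(inherits(ks, "radial_kspace"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(ks$data), path, "data_real")
  rhdf5::h5write(Im(ks$data), path, "data_imag")
  rhdf5::h5write(ks$angles, path, "angles")
  rhdf5::h5write(ks$times, path, "times")
  rhdf5::h5write(ks$enc_sign, path, "enc_sign")
  rhdf5::h5createGroup(path, "attrs")
  at <- list(venc = ks$venc, tr = ks$tr,
             spokes_per_frame = ks$spokes_per_frame,
             readout_samples = ks$readout_samples,
             matrix_size = ks$matrix_size, fov = ks$fov,
             pixel_mm = ks$pixel_mm, scale = ks$scale)
  for (nm in names(at)) rhdf5::h5write(at[[nm]], path, paste0("attrs/", nm))
  if (!is.null(ks$meta$aqueduct_mask)) {
    rhdf5::h5write(ks$meta$aqueduct_mask * 1L, path, "aqueduct_mask")
    rhdf5::h5write(ks$meta$support_mask * 1L, path, "support_mask")
    rhdf5::h5write(ks$meta$aqueduct_area_mm2, path, "attrs/aqueduct_area_mm2")
    wf <- ks$meta$waveform
    if (inherits(wf, "flow_waveform")) {
      rhdf5::h5createGroup(path, "waveform")
      for (nm in names(wf)) rhdf5::h5write(wf[[nm]], path,
                                           paste0("waveform/", nm))
    }
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read radial k-space data from HDF5
#'
#' @param path file written by [write_kspace()].
#' @return a `radial_kspace` object.
#' @export
read_kspace <- function(path) {
  re <- rhdf5::h5read(path, "data_real")
  im <- rhdf5::h5read(path, "data_imag")
  at <- rhdf5::h5read(path, "attrs")
  ls <- rhdf5::h5ls(path)$name
  meta <- list()
  if ("aqueduct_mask" %in% ls) {
    meta$aqueduct_mask <- rhdf5::h5read(path, "aqueduct_mask") > 0
    meta$support_mask <- rhdf5::h5read(path, "support_mask") > 0
    meta$aqueduct_area_mm2 <- as.numeric(at$aqueduct_area_mm2)
  }
  if ("waveform" %in% ls) {
    wfl <- rhdf5::h5read(path, "waveform")
    meta$waveform <- do.call(flow_waveform, lapply(wfl, as.numeric))
  }
  rhdf5::h5closeAll()
  structure(list(
    data = re + 1i * im,
    angles = as.numeric(rhdf5::h5read(path, "angles")),
    times = as.numeric(rhdf5::h5read(path, "times")),
    enc_sign = as.numeric(rhdf5::h5read(path, "enc_sign")),
    venc = as.numeric(at$venc), tr = as.numeric(at$tr),
    spokes_per_frame = as.integer(at$spokes_per_frame),
    readout_samples = as.integer(at$readout_samples),
    matrix_size = as.integer(at$matrix_size),
    fov = as.numeric(at$fov), pixel_mm = as.numeric(at$pixel_mm),
    scale = as.numeric(at$scale), meta = meta),
    class = "radial_kspace")
}

#' Write a velocity series to NIfTI
#'
#' Velocity (cm/s) and magnitude volumes with the time frames as the third
#' dimension and the pixel spacing in the header.
#'
#' @param vel a `velocity_series`.
#' @param path base path; `_vel.nii.gz` and `_mag.nii.gz` are appended.
#' @return paths of the written files, invisibly.
#' @export
write_velocity_nifti <- function(vel, path) {
  stopifnot(inherits(vel, "velocity_series"))
  dt <- if (length(vel$times) > 1) diff(vel$times)[1] else 1
  pv <- file.path(paste0(path, "_vel.nii.gz"))
  pm <- file.path(paste0(path, "_mag.nii.gz"))
  img <- RNifti::asNifti(vel$velocity)
  RNifti::pixdim(img) <- c(vel$pixel_mm, vel$pixel_mm, dt)
  RNifti::writeNifti(img, pv)
  mag <- RNifti::asNifti(vel$magnitude)
  RNifti::pixdim(mag) <- c(vel$pixel_mm, vel$pixel_mm, dt)
  RNifti::writeNifti(mag, pm)
  invisible(c(velocity = pv, magnitude = pm))
}

#' Read a velocity series from NIfTI
#'
#' For analysing externally reconstructed velocity maps with the flow
#' tools.
#'
#' @param vel_path NIfTI file with velocity (cm/s), frames as 3rd
#'   dimension.
#' @param mag_path optional magnitude NIfTI.
#' @param venc velocity encoding in cm/s.
#' @return a `velocity_series`.
#' @export
read_velocity_nifti <- function(vel_path, mag_path = NULL, venc = 15) {
  v <- RNifti::readNifti(vel_path)
  pd <- RNifti::pixdim(v)
  d <- dim(v)
  mag <- if (!is.null(mag_path))
    array(as.numeric(RNifti::readNifti(mag_path)), d)
  else array(1, d)
  structure(list(velocity = array(as.numeric(v), d), magnitude = mag,
                 times = (seq_len(d[3]) - 0.5) * pd[3], venc = venc,
                 pixel_mm = pd[1]),
            class = "velocity_series")
}

#' Write a flow curve (optionally with its filtered version) to CSV
#'
#' Columns `time_s`, `flow_ml_s` and, when `filtered` is given,
#' `flow_filtered_ml_s`.
#'
#' @param curve a [flow_curve()].
#' @param path output CSV.
#' @param filtered optional filtered [flow_curve()] on the same grid.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(curve, path, filtered = NULL) {
  stopifnot(inherits(curve, "flow_curve"))
  df <- data.frame(time_s = (seq_along(curve$samples) - 0.5) * curve$dt,
                   flow_ml_s = curve$samples)
  if (!is.null(filtered)) df$flow_filtered_ml_s <- filtered$samples
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics list to JSON
#'
#' @param metrics named list of scalars/vectors.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
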