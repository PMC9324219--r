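# End-to-end drivers: the baseline numerical experiment, the four parameter
# sweeps (heart rate, TR, diameter, lambda), and deterministic fixture
# generation.

#' Default simulation configurations
#'
#' Bundles the phantom, waveform and acquisition configurations of the
#' baseline numerical experiment (aqueduct diameter 2.5 mm, heart rate
#' 60 bpm, respiration 15/min, TR 10.5 ms, VENC 15 cm/s, 8 spokes/frame,
#' 2 encodings, 20 s, 8 coils, noise-free). `size = "tiny"` is a reduced
#' geometry (96 px, 6 s) for fast tests at the same pixel pitch.
#'
#' @param size `"baseline"` or `"tiny"`.
#' @param ... overrides for any of the [phantom_config()],
#'   [flow_waveform()] or [acquisition_config()] arguments.
#' @return list with `phantom`, `waveform`, `acq`.
#' @export
default_configs <- function(size = c("baseline", "tiny"), ...) {
  size <- match.arg(size)
  over <- list(...)
  base <- if (size == "baseline")
    list(matrix_size = 240, fov = 192, duration = 20)
  else
    list(matrix_size = 96, fov = 76.8, duration = 8.4)  # >= 2 resp periods
  pick <- function(fn, defaults) {
    args <- names(formals(fn))
    do.call(fn, modifyList(defaults[names(defaults) %in% args],
                           over[names(over) %in% args]))
  }
  list(
    phantom = pick(phantom_config,
                   list(matrix_size = base$matrix_size, fov = base$fov,
                        aqueduct_center = c(0, -20))),
    waveform = pick(flow_waveform, list()),
    acq = pick(acquisition_config, list(duration = base$duration)))
}

.simulate_from_configs <- function(cfgs) {
  scene <- build_scene(cfgs$phantom)
  maps <- simulate_coil_maps(cfgs$phantom$n_coils, cfgs$phantom$matrix_size)
  simulate_kspace(scene, cfgs$waveform, maps, cfgs$acq)
}

# static-tissue mask: inside the support, outside a dilated aqueduct
.static_mask <- function(ks) {
  m <- ks$meta$aqueduct_mask
  n <- nrow(m)
  dil <- m
  for (dx in -2:2) for (dy in -2:2) {
    sh <- m[pmin(pmax(seq_len(n) - dx, 1), n),
            pmin(pmax(seq_len(n) - dy, 1), n)]
    dil <- dil | sh
  }
  ks$meta$support_mask & !dil
}

#' Full pipeline on one data set: preprocess, reconstruct, analyse
#'
#' Runs the reconstruction pipeline (echo-shift and zeroth-order phase
#' corrections, normalization, coil compression, gridding + Walsh coil
#' maps) for each requested reconstruction variant, extracts the aqueduct
#' flow curve (ground-truth ROI for simulated data) after background phase
#' correction, and computes Q_R / Q_C against the programmed analytic
#' waveform.
#'
#' @param ks a `radial_kspace` from [simulate_kspace()] (or loaded via
#'   [read_kspace()]).
#' @param variants list of [recon_config()]s (or a single one).
#' @param f_resp,f_card component frequencies in Hz; default from the
#'   waveform stored with the data.
#' @param n_virtual virtual coils for compression.
#' @param roi_mask,static_mask optional masks overriding the ground-truth
#'   aqueduct / static-tissue masks stored with simulated data.
#' @return object of class `phantom_report`: `table` (one row per variant
#'   with Q_R, Q_C), `curves` (list of real-time [flow_curve()]s),
#'   `reference` (reference flow curve), `velocity` (last variant's
#'   `velocity_series`), `maps`, and `provenance`.
#' @export
run_phantom_analysis <- function(ks, variants = list(recon_config("cs", 1e-6)),
                                 f_resp = NULL, f_card = NULL,
                                 n_virtual = 8, roi_mask = NULL,
                                 static_mask = NULL) {
  stopifnot(inherits(ks, "radial_kspace"))
  if (inherits(variants, "recon_config")) variants <- list(variants)
  wf <- ks$meta$waveform
  if (is.null(f_resp)) {
    if (!inherits(wf, "flow_waveform"))
      stop("f_resp/f_card must be given when no waveform is stored")
    f_resp <- wf$resp_frequency / 60
    f_card <- wf$card_frequency / 60
  }
  if (is.null(roi_mask)) roi_mask <- ks$meta$aqueduct_mask
  if (is.null(static_mask)) static_mask <- .static_mask(ks)

  pre <- correct_echo_shifts(ks)
  pre <- correct_zeroth_order(pre)
  pre <- normalize_kspace(pre)
  pre <- compress_coils(pre, min(n_virtual, dim(pre$data)[3]))
  maps <- walsh_sensitivities(gridded_recon(pre, "both"))

  area <- ks$meta$aqueduct_area_mm2
  ref_fun <- function(t) evaluate_velocity(wf, t) * area * 1e-2  # mL/s
  rows <- list(); curves <- list(); vel <- NULL; ref_curve <- NULL
  for (v in variants) {
    stopifnot(inherits(v, "recon_config"))
    rec <- switch(v$mode,
      "gridding" = {
        p <- .image_series(.gridding_series(pre, maps, "plus"),
                           .gridding_times(pre), pre$pixel_mm, "plus")
        m <- .image_series(.gridding_series(pre, maps, "minus"),
                           .gridding_times(pre), pre$pixel_mm, "minus")
        .recon_result(p, m, "gridding", NA, NA, pre$venc)
      },
      "cg-sense" = cg_sense(pre, maps, n_iters = v$n_iters),
      "cs" = cs_temporal_tv(pre, maps, lambda = v$lambda,
                            n_iters = v$n_iters))
    vel <- velocity_map(rec)
    vel <- background_phase_correct(vel, static_mask)
    fc <- roi_flow(vel, roi_mask)
    t <- (seq_along(fc$samples) - 0.5) * fc$dt
    ref_curve <- flow_curve(ref_fun(t), fc$dt)
    qr_ <- q_ratios(fc, ref_curve, f_resp, f_card)
    lab <- if (v$mode == "cs") paste0("cs_", format(v$lambda)) else v$mode
    rows[[length(rows) + 1]] <-
      data.frame(mode = v$mode, lambda = ifelse(v$mode == "cs", v$lambda, NA),
                 q_r = qr_$q_r, q_c = qr_$q_c,
                 r_rt = qr_$r_rt, r_ref = qr_$r_ref,
                 c_rt = qr_$c_rt, c_ref = qr_$c_ref)
    curves[[lab]] <- fc
  }
  structure(list(table = do.call(rbind, rows), curves = curves,
                 reference = ref_curve, velocity = vel, maps = maps,
                 provenance = .provenance(ks)),
            class = "phantom_report")
}

# per-frame gridding reconstruction (coil-combined with the maps)
.gridding_series <- function(ks, maps, encoding) {
  fr <- .frame_coords(ks, encoding)
  n <- ks$matrix_size
  nF <- dim(fr$data)[3]
  w <- ramlak_weights(ks$readout_samples)
  scale <- attr(w, "raw_mean") * (1 / ks$readout_samples) *
    (pi / ks$spokes_per_frame)
  out <- array(0i, dim = c(n, n, nF))
  nc <- dim(maps)[3]
  ww <- rep(as.numeric(w) * scale, ks$spokes_per_frame)
  for (f in seq_len(nF)) {
    img <- nufft_adjoint(fr$data[, , f] * ww, cbind(fr$kx[, f], fr$ky[, f]), n)
    acc <- 0i
    for (c in seq_len(nc)) acc <- acc + Conj(maps[, , c]) * img[, , c]
    out[, , f] <- acc
  }
  out
}

.gridding_times <- function(ks) {
  frame_bins(sum(ks$enc_sign > 0), ks$spokes_per_frame, ks$tr)$timestamps_s
}

#' @export
print.phantom_report <- function(x, ...) {
  cat("<phantom_report>\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

.provenance <- function(ks) {
  list(package = "aqueflow",
       version = as.character(packageVersion("aqueflow")),
       r_version = R.version.string,
       acquisition = ks$meta$acquisition,
       phantom = ks$meta$phantom,
       waveform = ks$meta$waveform)
}

#' Run one of the four numerical parameter sweeps
#'
#' For each value of the swept parameter the pipeline is run end to end:
#' simulate (noise-free), reconstruct, extract the aqueduct flow, and
#' compute Q_R / Q_C against the programmed waveform. The baseline is
#' d = 2.5 mm, heart rate 60 bpm, TR 10.5 ms, 8 spokes per frame. A failing
#' value is recorded with NA ratios and a diagnostic message rather than
#' aborting the sweep.
#'
#' @param parameter one of `"heart_rate"` (bpm), `"tr"` (ms), `"diameter"`
#'   (mm), `"lambda"`.
#' @param values numeric values to sweep. Defaults follow the study design:
#'   heart rate 60-120 by 15; TR 2-10.5 by 1 ms; diameter 2-10 by 1 mm;
#'   lambda 10^(-9..-2) in exponent steps of 0.5.
#' @param recon a [recon_config()] used for every value (CS, lambda 1e-6 by
#'   default; ignored for the lambda sweep which varies it).
#' @param size `"baseline"` or `"tiny"` simulation scale.
#' @param ... further overrides passed to [default_configs()].
#' @return data.frame of class `aq_sweep` with columns `parameter`,
#'   `value`, `q_r`, `q_c` (and `error` messages where a value failed);
#'   full configuration in attribute `provenance`.
#' @export
run_sweep <- function(parameter = c("heart_rate", "tr", "diameter", "lambda"),
                      values = NULL,
                      recon = recon_config("cs", lambda = 1e-6),
                      size = "baseline", ...) {
  parameter <- match.arg(parameter)
  if (is.null(values))
    values <- switch(parameter,
                     heart_rate = seq(60, 120, by = 15),
                     tr = c(seq(2, 10, by = 1), 10.5),
                     diameter = seq(2, 10, by = 1),
                     lambda = 10^seq(-9, -2, by = 0.5))
  rows <- vector("list", length(values))
  prov <- list()
  for (i in seq_along(values)) {
    v <- values[i]
    res <- tryCatch({
      over <- switch(parameter,
                     heart_rate = list(card_frequency = v),
                     tr = list(tr = v),
                     diameter = list(aqueduct_diameter = v),
                     lambda = list())
      cfgs <- do.call(default_configs,
                      c(list(size = size), over, list(...)))
      ks <- .simulate_from_configs(cfgs)
      rc <- if (parameter == "lambda") recon_config("cs", lambda = v,
                                                    n_iters = recon$n_iters)
            else recon
      rep_ <- run_phantom_analysis(ks, list(rc))
      prov[[i]] <- rep_$provenance
      data.frame(parameter = parameter, value = v,
                 q_r = rep_$table$q_r[1], q_c = rep_$table$q_c[1],
                 error = NA_character_)
    }, error = function(e) {
      message("sweep value ", v, " failed: ", conditionMessage(e))
      data.frame(parameter = parameter, value = v, q_r = NA_real_,
                 q_c = NA_real_, error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("aq_sweep", "data.frame")
  attr(out, "provenance") <- prov
  attr(out, "recon") <- recon
  out
}

#' @export
plot.aq_sweep <- function(x, ...) {
  graphics::matplot(x$value, cbind(x$q_r, x$q_c), type = "b", pch = c(1, 2),
                    lty = 1, col = c("blue", "red"),
                    log = if (x$parameter[1] == "lambda") "x" else "",
                    xlab = x$parameter[1], ylab = "Q ratio",
                    ylim = c(0, max(1, x$q_r, x$q_c, na.rm = TRUE)), ...)
  graphics::legend("bottomright", c("Q_R", "Q_C"), pch = c(1, 2),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Write deterministic test fixtures
#'
#' Generates a small simulated data set (k-space HDF5 + configuration YAML)
#' together with MD5 checksums; regenerating yields identical files.
#'
#' @param dir output directory (created if needed).
#' @param size `"tiny"` (96 px, 6 s; default) or `"baseline"`.
#' @return named character vector of MD5 checksums, invisibly.
#' @export
make_fixtures <- function(dir, size = "tiny") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfgs <- if (size == "tiny") default_configs("tiny", duration = 6)
          else default_configs(size)
  ks <- .simulate_from_configs(cfgs)
  h5 <- file.path(dir, paste0("kspace_", size, ".h5"))
  write_kspace(ks, h5)
  yml <- file.path(dir, paste0("config_", size, ".yaml"))
  yaml::write_yaml(list(phantom = unclass(cfgs$phantom),
                        waveform = unclass(cfgs$waveform),
                        acquisition = unclass(cfgs$acq)), yml)
  # checksum the content, not the container (HDF5 headers carry timestamps)
  can <- tempfile()
  on.exit(unlink(can))
  saveRDS(list(data = ks$data, angles = ks$angles, times = ks$times,
               enc = ks$enc_sign), can, compress = FALSE)
  sums <- c(tools::md5sum(can), tools::md5sum(yml))
  names(sums) <- basename(c(h5, yml))
  writeLines(paste(sums, names(sums)), file.path(dir, "checksums.md5"))
  invisible(sums)
}
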