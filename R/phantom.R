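# Numerical flow phantom: a modified Shepp-Logan scene with a circular
# "aqueduct" whose through-plane velocity modulates the image phase, plus
# synthetic coil sensitivities and spoke-by-spoke radial k-space simulation.

# Toft's "modified Shepp-Logan" ellipse table: value, semi-axes a/b,
# centre x0/y0, rotation (deg), in units of the half-FOV.
.shepp_logan_ellipses <- function() {
  matrix(c(
     1.0, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.8, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.2, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.2, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.1, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.1, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.1, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.1, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.1, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.1, 0.0230, 0.0460,  0.06, -0.6050,   0),
    ncol = 6, byrow = TRUE,
    dimnames = list(NULL, c("value", "a", "b", "x0", "y0", "phi")))
}

#' Numerical phantom configuration
#'
#' Geometry of the simulated scene: a modified Shepp-Logan head with a small
#' circular aqueduct added. `tissue_magnitude` is the signal level of the
#' brain-tissue plateau surrounding the aqueduct (the whole Shepp-Logan
#' scene is rescaled accordingly); `aqueduct_magnitude` is the CSF signal in
#' the disc, brighter than tissue as CSF is in long-TR gradient-echo flow
#' imaging.
#'
#' @param matrix_size pixels per side (even).
#' @param fov field of view in mm.
#' @param aqueduct_center (x, y) offset from the image centre in mm.
#' @param aqueduct_diameter disc diameter in mm (baseline 2.5).
#' @param aqueduct_magnitude,tissue_magnitude signal magnitudes (arbitrary
#'   units).
#' @param n_coils number of simulated receive coils.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(matrix_size = 240, fov = 192,
                           aqueduct_center = c(0, -20),
                           aqueduct_diameter = 2.5,
                           aqueduct_magnitude = 0.8,
                           tissue_magnitude = 0.2,
                           n_coils = 8) {
  if (matrix_size %% 2 != 0) stop("matrix_size must be even")
  if (aqueduct_diameter <= 0) stop("aqueduct_diameter must be > 0")
  if (n_coils < 1) stop("n_coils must be >= 1")
  cfg <- structure(list(matrix_size = as.integer(matrix_size), fov = fov,
                        aqueduct_center = aqueduct_center,
                        aqueduct_diameter = aqueduct_diameter,
                        aqueduct_magnitude = aqueduct_magnitude,
                        tissue_magnitude = tissue_magnitude,
                        n_coils = as.integer(n_coils)),
                   class = "phantom_config")
  # the disc must lie fully inside the scene support (the outer head ellipse)
  h <- fov / 2
  r <- aqueduct_diameter / 2
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  px <- (aqueduct_center[1] + r * cos(th)) / (0.69 * h)
  py <- (aqueduct_center[2] + r * sin(th)) / (0.92 * h)
  if (any(px^2 + py^2 >= 1))
    stop("configuration error: aqueduct disc extends outside the scene support")
  cfg
}

#' Flow waveform: respiratory plus cardiac sinusoid
#'
#' Through-plane velocity programmed as the superposition of a slow
#' respiratory component and a faster cardiac component,
#' `v(t) = A_r sin(2 pi f_r t + phi_r) + A_c sin(2 pi f_c t + phi_c)`.
#' Default amplitudes are the component amplitudes measured in the pump
#' phantom experiment (3.02 and 2.76 cm/s).
#'
#' @param resp_amplitude,card_amplitude component amplitudes in cm/s.
#' @param resp_frequency,card_frequency frequencies in cycles/min
#'   (respiration 15; cardiac one of 45-120).
#' @param resp_phase,card_phase phases in radians.
#' @return object of class `flow_waveform`.
#' @export
flow_waveform <- function(resp_amplitude = 3.02, resp_frequency = 15,
                          card_amplitude = 2.76, card_frequency = 60,
                          resp_phase = 0, card_phase = 0) {
  if (resp_frequency <= 0 || card_frequency <= 0)
    stop("frequencies must be > 0")
  if (resp_frequency >= card_frequency)
    stop("resp_frequency must be below card_frequency")
  structure(list(resp_amplitude = resp_amplitude,
                 resp_frequency = resp_frequency,
                 card_amplitude = card_amplitude,
                 card_frequency = card_frequency,
                 resp_phase = resp_phase, card_phase = card_phase),
            class = "flow_waveform")
}

#' Evaluate the programmed velocity waveform
#'
#' @param wf a [flow_waveform()], or any function of time returning cm/s.
#' @param t time(s) in seconds, `t >= 0`.
#' @return velocity in cm/s (vectorized over `t`).
#' @export
evaluate_velocity <- function(wf, t) {
  stopifnot(all(t >= 0))
  if (is.function(wf)) return(wf(t))
  stopifnot(inherits(wf, "flow_waveform"))
  fr <- wf$resp_frequency / 60
  fc <- wf$card_frequency / 60
  wf$resp_amplitude * sin(2 * pi * fr * t + wf$resp_phase) +
    wf$card_amplitude * sin(2 * pi * fc * t + wf$card_phase)
}

#' Velocity-induced phase of one encoding
#'
#' Symmetric bipolar convention: each encoding contributes
#' `sign * (pi/2) * v / venc`, so that the phase difference between the two
#' encodings is `pi * v / venc` and velocity `v = venc` maps to a phase
#' difference of exactly pi (the defining property of VENC).
#'
#' @param v velocity in cm/s.
#' @param venc velocity-encoding parameter in cm/s (> 0).
#' @param sign encoding sign, +1 or -1.
#' @return phase in radians.
#' @export
velocity_to_phase <- function(v, venc, sign) {
  stopifnot(venc > 0, all(sign %in% c(-1, 1)))
  sign * (pi / 2) * v / venc
}

#' Deterministic synthetic coil sensitivity maps
#'
#' Smooth loop-like sensitivities: `n_coils` elements evenly placed on a
#' circle just outside the FOV, each with a Lorentzian magnitude fall-off
#' (Biot-Savart-like) and a slowly varying phase along its viewing
#' direction. The root sum of squares is bounded away from zero over the
#' whole image. Fully deterministic in (`n_coils`, `matrix_size`).
#'
#' @param n_coils number of coils (>= 1). `n_coils = 1` yields a uniform
#'   unit map.
#' @param matrix_size image size in pixels.
#' @return complex array `matrix_size x matrix_size x n_coils`.
#' @export
simulate_coil_maps <- function(n_coils, matrix_size) {
  stopifnot(n_coils >= 1, matrix_size >= 2)
  n <- matrix_size
  if (n_coils == 1)
    return(array(1 + 0i, dim = c(n, n, 1)))
  p <- seq_len(n) - 1 - n / 2
  x <- matrix(p, n, n)
  y <- matrix(p, n, n, byrow = TRUE)
  maps <- array(0i, dim = c(n, n, n_coils))
  rad <- 0.58 * n          # coil circle radius, pixels
  falloff <- 0.45 * n      # Lorentzian width
  for (c in seq_len(n_coils)) {
    th <- 2 * pi * (c - 1) / n_coils
    cx <- rad * cos(th)
    cy <- rad * sin(th)
    d2 <- (x - cx)^2 + (y - cy)^2
    mag <- falloff^2 / (falloff^2 + d2)
    ph <- 2 * pi * 0.1 * (x * cos(th) + y * sin(th)) / n + 2 * pi * (c - 1) / n_coils
    maps[, , c] <- mag * exp(1i * ph)
  }
  maps
}

#' Render the numerical phantom scene
#'
#' Standard modified Shepp-Logan ellipses rendered at `matrix_size`
#' (pixel-centre convention, image centre at pixel `n/2`, 0-based), rescaled
#' so the tissue plateau equals `tissue_magnitude`, with a circular disc of
#' `aqueduct_magnitude` at `aqueduct_center`. A pixel belongs to the
#' aqueduct when its centre falls inside the disc. The phase is zero
#' everywhere at t = 0.
#'
#' @param cfg a [phantom_config()].
#' @return object of class `phantom_scene`: list with complex `image`,
#'   logical `aqueduct_mask` and `support_mask`, `pixel_mm`, and `config`.
#' @export
build_scene <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  n <- cfg$matrix_size
  h <- cfg$fov / 2
  px <- cfg$fov / n
  pos <- (seq_len(n) - 1 - n / 2) * px
  x <- matrix(pos, n, n) / h           # normalized [-1, 1)
  y <- matrix(pos, n, n, byrow = TRUE) / h
  img <- matrix(0, n, n)
  ell <- .shepp_logan_ellipses()
  for (e in seq_len(nrow(ell))) {
    phi <- ell[e, "phi"] * pi / 180
    xr <- (x - ell[e, "x0"]) * cos(phi) + (y - ell[e, "y0"]) * sin(phi)
    yr <- -(x - ell[e, "x0"]) * sin(phi) + (y - ell[e, "y0"]) * cos(phi)
    inside <- (xr / ell[e, "a"])^2 + (yr / ell[e, "b"])^2 <= 1
    img[inside] <- img[inside] + ell[e, "value"]
  }
  img[abs(img) < 1e-12] <- 0       # clear floating residue of ellipse sums
  img <- img * (cfg$tissue_magnitude / 0.2)
  support <- (x / 0.69)^2 + (y / 0.92)^2 <= 1
  xm <- matrix(pos, n, n)
  ym <- matrix(pos, n, n, byrow = TRUE)
  r2 <- (xm - cfg$aqueduct_center[1])^2 + (ym - cfg$aqueduct_center[2])^2
  mask <- r2 <= (cfg$aqueduct_diameter / 2)^2
  if (!any(mask))
    warning("aqueduct disc smaller than one pixel: empty aqueduct mask")
  img[mask] <- cfg$aqueduct_magnitude
  structure(list(image = img + 0i, aqueduct_mask = mask,
                 support_mask = support, pixel_mm = px, config = cfg),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cfg <- x$config
  cat("<phantom_scene> ", cfg$matrix_size, "x", cfg$matrix_size,
      " px, FOV ", cfg$fov, " mm (", format(x$pixel_mm, digits = 3),
      " mm/px)\n", sep = "")
  cat("  aqueduct: d = ", cfg$aqueduct_diameter, " mm at (",
      cfg$aqueduct_center[1], ", ", cfg$aqueduct_center[2], ") mm, ",
      sum(x$aqueduct_mask), " px\n", sep = "")
  invisible(x)
}

#' Acquisition configuration
#'
#' Timing and encoding of the real-time radial flow sequence. Flip angle,
#' TE and bandwidth are carried as metadata only; relaxation and
#' off-resonance are not simulated.
#'
#' @param tr repetition time in ms (baseline 10.5).
#' @param venc velocity encoding in cm/s (15).
#' @param spokes_per_frame radial spokes per reconstructed frame (8).
#' @param n_encodings interleaved velocity encodings (fixed at 2).
#' @param duration acquisition duration in s.
#' @param readout_samples samples per spoke; default `NULL` means the image
#'   matrix size (Nyquist along the spoke).
#' @param flip_angle,te,bandwidth sequence metadata (deg, ms, Hz/pixel).
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(tr = 10.5, venc = 15, spokes_per_frame = 8,
                               n_encodings = 2, duration = 20,
                               readout_samples = NULL, flip_angle = 7,
                               te = 5.1, bandwidth = 208) {
  stopifnot(tr > 0, venc > 0, spokes_per_frame >= 1, duration > 0)
  if (n_encodings != 2)
    stop("only two interleaved velocity encodings are supported")
  structure(list(tr = tr, venc = venc,
                 spokes_per_frame = as.integer(spokes_per_frame),
                 n_encodings = 2L, duration = duration,
                 readout_samples = readout_samples,
                 flip_angle = flip_angle, te = te, bandwidth = bandwidth),
            class = "acquisition_config")
}

#' Simulate spoke-by-spoke radial k-space data
#'
#' For TR index i (time `t = i TR`), the aqueduct phase is set from the
#' programmed velocity and the encoding sign (alternating every TR), and one
#' radial spoke of the coil-weighted scene is sampled by nonuniform Fourier
#' transform. The spoke angle advances by the golden angle every second TR,
#' so the two encodings of a pair share an angle. The velocity is frozen
#' during each readout. Noise-free and fully deterministic.
#'
#' Because the disc phase is spatially uniform within a TR, the simulation
#' decomposes the scene into static-background and aqueduct parts, takes the
#' NUFFT of each once per coil, and phase-modulates the aqueduct part per
#' TR; this is algebraically identical to one NUFFT per TR.
#'
#' @param scene a [build_scene()] result.
#' @param wf a [flow_waveform()] or function of time (s) returning cm/s.
#' @param maps coil maps as from [simulate_coil_maps()], or `NULL` for a
#'   single uniform coil.
#' @param acq an [acquisition_config()].
#' @return object of class `radial_kspace`: complex `data`
#'   (samples x spokes x coils), per-spoke `angles` (deg), `times` (s),
#'   `enc_sign`, plus acquisition/scene metadata.
#' @export
simulate_kspace <- function(scene, wf, maps, acq) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(acq, "acquisition_config"))
  n <- scene$config$matrix_size
  if (is.null(maps)) maps <- array(1 + 0i, dim = c(n, n, 1))
  stopifnot(length(dim(maps)) == 3, dim(maps)[1] == n, dim(maps)[2] == n)
  nc <- dim(maps)[3]
  ns <- if (is.null(acq$readout_samples)) n else as.integer(acq$readout_samples)
  tr_s <- acq$tr / 1000
  n_pairs <- floor(acq$duration / tr_s / 2)
  if (n_pairs < acq$spokes_per_frame)
    stop("duration too short for one frame (", n_pairs, " spoke pairs < ",
         acq$spokes_per_frame, ")")
  angles <- golden_angles(n_pairs)

  coords <- do.call(rbind, lapply(angles, spoke_coords, n_samples = ns))
  base <- scene$image
  base[scene$aqueduct_mask] <- 0
  disc <- scene$image
  disc[!scene$aqueduct_mask] <- 0
  stack <- function(img) {
    a <- array(0i, dim = c(n, n, nc))
    for (c in seq_len(nc)) a[, , c] <- img * maps[, , c]
    a
  }
  ks_base <- cpp_nufft_forward(stack(base), coords[, 1], coords[, 2],
                               n, nc, 1.25, 4L)      # (n_pairs*ns, nc)
  ks_disc <- cpp_nufft_forward(stack(disc), coords[, 1], coords[, 2],
                               n, nc, 1.25, 4L)

  n_spokes <- 2L * n_pairs
  t_all <- (seq_len(n_spokes) - 1) * tr_s
  enc <- rep(c(1, -1), n_pairs)
  v <- evaluate_velocity(wf, t_all)
  ph <- velocity_to_phase(v, acq$venc, enc)

  data <- array(0i, dim = c(ns, n_spokes, nc))
  dim(ks_base) <- c(ns, n_pairs, nc)
  dim(ks_disc) <- c(ns, n_pairs, nc)
  for (c in seq_len(nc)) {
    b <- ks_base[, , c]
    d <- ks_disc[, , c]
    m <- matrix(0i, ns, n_spokes)
    m[, seq(1, n_spokes, 2)] <- b + d * rep(exp(1i * ph[seq(1, n_spokes, 2)]),
                                            each = ns)
    m[, seq(2, n_spokes, 2)] <- b + d * rep(exp(1i * ph[seq(2, n_spokes, 2)]),
                                            each = ns)
    data[, , c] <- m
  }

  structure(list(
    data = data,
    angles = rep(angles, each = 2),
    times = t_all,
    enc_sign = enc,
    venc = acq$venc,
    tr = acq$tr,
    spokes_per_frame = acq$spokes_per_frame,
    readout_samples = ns,
    matrix_size = n,
    fov = scene$config$fov,
    pixel_mm = scene$pixel_mm,
    scale = 1,
    meta = list(aqueduct_mask = scene$aqueduct_mask,
                support_mask = scene$support_mask,
                aqueduct_area_mm2 = pi * (scene$config$aqueduct_diameter / 2)^2,
                waveform = wf,
                acquisition = acq,
                phantom = scene$config)),
    class = "radial_kspace")
}

#' @export
print.radial_kspace <- function(x, ...) {
  cat("<radial_kspace> ", dim(x$data)[1], " samples x ", dim(x$data)[2],
      " spokes x ", dim(x$data)[3], " coils\n", sep = "")
  cat("  TR ", x$tr, " ms, VENC ", x$venc, " cm/s, ",
      x$spokes_per_frame, " spokes/frame, duration ",
      format(max(x$times) + x$tr / 1000, digits = 4), " s\n", sep = "")
  invisible(x)
}
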