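# From velocity maps to flow curves and summary measures: background phase
# correction, ROI flow extraction and tracking, FFT component amplitudes and
# Q ratios, zero-phase FIR low-pass filtering, flow volumes, and
# magnitude-squared coherence with a respiratory trace.

#' Flow curve container
#'
#' @param samples volumetric flow per frame, mL/s.
#' @param dt frame duration in s (uniform sampling).
#' @param mean_velocity optional mean ROI velocity track, cm/s.
#' @return object of class `flow_curve`.
#' @export
flow_curve <- function(samples, dt, mean_velocity = NULL) {
  stopifnot(dt > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), dt = dt,
                 mean_velocity = mean_velocity),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat("<flow_curve> ", length(x$samples), " samples, dt ",
      format(x$dt, digits = 4), " s (", format(length(x$samples) * x$dt,
      digits = 4), " s)\n", sep = "")
  invisible(x)
}

#' @export
plot.flow_curve <- function(x, ...) {
  t <- (seq_along(x$samples) - 0.5) * x$dt
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "flow (mL/s)", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Background phase correction by first-order polynomial fit
#'
#' Per frame, a plane `a + b x + c y` is least-squares fitted to the
#' velocities of static-tissue pixels and subtracted from the whole map,
#' removing residual eddy-current phase offsets.
#'
#' @param vmap a `velocity_series`.
#' @param static_mask logical matrix of static-tissue pixels (>= 3 pixels,
#'   disjoint from the flow ROI).
#' @return corrected `velocity_series`; fitted coefficients (3 x frames) in
#'   attribute `plane_coefficients`.
#' @export
background_phase_correct <- function(vmap, static_mask) {
  stopifnot(inherits(vmap, "velocity_series"))
  idx <- which(static_mask)
  if (length(idx) < 3) stop("need at least 3 static pixels")
  d <- dim(vmap$velocity)
  xg <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  yg <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  X <- cbind(1, xg[idx], yg[idx])
  V <- matrix(vmap$velocity, nrow = d[1] * d[2])[idx, , drop = FALSE]
  B <- qr.coef(qr(X), V)                       # 3 x frames
  plane <- cbind(1, as.numeric(xg), as.numeric(yg)) %*% B
  vmap$velocity <- vmap$velocity - array(plane, d)
  attr(vmap, "plane_coefficients") <- B
  vmap
}

#' ROI flow extraction
#'
#' Flow per frame is the velocity of each ROI pixel times the pixel area,
#' summed over the ROI, converted to mL/s (cm/s x mm^2 x 1e-2). The mean
#' ROI velocity is also returned.
#'
#' @param vmap a `velocity_series`.
#' @param roi_mask logical matrix (fixed ROI) or logical array
#'   `n x n x frames` (tracked ROI).
#' @param pixel_area pixel area in mm^2; defaults to `pixel_mm^2` from the
#'   series.
#' @return a [flow_curve()].
#' @export
roi_flow <- function(vmap, roi_mask, pixel_area = NULL) {
  stopifnot(inherits(vmap, "velocity_series"))
  if (is.null(pixel_area)) pixel_area <- vmap$pixel_mm^2
  d <- dim(vmap$velocity)
  nF <- d[3]
  per_frame <- length(dim(roi_mask)) == 3
  if (!per_frame && !any(roi_mask)) stop("empty ROI")
  flow <- numeric(nF)
  mv <- numeric(nF)
  for (f in seq_len(nF)) {
    m <- if (per_frame) roi_mask[, , f] else roi_mask
    if (!any(m)) stop("empty ROI in frame ", f)
    v <- vmap$velocity[, , f][m]
    flow[f] <- sum(v) * pixel_area * 1e-2
    mv[f] <- mean(v)
  }
  dt <- if (nF > 1) diff(vmap$times)[1] else vmap$times * 2
  flow_curve(flow, dt, mean_velocity = mv)
}

#' Track the ROI through the time series
#'
#' Rigid integer-pixel translation per frame, maximizing the normalized
#' cross-correlation of a magnitude patch around the ROI against frame 1.
#' A warning is raised when the correlation peak lies on the edge of the
#' search window.
#'
#' @param magnitude magnitude image array `n x n x frames` (e.g. the
#'   `magnitude` of a `velocity_series`).
#' @param initial_mask logical ROI mask on frame 1.
#' @param search_radius maximum shift in pixels (0 = identity masks).
#' @param pad patch padding around the ROI bounding box, pixels.
#' @return list with `masks` (logical array per frame) and `shifts`
#'   (frames x 2 integer matrix).
#' @export
track_roi <- function(magnitude, initial_mask, search_radius = 3, pad = 5) {
  d <- dim(magnitude)
  stopifnot(length(d) == 3, any(initial_mask))
  nF <- d[3]
  rr <- range(which(rowSums(initial_mask) > 0))
  cc <- range(which(colSums(initial_mask) > 0))
  r0 <- max(rr[1] - pad, 1 + search_radius)
  r1 <- min(rr[2] + pad, d[1] - search_radius)
  c0 <- max(cc[1] - pad, 1 + search_radius)
  c1 <- min(cc[2] + pad, d[2] - search_radius)
  ref <- magnitude[r0:r1, c0:c1, 1]
  ref <- ref - mean(ref)
  refn <- sqrt(sum(ref^2))
  masks <- array(FALSE, dim = d)
  shifts <- matrix(0L, nF, 2)
  edge_hit <- FALSE
  for (f in seq_len(nF)) {
    best <- -Inf; bs <- c(0L, 0L)
    for (sx in -search_radius:search_radius) {
      for (sy in -search_radius:search_radius) {
        patch <- magnitude[(r0:r1) + sx, (c0:c1) + sy, f]
        patch <- patch - mean(patch)
        pn <- sqrt(sum(patch^2))
        ncc <- if (pn == 0 || refn == 0) 0 else sum(patch * ref) / (pn * refn)
        if (ncc > best) { best <- ncc; bs <- c(sx, sy) }
      }
    }
    if (search_radius > 0 && any(abs(bs) == search_radius)) edge_hit <- TRUE
    shifts[f, ] <- bs
    src <- which(initial_mask, arr.ind = TRUE)
    dst <- cbind(src[, 1] + bs[1], src[, 2] + bs[2])
    keep <- dst[, 1] >= 1 & dst[, 1] <= d[1] & dst[, 2] >= 1 & dst[, 2] <= d[2]
    masks[cbind(dst[keep, , drop = FALSE], f)] <- TRUE
  }
  if (edge_hit)
    warning("correlation peak at search-window edge; increase search_radius")
  list(masks = masks, shifts = shifts)
}

#' Single-sided FFT amplitude of one frequency component
#'
#' Amplitude `2 |FFT| / N` at the discrete bin nearest `f` (DC excluded).
#' When `f` falls between bins, the spectral peak is refined by quadratic
#' interpolation of `|FFT|` over the three bins around it; no window or
#' detrending is applied by default.
#'
#' @param curve a [flow_curve()] (or any uniformly sampled numeric vector
#'   with attribute-free values; then `dt` must be given).
#' @param f target frequency in Hz (below Nyquist; the curve must cover at
#'   least two periods of `f`).
#' @param dt sampling interval, taken from the curve if omitted.
#' @return amplitude in the curve's units.
#' @export
component_amplitude <- function(curve, f, dt = NULL) {
  if (inherits(curve, "flow_curve")) {
    x <- curve$samples
    dt <- curve$dt
  } else x <- as.numeric(curve)
  stopifnot(!is.null(dt), f > 0)
  N <- length(x)
  if (f >= 0.5 / dt) stop("f at or above the Nyquist frequency")
  if (N * dt < 2 / f) stop("curve shorter than two periods of f")
  X <- Mod(fft(x))
  b <- round(f * N * dt)                      # 0-based bin
  b <- max(1, min(b, floor(N / 2) - 1))
  y2 <- X[b + 1]
  if (b >= 2 && b + 2 <= N) {
    y1 <- X[b]; y3 <- X[b + 2]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && abs(den) > .Machine$double.eps * max(y2, 1)) {
      p <- 0.5 * (y1 - y3) / den
      if (abs(p) <= 0.5) y2 <- y2 - 0.25 * (y1 - y3) * p
    }
  }
  2 * y2 / N
}

#' Spectral amplitude ratios Q_R and Q_C
#'
#' Accuracy indices of real-time flow: the ratio of the respiratory
#' (cardiac) FFT component amplitude in the real-time curve to that in the
#' reference, `Q_R = R_RT / R_Ref` and `Q_C = C_RT / C_Ref`. A ratio of 1
#' indicates accurate quantification; below 1, underestimation of the
#' oscillation.
#'
#' @param rt real-time [flow_curve()].
#' @param ref reference: a [flow_curve()], a numeric vector sampled like
#'   `rt`, or a function of time (s) evaluated at the `rt` sample times.
#' @param f_resp,f_card component frequencies in Hz.
#' @return object of class `spectral_ratios` with `q_r`, `q_c` and the four
#'   component amplitudes.
#' @export
q_ratios <- function(rt, ref, f_resp, f_card) {
  stopifnot(inherits(rt, "flow_curve"))
  if (is.function(ref)) {
    t <- (seq_along(rt$samples) - 0.5) * rt$dt
    ref <- flow_curve(ref(t), rt$dt)
  } else if (!inherits(ref, "flow_curve")) {
    ref <- flow_curve(as.numeric(ref), rt$dt)
  }
  r_rt <- component_amplitude(rt, f_resp)
  c_rt <- component_amplitude(rt, f_card)
  r_ref <- component_amplitude(ref, f_resp)
  c_ref <- component_amplitude(ref, f_card)
  if (r_ref == 0 || c_ref == 0) stop("reference component amplitude is zero")
  structure(list(q_r = r_rt / r_ref, q_c = c_rt / c_ref,
                 r_rt = r_rt, r_ref = r_ref, c_rt = c_rt, c_ref = c_ref),
            class = "spectral_ratios")
}

#' @export
print.spectral_ratios <- function(x, ...) {
  cat("<spectral_ratios> Q_R = ", format(x$q_r, digits = 3),
      ", Q_C = ", format(x$q_c, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Design the respiratory-isolation FIR low-pass filter
#'
#' Equiripple (Parks-McClellan) FIR meeting the passband/stopband
#' specification at minimum order: all frequencies below `passband` Hz are
#' accepted (ripple `ripple_db`), all frequencies above `stopband` Hz are
#' rejected (`atten_db` single-pass attenuation; the forward-backward
#' application in [lowpass_zero_phase()] doubles this).
#'
#' @param fs sampling rate in Hz (> 2 * `stopband`).
#' @param passband,stopband band edges in Hz (defaults 0.5 and 0.75).
#' @param ripple_db passband ripple in dB (default 0.1).
#' @param atten_db single-pass stopband attenuation in dB (default 20).
#' @return numeric vector of filter taps, with attributes `order`,
#'   `passband_ripple_db`, `stopband_atten_db` (achieved values).
#' @export
design_lowpass_fir <- function(fs, passband = 0.5, stopband = 0.75,
                               ripple_db = 0.1, atten_db = 20) {
  if (fs <= 2 * stopband) stop("sampling rate too low for the stopband edge")
  nyq <- fs / 2
  dp <- 10^(ripple_db / 20) - 1
  ds <- 10^(-atten_db / 20)
  df <- (stopband - passband) / fs
  # Kaiser-Bessel order estimate, then grow until the spec is met
  ord <- ceiling((-20 * log10(sqrt(dp * ds)) - 13) / (14.6 * df))
  ord <- max(6, ord + ord %% 2)       # even order, type-I linear phase
  fgrid <- seq(0, 1, length.out = 1024)
  repeat {
    b <- signal::remez(ord, c(0, passband / nyq, stopband / nyq, 1),
                       c(1, 1, 0, 0), w = c(1, dp / ds))
    H <- Mod(vapply(fgrid, function(f)
      sum(b * exp(-1i * pi * f * (seq_along(b) - 1))), complex(1)))
    pb <- fgrid <= passband / nyq
    sb <- fgrid >= stopband / nyq
    rip <- max(abs(20 * log10(pmax(H[pb], 1e-12))))
    att <- -20 * log10(max(H[sb]))
    if (rip <= ripple_db && att >= atten_db) break
    ord <- ord + 2
    if (ord > 400) stop("FIR design did not meet the specification")
  }
  attr(b, "order") <- ord
  attr(b, "passband_ripple_db") <- rip
  attr(b, "stopband_atten_db") <- att
  b
}

#' Zero-phase low-pass filtering of a flow curve
#'
#' Applies the FIR of [design_lowpass_fir()] twice, the second pass on the
#' time-reversed signal, giving zero phase delay and doubled stopband
#' attenuation (>= 40 dB). Edges are handled by reflect-padding with one
#' filter length. Used to remove (underestimated) cardiac oscillations and
#' isolate the respiratory flow component.
#'
#' @param curve a [flow_curve()].
#' @param passband,stopband,ripple_db,atten_db see [design_lowpass_fir()].
#' @return filtered [flow_curve()]; taps in attribute `filter`.
#' @export
lowpass_zero_phase <- function(curve, passband = 0.5, stopband = 0.75,
                               ripple_db = 0.1, atten_db = 20) {
  stopifnot(inherits(curve, "flow_curve"))
  fs <- 1 / curve$dt
  if (fs <= 2 * stopband)
    stop("sampling rate must exceed ", 2 * stopband, " Hz")
  b <- design_lowpass_fir(fs, passband, stopband, ripple_db, atten_db)
  L <- length(b)
  x <- curve$samples
  if (length(x) < 3 * L)
    stop("curve shorter than 3 filter lengths (", 3 * L, " samples)")
  pass <- function(x) {
    xp <- c(2 * x[1] - rev(x[2:(L + 1)]), x,
            2 * x[length(x)] - rev(x[(length(x) - L):(length(x) - 1)]))
    y <- stats::filter(xp, b, method = "convolution", sides = 2)
    as.numeric(y[(L + 1):(L + length(x))])
  }
  y <- rev(pass(rev(pass(x))))
  out <- flow_curve(y, curve$dt, mean_velocity = curve$mean_velocity)
  attr(out, "filter") <- b
  out
}

#' Cranial, caudal and net flow volumes
#'
#' Frames are separated into positive flow (cranial, toward the head) and
#' negative flow (caudal); each is summed, divided by the scan duration and
#' converted to mL/min. Net flow is the signed sum, so
#' `net = cranial + caudal` exactly.
#'
#' @param curve a [flow_curve()] in mL/s.
#' @return object of class `flow_volumes` with `cranial`, `caudal`, `net`
#'   (mL/min).
#' @export
flow_volumes <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"), length(curve$samples) > 0)
  x <- curve$samples
  dur <- length(x) * curve$dt
  cranial <- sum(pmax(x, 0)) * curve$dt / dur * 60
  caudal <- sum(pmin(x, 0)) * curve$dt / dur * 60
  structure(list(cranial = cranial, caudal = caudal, net = cranial + caudal),
            class = "flow_volumes")
}

#' @export
print.flow_volumes <- function(x, ...) {
  cat("<flow_volumes> cranial ", format(x$cranial, digits = 3),
      ", caudal ", format(x$caudal, digits = 3), ", net ",
      format(x$net, digits = 3), " mL/min\n", sep = "")
  invisible(x)
}

.welch_spectra <- function(x, y, nseg = 8, overlap = 0.5) {
  N <- length(x)
  L <- floor(N / (nseg * (1 - overlap) + overlap))
  if (L < 4) stop("series too short for ", nseg, " Welch segments")
  step <- max(1, floor(L * (1 - overlap)))
  starts <- seq(1, N - L + 1, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))  # Hamming
  pxx <- pyy <- numeric(L)
  pxy <- complex(L)
  for (s in starts) {
    xs <- (x[s:(s + L - 1)] - mean(x[s:(s + L - 1)])) * win
    ys <- (y[s:(s + L - 1)] - mean(y[s:(s + L - 1)])) * win
    X <- fft(xs); Y <- fft(ys)
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  list(pxx = pxx, pyy = pyy, pxy = pxy, L = L, nseg = length(starts))
}

#' Magnitude-squared coherence with the respiratory trace
#'
#' Welch overlapping-periodogram coherence (8 segments, 50% overlap,
#' Hamming window) between the flow curve and a respiratory-bellows signal.
#' The respiratory frequency is taken as the peak of the bellows power
#' spectral density, and the coherence at that frequency (0 = none,
#' 1 = full) is returned.
#'
#' @param flow a [flow_curve()].
#' @param bellows respiratory trace: numeric vector sampled like `flow`, or
#'   a two-column data frame `(time_s, amplitude)` resampled to the flow
#'   rate by linear interpolation.
#' @param fs sampling rate in Hz; defaults to `1/flow$dt`.
#' @return list with `f_resp` (Hz), `coherence` (at `f_resp`), and the full
#'   `freq`/`coh` curves.
#' @export
coherence_at_resp <- function(flow, bellows, fs = NULL) {
  stopifnot(inherits(flow, "flow_curve"))
  if (is.null(fs)) fs <- 1 / flow$dt
  x <- flow$samples
  if (is.data.frame(bellows)) {
    t <- (seq_along(x) - 0.5) / fs
    bellows <- approx(bellows[[1]], bellows[[2]], xout = t, rule = 2)$y
  }
  if (length(bellows) != length(x))
    stop("flow and bellows series must have the same length/rate")
  w <- .welch_spectra(x, bellows)
  coh <- Mod(w$pxy)^2 / pmax(w$pxx * w$pyy, .Machine$double.xmin)
  half <- 2:(floor(w$L / 2))                   # exclude DC and fold
  freq <- (half - 1) * fs / w$L
  i <- half[which.max(w$pyy[half])]
  list(f_resp = (i - 1) * fs / w$L,
       coherence = coh[i],
       freq = freq, coh = coh[half], n_segments = w$nseg)
}
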