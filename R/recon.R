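# Image reconstruction: density-compensated gridding, Walsh coil-map
# estimation, CG-SENSE, compressed sensing with temporal total variation,
# and phase-difference velocity mapping.

#' Reconstruction configuration
#'
#' @param mode one of `"gridding"`, `"cg-sense"`, `"cs"`.
#' @param lambda temporal-TV regularization weight (applied to data
#'   normalized by the largest k-space magnitude); in vivo default 1e-6.
#'   `lambda = 0` with mode `"cs"` is equivalent to CG-SENSE.
#' @param n_iters iteration count (100, the value observed to give
#'   convergence).
#' @return object of class `recon_config`.
#' @export
recon_config <- function(mode = c("cs", "cg-sense", "gridding"),
                         lambda = 1e-6, n_iters = 100) {
  mode <- match.arg(mode)
  if (lambda < 0) stop("lambda must be >= 0")
  if (n_iters < 1) stop("n_iters must be >= 1")
  structure(list(mode = mode, lambda = lambda, n_iters = as.integer(n_iters)),
            class = "recon_config")
}

.spoke_coord_matrix <- function(angles, ns) {
  co <- lapply(angles, spoke_coords, n_samples = ns)
  list(kx = vapply(co, function(m) m[, 1], numeric(ns)),
       ky = vapply(co, function(m) m[, 2], numeric(ns)))
}

.select_encoding <- function(raw, encoding) {
  idx <- switch(encoding,
                plus = which(raw$enc_sign > 0),
                minus = which(raw$enc_sign < 0),
                both = seq_along(raw$enc_sign))
  idx
}

#' Density-compensated gridding reconstruction (one image per coil)
#'
#' Adjoint NUFFT of Ram-Lak density-compensated data, scaled by the polar
#' area element so image values approximate the scene. With all spokes of
#' the acquisition pooled this is the fully-sampled reference used to
#' estimate coil sensitivity maps.
#'
#' @param raw a `radial_kspace` object.
#' @param encoding `"both"` (default; encodings pooled), `"plus"` or
#'   `"minus"`.
#' @return complex array `n x n x n_coils`.
#' @export
gridded_recon <- function(raw, encoding = c("both", "plus", "minus")) {
  stopifnot(inherits(raw, "radial_kspace"))
  encoding <- match.arg(encoding)
  idx <- .select_encoding(raw, encoding)
  n <- raw$matrix_size
  ns <- raw$readout_samples
  nsp <- length(idx)
  w <- ramlak_weights(ns)
  scale <- attr(w, "raw_mean") * (1 / ns) * (pi / nsp)
  co <- .spoke_coord_matrix(raw$angles[idx], ns)
  d <- matrix(raw$data[, idx, , drop = FALSE],
              nrow = ns * nsp)                       # (ns*nsp, nc)
  d <- d * (as.numeric(w) * scale)
  nufft_adjoint(d, cbind(as.numeric(co$kx), as.numeric(co$ky)), n)
}

#' Walsh adaptive coil sensitivity maps
#'
#' Per-pixel dominant eigenvector of the local coil covariance over a
#' sliding window (computed by box filtering of coil-product images and
#' power iteration), normalized so the root sum of squares is 1 everywhere,
#' with the phase referenced to the first coil so maps are smooth.
#'
#' @param coil_images complex array `n x n x n_coils` (e.g. from
#'   [gridded_recon()]).
#' @param window sliding-window side length in pixels (default 8).
#' @return complex array of maps, RSS = 1 at every pixel.
#' @export
walsh_sensitivities <- function(coil_images, window = 8) {
  d <- dim(coil_images)
  stopifnot(length(d) == 3)
  n1 <- d[1]; n2 <- d[2]; nc <- d[3]
  if (window > min(n1, n2)) stop("window larger than image")
  box <- function(m) {
    # sliding-window box sum via cumulative sums (edge-clamped)
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumsum table
    cs <- t(cs)
    h <- window %/% 2
    pad <- function(i, nmax) pmin(pmax(i, 0L), nmax)
    i1 <- pad(seq_len(n1) + h, n1); i0 <- pad(seq_len(n1) - h - 1L, n1)
    j1 <- pad(seq_len(n2) + h, n2); j0 <- pad(seq_len(n2) - h - 1L, n2)
    csp <- rbind(0, cbind(0, cs))  # prepend zero row/col -> 1-based prefix
    csp[i1 + 1L, j1 + 1L] - csp[i0 + 1L, j1 + 1L] -
      csp[i1 + 1L, j0 + 1L] + csp[i0 + 1L, j0 + 1L]
  }
  C <- vector("list", nc * nc)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    prod <- coil_images[, , i] * Conj(coil_images[, , j])
    C[[(i - 1) * nc + j]] <- box(Re(prod)) + 1i * box(Im(prod))
  }
  v <- coil_images  # initialize with the coil images themselves
  for (iter in 1:15) {
    vn <- array(0i, dim = d)
    for (i in seq_len(nc)) {
      acc <- 0i
      for (j in seq_len(nc)) acc <- acc + C[[(i - 1) * nc + j]] * v[, , j]
      vn[, , i] <- acc
    }
    rss <- sqrt(Reduce(`+`, lapply(seq_len(nc), function(c) Mod(vn[, , c])^2)))
    rss[rss == 0] <- 1
    for (i in seq_len(nc)) vn[, , i] <- vn[, , i] / rss
    v <- vn
  }
  ref <- Arg(v[, , 1])
  for (i in seq_len(nc)) v[, , i] <- v[, , i] * exp(-1i * ref)
  v
}

.frame_coords <- function(raw, encoding) {
  idx <- .select_encoding(raw, encoding)
  fb <- frame_bins(length(idx), raw$spokes_per_frame, raw$tr)
  ns <- raw$readout_samples
  spf <- raw$spokes_per_frame
  nF <- fb$n_frames
  kx <- matrix(0, ns * spf, nF)
  ky <- matrix(0, ns * spf, nF)
  dat <- array(0i, dim = c(ns * spf, dim(raw$data)[3], nF))
  for (f in seq_len(nF)) {
    sp <- idx[which(fb$frame == f)]
    co <- .spoke_coord_matrix(raw$angles[sp], ns)
    kx[, f] <- as.numeric(co$kx)
    ky[, f] <- as.numeric(co$ky)
    dat[, , f] <- matrix(raw$data[, sp, , drop = FALSE], nrow = ns * spf)
  }
  list(kx = kx, ky = ky, data = dat, bins = fb)
}

.image_series <- function(x, times, pixel_mm, encoding, diagnostics = NULL) {
  structure(list(data = x, times = times, pixel_mm = pixel_mm,
                 encoding = encoding, diagnostics = diagnostics),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_series> ", d[1], "x", d[2], " px, ", d[3], " frames (dt ",
      format(if (d[3] > 1) diff(x$times)[1] else NA, digits = 4),
      " s), encoding ", x$encoding, "\n", sep = "")
  invisible(x)
}

.recon_result <- function(plus, minus, mode, lambda, n_iters, venc) {
  structure(list(plus = plus, minus = minus, mode = mode, lambda = lambda,
                 n_iters = n_iters, venc = venc), class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat("<recon_result> mode ", x$mode,
      if (x$mode == "cs") paste0(" (lambda ", format(x$lambda), ")"),
      ", ", dim(x$plus$data)[3], " frames\n", sep = "")
  invisible(x)
}

#' CG-SENSE reconstruction
#'
#' Per-frame least-squares solution of `||W^(1/2)(F_r S x - d)||_2^2` by
#' conjugate gradients on the normal equations (zero initialization,
#' square-root density weighting as k-space preconditioner). Each velocity
#' encoding is reconstructed separately.
#'
#' @param raw a `radial_kspace` object (preprocessed).
#' @param maps coil sensitivity maps `n x n x n_coils`.
#' @param n_iters maximum CG iterations per frame.
#' @param tol early-stopping tolerance on the relative normal-equation
#'   residual.
#' @param encoding `"both"` (default), `"plus"` or `"minus"`.
#' @return a `recon_result` (both encodings) or a single `image_series`.
#' @export
cg_sense <- function(raw, maps, n_iters = 100, tol = 1e-6,
                     encoding = c("both", "plus", "minus")) {
  stopifnot(inherits(raw, "radial_kspace"))
  encoding <- match.arg(encoding)
  n <- raw$matrix_size
  nc <- dim(maps)[3]
  stopifnot(dim(raw$data)[3] == nc)
  sq <- sqrt(ramlak_weights(raw$readout_samples))
  one <- function(enc) {
    fr <- .frame_coords(raw, enc)
    sw <- rep(sq, raw$spokes_per_frame)
    res <- cpp_cg_sense(fr$data, fr$kx, fr$ky, as.complex(maps), sw,
                        as.integer(n), as.integer(nc),
                        as.integer(dim(fr$data)[3]), .nufft_os, .nufft_width,
                        as.integer(n_iters), tol)
    if (any(res$relres > 1e3))
      stop("CG-SENSE diverged (relative residual ",
           format(max(res$relres)), ")")
    .image_series(res$x, fr$bins$timestamps_s, raw$pixel_mm, enc,
                  diagnostics = list(iters = res$iters, relres = res$relres))
  }
  if (encoding != "both") return(one(encoding))
  .recon_result(one("plus"), one("minus"), "cg-sense", 0, n_iters, raw$venc)
}

#' Compressed-sensing reconstruction with temporal total variation
#'
#' Approximate minimizer of
#' `||W^(1/2)(F_r S x - d)||_2^2 + lambda ||T x||_1`, with `T` the
#' first-order (non-periodic) temporal finite difference, solved by
#' monotone FISTA with an exact taut-string TV prox applied per pixel to
#' the real and imaginary parts. Frames are reconstructed jointly (the
#' temporal term couples them); each velocity encoding is reconstructed
#' separately. `lambda` refers to data normalized by the largest k-space
#' magnitude (see [normalize_kspace()]).
#'
#' @inheritParams cg_sense
#' @param lambda regularization weight (>= 0).
#' @return a `recon_result` (both encodings) or a single `image_series`
#'   whose `diagnostics` carry the (non-increasing) objective trace.
#' @export
cs_temporal_tv <- function(raw, maps, lambda = 1e-6, n_iters = 100,
                           encoding = c("both", "plus", "minus")) {
  stopifnot(inherits(raw, "radial_kspace"))
  if (lambda < 0) stop("lambda must be >= 0")
  encoding <- match.arg(encoding)
  n <- raw$matrix_size
  nc <- dim(maps)[3]
  sq <- sqrt(ramlak_weights(raw$readout_samples))
  one <- function(enc) {
    fr <- .frame_coords(raw, enc)
    if (dim(fr$data)[3] < 2 && lambda > 0)
      stop("temporal TV needs at least 2 frames")
    sw <- rep(sq, raw$spokes_per_frame)
    res <- cpp_cs_tv(fr$data, fr$kx, fr$ky, as.complex(maps), sw,
                     as.integer(n), as.integer(nc),
                     as.integer(dim(fr$data)[3]), .nufft_os, .nufft_width,
                     lambda, as.integer(n_iters))
    .image_series(res$x, fr$bins$timestamps_s, raw$pixel_mm, enc,
                  diagnostics = list(objective = res$objective,
                                     lipschitz = res$lipschitz))
  }
  if (encoding != "both") return(one(encoding))
  .recon_result(one("plus"), one("minus"), "cs", lambda, n_iters, raw$venc)
}

#' Phase-difference velocity mapping by complex division
#'
#' `v = Arg(x_plus * Conj(x_minus)) * venc / pi` per pixel and frame, with
#' magnitude `|x_plus * Conj(x_minus)|^(1/2)` retained for ROI work. No
#' velocity anti-aliasing is performed, so `|v| <= venc` by construction.
#'
#' @param x_plus,x_minus `image_series` for the two encodings, or a single
#'   `recon_result` passed as `x_plus`.
#' @param venc velocity encoding in cm/s.
#' @return object of class `velocity_series`: `velocity` (cm/s,
#'   `n x n x frames`), `magnitude`, `times`, `venc`, `pixel_mm`.
#' @export
velocity_map <- function(x_plus, x_minus = NULL, venc = NULL) {
  if (inherits(x_plus, "recon_result")) {
    if (is.null(venc)) venc <- x_plus$venc
    x_minus <- x_plus$minus
    x_plus <- x_plus$plus
  }
  stopifnot(inherits(x_plus, "image_series"), inherits(x_minus, "image_series"),
            !is.null(venc))
  if (!identical(dim(x_plus$data), dim(x_minus$data)))
    stop("encoding image series have mismatched shapes")
  z <- x_plus$data * Conj(x_minus$data)
  structure(list(velocity = Arg(z) * venc / pi,
                 magnitude = sqrt(Mod(z)),
                 times = x_plus$times, venc = venc,
                 pixel_mm = x_plus$pixel_mm),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$velocity)
  cat("<velocity_series> ", d[1], "x", d[2], " px, ", d[3],
      " frames, VENC ", x$venc, " cm/s\n", sep = "")
  invisible(x)
}

#' @export
plot.velocity_series <- function(x, frame = 1, what = c("velocity", "magnitude"),
                                 ...) {
  what <- match.arg(what)
  m <- x[[what]][, , frame]
  graphics::image(t(m)[, rev(seq_len(nrow(m)))], asp = 1, axes = FALSE,
                  main = paste0(what, ", frame ", frame,
                                " (t = ", format(x$times[frame], digits = 3),
                                " s)"),
                  col = grDevices::hcl.colors(
                    64, if (what == "velocity") "Blue-Red 3" else "Grays"),
                  ...)
  invisible(x)
}
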