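# R-level interface to the Kaiser-Bessel gridding NUFFT and the
# coil-weighted radial encoding operator (F_r S of the reconstruction
# model).

.nufft_os <- 1.25
.nufft_width <- 4L

#' Nonuniform Fourier transform (type 2): image to radial samples
#'
#' Evaluates `F(k) = sum_p x(p) exp(-2 pi i k . p)` (pixel positions `p`
#' centred on the image, `k` in cycles/pixel) by Kaiser-Bessel gridding on a
#' 1.25x oversampled FFTW grid, kernel width 4.
#'
#' @param img complex matrix `n x n`, or array `n x n x n_coils`.
#' @param coords two-column matrix (kx, ky) in cycles/pixel.
#' @return complex matrix `nrow(coords) x n_coils`.
#' @export
nufft_forward <- function(img, coords) {
  d <- dim(img)
  nc <- if (length(d) == 3) d[3] else 1L
  stopifnot(d[1] == d[2])
  cpp_nufft_forward(as.complex(img), coords[, 1], coords[, 2],
                    as.integer(d[1]), as.integer(nc), .nufft_os, .nufft_width)
}

#' Adjoint nonuniform Fourier transform (type 1): samples to image
#'
#' Exact algebraic adjoint of [nufft_forward()] (spread + inverse FFT +
#' deapodization). Apply density-compensation weights to the samples first
#' to use it as an approximate inverse (gridding reconstruction).
#'
#' @param samples complex matrix `M x n_coils` (a vector is treated as one
#'   coil).
#' @param coords two-column matrix (kx, ky) in cycles/pixel.
#' @param n output image size in pixels.
#' @return complex array `n x n x n_coils`.
#' @export
nufft_adjoint <- function(samples, coords, n) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  nc <- ncol(samples)
  cpp_nufft_adjoint(samples, coords[, 1], coords[, 2], as.integer(n),
                    as.integer(nc), .nufft_os, .nufft_width)
}

#' Radial encoding operator for one time frame
#'
#' Realizes `E = W^(1/2) F_r S`: coil-map multiplication, radial NUFFT and
#' square-root density weighting, together with its exact adjoint. This is
#' the operator whose normal equations CG-SENSE solves. Double precision;
#' `forward` maps an `n x n` image to an `M x n_coils` sample matrix and
#' `adjoint` maps back.
#'
#' @param coords two-column matrix (kx, ky), M rows.
#' @param maps complex coil maps `n x n x n_coils`.
#' @param dcf density-compensation weights (length M); internally the
#'   square root is applied on both sides. Use `rep(1, M)` for an
#'   unweighted operator.
#' @return object of class `encoding_operator` with elements `forward`,
#'   `adjoint`, `n`, `n_coils`, `M`.
#' @export
encoding_operator <- function(coords, maps, dcf) {
  d <- dim(maps)
  stopifnot(length(d) == 3, d[1] == d[2], nrow(coords) == length(dcf))
  n <- d[1]; nc <- d[3]
  sq <- sqrt(dcf)
  kx <- coords[, 1]; ky <- coords[, 2]
  structure(list(
    forward = function(x)
      cpp_op_forward(as.complex(x), as.complex(maps), sq, kx, ky,
                     as.integer(n), as.integer(nc), .nufft_os, .nufft_width),
    adjoint = function(y)
      cpp_op_adjoint(y, as.complex(maps), sq, kx, ky, as.integer(n),
                     as.integer(nc), .nufft_os, .nufft_width),
    n = n, n_coils = nc, M = nrow(coords)),
    class = "encoding_operator")
}

#' Adjoint-consistency check of an encoding operator
#'
#' Computes the worst relative mismatch of `<A x, y>` and `<x, A^H y>` over
#' random draws; a correct adjoint pair agrees to near machine precision.
#'
#' @param op an [encoding_operator()].
#' @param n_trials number of random draws.
#' @param seed RNG seed.
#' @return maximum relative mismatch (numeric scalar).
#' @export
adjoint_mismatch <- function(op, n_trials = 5, seed = 1) {
  stopifnot(inherits(op, "encoding_operator"))
  set.seed(seed)
  worst <- 0
  for (i in seq_len(n_trials)) {
    x <- matrix(complex(real = rnorm(op$n^2), imaginary = rnorm(op$n^2)),
                op$n, op$n)
    y <- matrix(complex(real = rnorm(op$M * op$n_coils),
                        imaginary = rnorm(op$M * op$n_coils)),
                op$M, op$n_coils)
    ax <- op$forward(x)
    ahy <- op$adjoint(y)
    lhs <- sum(ax * Conj(y))
    rhs <- sum(x * Conj(ahy))
    worst <- max(worst, Mod(lhs - rhs) / max(Mod(lhs), Mod(rhs), 1e-300))
  }
  worst
}

#' Exact 1D total-variation denoising (taut string)
#'
#' Solves `argmin_u 0.5 ||u - y||^2 + lam * sum |u[i+1] - u[i]|` exactly.
#' This is the proximal operator used per pixel (real and imaginary parts
#' separately) by the temporal-TV compressed-sensing solver; exported for
#' direct use and testing.
#'
#' @param y numeric vector.
#' @param lam nonnegative penalty weight.
#' @return denoised numeric vector.
#' @export
tv_denoise <- function(y, lam) {
  stopifnot(lam >= 0)
  cpp_tv_denoise(as.numeric(y), lam)
}
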