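shift_spoke <- function(col, delta) {
  ns <- length(col)
  fx <- c(0:(ns / 2 - 1), -(ns / 2):-1)
  fft(fft(col) * exp(-2i * pi * delta * fx / ns), inverse = TRUE) / ns
}

test_that("echo-shift estimation recovers injected sub-sample shifts", {
  st <- tiny_static()
  ks0 <- st$ks
  ks <- ks0
  for (delta in c(0.3, -0.55, 1)) {
    ks$data[, 7, 1] <- shift_spoke(ks0$data[, 7, 1], delta)
    kc <- correct_echo_shifts(ks)
    expect_lt(abs(attr(kc, "echo_shifts")[7] - delta), 0.01)
    # round trip: correct(shift(s, delta)) ~ s
    expect_lt(max(Mod(kc$data[, 7, 1] - ks0$data[, 7, 1])),
              0.02 * max(Mod(ks0$data[, 7, 1])))
  }
})

test_that("already-centred spokes and all-zero spokes are left unchanged", {
  ns <- 64
  x <- exp(-((seq_len(ns) - 1 - ns / 2) / 6)^2)   # symmetric echo
  ks <- structure(list(data = array(as.complex(x), c(ns, 2, 1)),
                       angles = c(0, 0), times = c(0, 1), enc_sign = c(1, -1),
                       venc = 15, tr = 10.5, spokes_per_frame = 1L,
                       readout_samples = ns, matrix_size = ns, fov = 64,
                       pixel_mm = 1, scale = 1, meta = list()),
                  class = "radial_kspace")
  kc <- correct_echo_shifts(ks)
  expect_lt(max(Mod(kc$data - ks$data)), 1e-10)
  ks$data[, 2, 1] <- 0i
  expect_equal(correct_echo_shifts(ks)$data[, 2, 1], ks$data[, 2, 1])
})

test_that("zeroth-order correction aligns k = 0 phases and preserves spectra", {
  st <- tiny_static()
  ks <- st$ks
  set.seed(5)
  ph <- runif(dim(ks$data)[2], -pi, pi)
  ks$data <- ks$data * rep(exp(1i * ph), each = dim(ks$data)[1])
  kc <- correct_zeroth_order(ks)
  c0 <- ks$readout_samples %/% 2 + 1
  for (e in c(1, -1)) {
    phases <- Arg(kc$data[c0, kc$enc_sign == e, 1])
    expect_lt(diff(range(phases)), 1e-10)
  }
  expect_equal(Mod(kc$data), Mod(ks$data), tolerance = 1e-12)
  # pristine static data (all spokes share the k = 0 phase) is unchanged
  k0 <- correct_zeroth_order(st$ks)
  expect_lt(max(Mod(k0$data - st$ks$data)), 1e-10 * max(Mod(st$ks$data)))
})

test_that("normalization scales to unit maximum and is idempotent in effect", {
  ts <- tiny_ks()
  k1 <- normalize_kspace(ts$ks)
  expect_equal(max(Mod(k1$data)), 1)
  k7 <- ts$ks
  k7$data <- k7$data * 7
  k7n <- normalize_kspace(k7)
  expect_equal(k7n$data, k1$data, tolerance = 1e-12)
  expect_equal(k7n$scale / k1$scale, 7, tolerance = 1e-12)
  kz <- ts$ks
  kz$data[] <- 0i
  expect_error(normalize_kspace(kz), "all-zero")
})

test_that("coil compression preserves energy and finds rank-1 structure", {
  ts <- tiny_ks()
  ks <- ts$ks
  full <- compress_coils(ks, 8)
  e0 <- sum(Mod(ks$data)^2)
  expect_lt(abs(sum(Mod(full$data)^2) - e0) / e0, 1e-10)
  A <- attr(full, "compression_matrix")
  expect_equal(A %*% Conj(t(A)), diag(8) + 0i, tolerance = 1e-10)
  # rank-1 coil structure: all coils proportional
  r1 <- ks
  for (c in 1:8) r1$data[, , c] <- ks$data[, , 1] * (c * exp(1i * c))
  r1c <- compress_coils(r1, 8)
  en <- apply(Mod(r1c$data)^2, 3, sum)
  expect_gt(en[1] / sum(en), 0.9999)
  expect_error(compress_coils(ks, 9), "exceeds")
})
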