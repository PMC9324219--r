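test_that("Walsh maps: uniform coil, normalization, and recovery of known maps", {
  st <- tiny_static()
  # single uniform coil
  one <- gridded_recon(st$ks, "both")
  w1 <- walsh_sensitivities(one)
  sup <- st$scene$support_mask
  expect_equal(Mod(w1[, , 1])[sup], rep(1, sum(sup)))
  # known synthetic maps recovered up to the RSS-invariant ambiguity
  ts <- tiny_ks()
  pc <- gridded_recon(normalize_kspace(ts$ks), "both")
  wm <- walsh_sensitivities(pc)
  rss <- sqrt(apply(Mod(wm)^2, 1:2, sum))
  expect_equal(range(rss), c(1, 1), tolerance = 1e-6)
  true_rss <- sqrt(apply(Mod(ts$maps)^2, 1:2, sum))
  err <- abs(Mod(wm[, , 4]) - Mod(ts$maps[, , 4]) / true_rss)
  inner <- sup & (Mod(ts$scene$image) > 0.05)
  expect_lt(stats::quantile(err[inner], 0.9), 0.05)
  expect_error(walsh_sensitivities(pc, window = 200), "window larger")
})

test_that("CG-SENSE recovers a band-limited scene from well-sampled data", {
  # a scene band-limited to the sampled k-space disc is exactly recoverable;
  # comparing against it isolates solver correctness from Gibbs ringing
  st <- tiny_static()
  scene <- st$scene
  scene$image <- bandlimit_disc(scene$image)
  ks <- normalize_kspace(simulate_kspace(scene, function(t) 0 * t, NULL,
                                         st$cfgs$acq))
  maps <- array(1 + 0i, c(96, 96, 1))
  wide <- ks
  wide$spokes_per_frame <- 250L   # well-sampled single-frame recon
  rec <- cg_sense(wide, maps, n_iters = 300, tol = 1e-8, encoding = "plus")
  expect_lt(nrmse(rec$data[, , 1], scene$image / ks$scale,
                  st$scene$support_mask), 0.02)
  # zero data -> zero solution
  kz <- ks
  kz$data[] <- 0i
  rz <- cg_sense(kz, maps, n_iters = 5, encoding = "plus")
  expect_equal(max(Mod(rz$data)), 0)
})

test_that("CG-SENSE data residual decreases monotonically with iterations", {
  ts <- tiny_ks()
  ks <- normalize_kspace(ts$ks)
  small <- ks
  keep <- 1:16                                 # one frame per encoding
  small$data <- ks$data[, keep, , drop = FALSE]
  small$angles <- ks$angles[keep]
  small$times <- ks$times[keep]
  small$enc_sign <- ks$enc_sign[keep]
  resid <- vapply(c(1, 3, 8, 20), function(it) {
    rec <- cg_sense(small, ts$maps, n_iters = it, tol = 0, encoding = "plus")
    x <- rec$data[, , 1]
    co <- do.call(rbind, lapply(small$angles[small$enc_sign > 0][1:8],
                                spoke_coords, n_samples = 96))
    dcf <- rep(as.numeric(ramlak_weights(96)), 8)
    op <- encoding_operator(co, ts$maps, dcf)
    d <- matrix(small$data[, small$enc_sign > 0, ], nrow = 96 * 8)
    sqrt(sum(Mod(op$forward(x) - d * sqrt(dcf))^2))
  }, numeric(1))
  expect_true(all(diff(resid) < 0))
})

test_that("temporal-TV prox is exact and the solver objective is monotone", {
  set.seed(21)
  for (trial in 1:25) {
    N <- sample(2:15, 1)
    y <- rnorm(N) * sample(c(0.1, 1, 10), 1)
    lam <- stats::runif(1) * sample(c(0.02, 0.5, 3), 1)
    a <- tv_denoise(y, lam)
    b <- tv_oracle(y, lam)
    fa <- 0.5 * sum((a - y)^2) + lam * sum(abs(diff(a)))
    fb <- 0.5 * sum((b - y)^2) + lam * sum(abs(diff(b)))
    expect_lte(fa, fb + 1e-8)
  }
  expect_equal(tv_denoise(1:6, 0), as.numeric(1:6))
  expect_lt(max(abs(diff(tv_denoise(rnorm(60), 1e7)))), 1e-12)

  ts <- tiny_ks()
  ks <- normalize_kspace(ts$ks)
  small <- ks
  keep <- 1:80                                 # 5 frames
  small$data <- ks$data[, keep, , drop = FALSE]
  small$angles <- ks$angles[keep]
  small$times <- ks$times[keep]
  small$enc_sign <- ks$enc_sign[keep]
  rec <- cs_temporal_tv(small, ts$maps, lambda = 1e-4, n_iters = 40,
                        encoding = "plus")
  obj <- rec$diagnostics$objective
  expect_true(all(diff(obj) <= 1e-6 * obj[1]))
})

test_that("CS with lambda = 0 agrees with CG-SENSE; huge lambda freezes time", {
  # at lambda = 0 the two solvers minimize the same objective; compare them
  # near convergence on a well-conditioned two-frame problem
  st <- tiny_static()
  ks <- normalize_kspace(st$ks)
  maps <- array(1 + 0i, c(96, 96, 1))
  wide2 <- ks
  wide2$spokes_per_frame <- 125L
  cg <- cg_sense(wide2, maps, n_iters = 300, tol = 1e-10, encoding = "plus")
  cs0 <- cs_temporal_tv(wide2, maps, lambda = 0, n_iters = 600,
                        encoding = "plus")
  expect_lt(nrmse(cs0$data, cg$data), 0.01)
  # very large lambda: temporal variation collapses
  ts <- tiny_ks()
  ksf <- normalize_kspace(ts$ks)
  small <- ksf
  keep <- 1:80
  small$data <- ksf$data[, keep, , drop = FALSE]
  small$angles <- ksf$angles[keep]
  small$times <- ksf$times[keep]
  small$enc_sign <- ksf$enc_sign[keep]
  tvnorm <- function(x) sum(abs(Re(apply(x, 1:2, diff)))) +
    sum(abs(Im(apply(x, 1:2, diff))))
  csref <- cs_temporal_tv(small, ts$maps, lambda = 0, n_iters = 60,
                          encoding = "plus")
  cshuge <- cs_temporal_tv(small, ts$maps, lambda = 1e3, n_iters = 30,
                           encoding = "plus")
  expect_lt(tvnorm(cshuge$data), 1e-3 * tvnorm(csref$data))
  expect_error(cs_temporal_tv(small, ts$maps, lambda = -1), "lambda")
})

test_that("complex division yields the encoded velocity", {
  ts <- tiny_ks()
  # x_plus = x_minus -> v = 0; delta phi = pi -> v = venc
  a <- aqueflow:::.image_series(array(1i, c(4, 4, 2)), c(0.1, 0.2), 1, "plus")
  b <- aqueflow:::.image_series(array(1i, c(4, 4, 2)), c(0.1, 0.2), 1, "minus")
  v0 <- velocity_map(a, b, venc = 15)
  expect_equal(max(abs(v0$velocity)), 0)
  b2 <- b
  b2$data <- b$data * exp(-1i * (pi - 1e-9))
  expect_equal(velocity_map(a, b2, venc = 15)$velocity[1, 1, 1], 15,
               tolerance = 1e-6)
  # programmed constant 5 cm/s recovered within 5% (fully-sampled gridding)
  st <- tiny_static()
  ksc <- simulate_kspace(st$scene, function(t) rep(5, length(t)),
                         NULL, st$cfgs$acq)
  wide <- ksc
  wide$spokes_per_frame <- 250L
  maps1 <- array(1 + 0i, c(96, 96, 1))
  rec <- lapply(c("plus", "minus"), function(enc)
    cg_sense(wide, maps1, n_iters = 15, encoding = enc))
  vel <- velocity_map(rec[[1]], rec[[2]], venc = 15)
  vmean <- mean(vel$velocity[, , 1][st$scene$aqueduct_mask])
  expect_lt(abs(vmean - 5), 0.25)
  expect_error(velocity_map(a, aqueflow:::.image_series(
    array(1i, c(4, 4, 3)), 1:3, 1, "minus"), venc = 15), "mismatched")
})
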