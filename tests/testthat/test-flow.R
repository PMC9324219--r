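make_vs <- function(v, dt = 0.168, pixel_mm = 0.8, venc = 15) {
  structure(list(velocity = v, magnitude = array(1, dim(v)),
                 times = (seq_len(dim(v)[3]) - 0.5) * dt, venc = venc,
                 pixel_mm = pixel_mm),
            class = "velocity_series")
}

test_that("background phase correction recovers an injected plane exactly", {
  n <- 48
  xg <- matrix(seq_len(n) - 1, n, n)
  yg <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  plane <- 0.3 + 0.01 * xg - 0.02 * yg
  v <- array(0, c(n, n, 3))
  for (f in 1:3) v[, , f] <- plane * f
  vs <- make_vs(v)
  mask <- matrix(FALSE, n, n)
  mask[seq(2, n, 3), seq(1, n, 4)] <- TRUE
  out <- background_phase_correct(vs, mask)
  expect_lt(max(abs(out$velocity)), 1e-9)
  B <- attr(out, "plane_coefficients")
  expect_equal(B[, 2], c(0.6, 0.02, -0.04), tolerance = 1e-6)
  # zero field unchanged; too few pixels error
  vz <- make_vs(array(0, c(n, n, 2)))
  expect_equal(background_phase_correct(vz, mask)$velocity, vz$velocity)
  m2 <- matrix(FALSE, n, n); m2[1, 1:2] <- TRUE
  expect_error(background_phase_correct(vs, m2), "3 static pixels")
})

test_that("ROI flow converts velocity times area to mL/s", {
  v <- array(0, c(8, 8, 2))
  v[3, 4, ] <- 15
  m <- matrix(FALSE, 8, 8); m[3, 4] <- TRUE
  fc <- roi_flow(make_vs(v, pixel_mm = 0.6), m)   # 0.36 mm^2 at 15 cm/s
  expect_equal(fc$samples, c(0.054, 0.054))
  expect_equal(roi_flow(make_vs(array(0, c(8, 8, 2))), m)$samples, c(0, 0))
  expect_error(roi_flow(make_vs(v), matrix(FALSE, 8, 8)), "empty ROI")
  # simulated disc at uniform 1 cm/s: flow ~ disc area within one pixel
  ts <- tiny_ks()
  mask <- ts$scene$aqueduct_mask
  v2 <- array(0, c(96, 96, 1))
  v2[, , 1][mask] <- 1
  f2 <- roi_flow(make_vs(v2, pixel_mm = 0.8), mask)
  expect_lt(abs(f2$samples - pi * 1.25^2 * 1e-2), 0.8^2 * 1e-2 * 2)
})

test_that("ROI tracking recovers injected shifts and honours radius 0", {
  set.seed(9)
  n <- 40
  base <- matrix(rnorm(n * n), n, n)
  base[18:22, 24:28] <- base[18:22, 24:28] + 6
  mag <- array(0, c(n, n, 4))
  mag[, , 1] <- base
  mag[, , 2] <- base                       # static
  sh <- function(m, dx, dy) m[((seq_len(n) - 1 - dx) %% n) + 1,
                              ((seq_len(n) - 1 - dy) %% n) + 1]
  mag[, , 3] <- sh(base, 2, -1)
  mag[, , 4] <- sh(base, -3, 3)
  mask <- matrix(FALSE, n, n); mask[18:22, 24:28] <- TRUE
  tr <- track_roi(mag, mask, search_radius = 4)
  expect_equal(tr$shifts[2, ], c(0L, 0L))
  expect_equal(tr$shifts[3, ], c(2L, -1L))
  expect_equal(tr$shifts[4, ], c(-3L, 3L))
  expect_equal(tr$masks[, , 3], sh(mask, 2, -1))
  tr0 <- track_roi(mag, mask, search_radius = 0)
  expect_true(all(apply(tr0$masks, 3, identical, mask)))
})

test_that("FFT component amplitudes are exact on-bin and close off-bin", {
  dt <- 0.168
  t <- (0:118 + 0.5) * dt
  # exact bin: 0.25 Hz is bin 5 of a 20 s window -> use 20/0.168 grid
  N <- 125
  t2 <- (seq_len(N) - 0.5) * 0.16          # 20 s, 0.25 Hz = bin 5 exactly
  x <- 3 * sin(2 * pi * 0.25 * t2 + 0.7)
  expect_equal(component_amplitude(flow_curve(x, 0.16), 0.25), 3,
               tolerance = 1e-9)
  expect_equal(component_amplitude(flow_curve(rep(0, N), 0.16), 0.25), 0)
  # two components, generic timing: recovered within 5%
  y <- 2 * sin(2 * pi * 0.25 * t) + 1 * sin(2 * pi * 1 * t + 1)
  expect_lt(abs(component_amplitude(flow_curve(y, dt), 0.25) - 2) / 2, 0.05)
  expect_lt(abs(component_amplitude(flow_curve(y, dt), 1) - 1), 0.05)
  expect_error(component_amplitude(flow_curve(y, dt), 3), "Nyquist")
  expect_error(component_amplitude(flow_curve(y[1:20], dt), 0.25),
               "two periods")
})

test_that("Q ratios: identity, linearity, and scale invariance", {
  dt <- 0.168
  t <- (0:118 + 0.5) * dt
  f <- flow_curve(2 * sin(2 * pi * 0.25 * t) + sin(2 * pi * t), dt)
  q1 <- q_ratios(f, f, 0.25, 1)
  expect_equal(q1$q_r, 1, tolerance = 1e-12)
  expect_equal(q1$q_c, 1, tolerance = 1e-12)
  half <- flow_curve(f$samples / 2, dt)
  q2 <- q_ratios(half, f, 0.25, 1)
  expect_equal(q2$q_r, 0.5, tolerance = 1e-12)
  expect_equal(q2$q_c, 0.5, tolerance = 1e-12)
  # common scaling of both signals cancels
  fs <- flow_curve(f$samples * 13, dt)
  hs <- flow_curve(half$samples * 13, dt)
  q3 <- q_ratios(hs, fs, 0.25, 1)
  expect_equal(q3$q_r, q2$q_r, tolerance = 1e-12)
  expect_error(q_ratios(f, flow_curve(rep(0, 119), dt), 0.25, 1),
               "reference component amplitude")
})

test_that("the zero-phase FIR meets its band specification", {
  dt <- 0.168
  b <- design_lowpass_fir(1 / dt)
  expect_lte(attr(b, "passband_ripple_db"), 0.1)
  expect_gte(attr(b, "stopband_atten_db"), 20)
  N <- 600
  t <- (seq_len(N) - 0.5) * dt
  # DC gain within the 0.1 dB ripple
  dcin <- flow_curve(rep(1, N), dt)
  expect_lt(max(abs(lowpass_zero_phase(dcin)$samples - 1)),
            10^(0.2 / 20) - 1 + 1e-3)      # ripple doubles over the two passes
  # 1 Hz attenuated by >= 40 dB after the double pass
  s1 <- flow_curve(sin(2 * pi * 1 * t), dt)
  out1 <- lowpass_zero_phase(s1)$samples[100:500]
  expect_lt(max(abs(out1)), 10^(-40 / 20))
  # zero phase: 0.2 Hz sinusoid peaks at lag 0
  s2 <- flow_curve(sin(2 * pi * 0.2 * t), dt)
  out2 <- lowpass_zero_phase(s2)$samples
  cc <- vapply(-3:3, function(l)
    sum(out2[(51 + l):(550 + l)] * s2$samples[51:550]), numeric(1))
  expect_equal(which.max(cc), 4)           # lag 0
  # sum of 0.25 + 1 Hz: the slow component comes back within 2%
  mix <- flow_curve(sin(2 * pi * 0.25 * t) + sin(2 * pi * t), dt)
  got <- lowpass_zero_phase(mix)$samples
  want <- sin(2 * pi * 0.25 * t)
  expect_lt(max(abs(got - want)[50:550]), 0.02)
  expect_error(lowpass_zero_phase(flow_curve(rep(0, 20), dt)),
               "3 filter lengths")
  expect_error(lowpass_zero_phase(flow_curve(rep(0, 600), 1)),
               "sampling rate")
})

test_that("flow volumes integrate signed flow per unit time", {
  fc <- flow_curve(rep(1, 50), 0.1)
  fv <- flow_volumes(fc)
  expect_equal(c(fv$cranial, fv$caudal, fv$net), c(60, 0, 60))
  # zero-mean sinusoid over whole periods
  t <- (0:199 + 0.5) * 0.1
  fs <- flow_curve(sin(2 * pi * 0.2 * t), 0.1)
  expect_lt(abs(flow_volumes(fs)$net), 1e-9)
  # offset sinusoid against a brute-force quadrature oracle
  x <- sin(2 * pi * t / 4) + 0.2
  fo <- flow_volumes(flow_curve(x, 0.1))
  expect_equal(fo$net, 0.2 * 60, tolerance = 1e-9)
  oracle_cranial <- sum(pmax(x, 0)) * 0.1 / 20 * 60
  expect_equal(fo$cranial, oracle_cranial)
  expect_equal(fo$net, fo$cranial + fo$caudal, tolerance = 1e-12)
})

test_that("coherence at the respiratory peak behaves as a coherence should", {
  dt <- 0.168
  N <- 300
  t <- (seq_len(N) - 0.5) * dt
  set.seed(2)
  fl <- flow_curve(sin(2 * pi * 0.22 * t) + 0.3 * rnorm(N), dt)
  # scaled copy: coherence 1
  co <- coherence_at_resp(fl, 2 * fl$samples)
  expect_equal(co$coherence, 1, tolerance = 1e-9)
  expect_true(all(co$coh >= 0 & co$coh <= 1 + 1e-12))
  expect_lt(abs(co$f_resp - 0.22), 0.05)
  # independent signals: low coherence at the bellows peak
  vals <- vapply(1:6, function(s) {
    set.seed(100 + s)
    a <- flow_curve(rnorm(N), dt)
    b <- rnorm(N)
    coherence_at_resp(a, b)$coherence
  }, numeric(1))
  expect_lt(mean(vals), 0.5)
  # bellows as (time, amplitude) data frame is resampled
  df <- data.frame(time_s = seq(0, 60, by = 0.05),
                   amplitude = sin(2 * pi * 0.22 * seq(0, 60, by = 0.05)))
  co2 <- coherence_at_resp(fl, df)
  expect_gt(co2$coherence, 0.8)
  expect_error(coherence_at_resp(flow_curve(rnorm(10), dt), rnorm(10)),
               "too short")
})
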