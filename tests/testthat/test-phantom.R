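test_that("aqueduct disc rendering matches exhaustive pixel-centre counting", {
  # 2.5 mm disc, 0.6 mm pixels: area pi * (2.5/0.6/2)^2 = 13.6 px
  cfg <- phantom_config(matrix_size = 400, fov = 240, aqueduct_diameter = 2.5,
                        aqueduct_center = c(0, -20))
  sc <- build_scene(cfg)
  n <- 400; px <- 240 / 400
  pos <- (seq_len(n) - 1 - n / 2) * px
  cnt <- 0L
  for (i in seq_len(n)) {
    d2 <- (pos[i] - 0)^2 + (pos - (-20))^2
    cnt <- cnt + sum(d2 <= 1.25^2)
  }
  expect_equal(sum(sc$aqueduct_mask), cnt)
  expect_true(cnt >= 13 && cnt <= 14)
})

test_that("degenerate disc sizes and contrasts behave as specified", {
  # one-pixel disc centred on a pixel centre
  cfg <- phantom_config(matrix_size = 96, fov = 96, aqueduct_diameter = 1,
                        aqueduct_center = c(0, -20))
  sc <- build_scene(cfg)
  expect_equal(sum(sc$aqueduct_mask), 1L)
  # equal magnitudes: no visible disc
  cfg2 <- phantom_config(matrix_size = 96, fov = 76.8,
                         aqueduct_magnitude = 0.2, tissue_magnitude = 0.2)
  sc2 <- build_scene(cfg2)
  cfg3 <- phantom_config(matrix_size = 96, fov = 76.8,
                         aqueduct_magnitude = 0.9, tissue_magnitude = 0.2)
  sc3 <- build_scene(cfg3)
  ref <- sc3$image
  ref[sc3$aqueduct_mask] <- 0.2
  expect_equal(max(Mod(sc2$image - ref)), 0)
  expect_equal(Arg(sc2$image[Mod(sc2$image) > 0]), rep(0, sum(Mod(sc2$image) > 0)))
})

test_that("a disc outside the scene support is a configuration error", {
  expect_error(phantom_config(aqueduct_center = c(0, -88)),
               "configuration error")
  expect_error(phantom_config(aqueduct_diameter = -1), "> 0")
  expect_error(phantom_config(matrix_size = 97), "even")
})

test_that("velocity waveform evaluation is the stated two-sinusoid model", {
  wf <- flow_waveform(resp_amplitude = 1, resp_frequency = 15,
                      card_amplitude = 0, card_frequency = 60)
  expect_equal(evaluate_velocity(wf, 1), sin(2 * pi * 0.25), tolerance = 1e-12)
  wf2 <- flow_waveform()
  expect_equal(evaluate_velocity(wf2, 0), 0)
  # amplitudes matching the phantom study's measured components
  t <- seq(0, 60, by = 1e-3)
  expect_lte(max(abs(evaluate_velocity(wf2, t))), 3.02 + 2.76)
  expect_error(flow_waveform(resp_frequency = 80, card_frequency = 60),
               "below")
})

test_that("velocity-to-phase follows the symmetric VENC convention", {
  expect_equal(velocity_to_phase(15, 15, 1) - velocity_to_phase(15, 15, -1), pi)
  expect_equal(velocity_to_phase(0, 15, 1), 0)
  expect_equal(velocity_to_phase(-7.5, 15, 1) - velocity_to_phase(-7.5, 15, -1),
               -pi / 2)
})

test_that("simulated coil maps are smooth, deterministic, with RSS away from 0", {
  m1 <- simulate_coil_maps(1, 32)
  expect_equal(m1[, , 1], matrix(1 + 0i, 32, 32))
  m8 <- simulate_coil_maps(8, 96)
  rss <- sqrt(apply(Mod(m8)^2, 1:2, sum))
  expect_gt(min(rss), 0.5)
  expect_identical(m8, simulate_coil_maps(8, 96))
})

test_that("k-space simulation has the documented size, timing and determinism", {
  st <- tiny_static()
  cfgs <- default_configs("baseline")
  # 20 s at TR 10.5 ms: 952 spokes per encoding, 119 frames of 8 spokes
  n_pairs <- floor(cfgs$acq$duration / (cfgs$acq$tr / 1000) / 2)
  expect_equal(n_pairs, 952)
  expect_equal(frame_bins(n_pairs, 8, 10.5)$n_frames, 119)
  ks <- st$ks
  expect_equal(dim(ks$data)[2], 2 * floor(6 / 0.0105 / 2))
  expect_equal(ks$times[1:4], c(0, 1, 2, 3) * 0.0105)
  expect_equal(ks$enc_sign[1:4], c(1, -1, 1, -1))
  expect_equal(ks$angles[1], ks$angles[2])     # pairs share an angle
  ks2 <- simulate_kspace(st$scene, function(t) 0 * t, NULL, st$cfgs$acq)
  expect_identical(ks$data, ks2$data)          # bit-identical rerun
  expect_error(simulate_kspace(st$scene, function(t) 0 * t, NULL,
                               acquisition_config(duration = 0.05)),
               "duration too short")
})

test_that("static scene gives identical encodings; flow modulates only the disc", {
  st <- tiny_static()
  ks <- st$ks
  plus <- ks$data[, ks$enc_sign > 0, 1]
  minus <- ks$data[, ks$enc_sign < 0, 1]
  expect_lt(max(Mod(plus - minus)), 1e-12 * max(Mod(plus)))
  # with flow, the paired-spoke difference is exactly the disc spoke times
  # the encoding phase factor difference
  wf <- function(t) rep(7.5, length(t))      # venc/2 -> phase +/- pi/4
  ksf <- simulate_kspace(st$scene, wf, NULL, st$cfgs$acq)
  disc <- st$scene$image
  disc[!st$scene$aqueduct_mask] <- 0
  dspoke <- nufft_forward(disc, spoke_coords(ksf$angles[1], 96))
  pred <- dspoke * (exp(1i * pi / 4) - exp(-1i * pi / 4))
  got <- ksf$data[, 1, 1] - ksf$data[, 2, 1]
  expect_lt(max(Mod(got - pred)), 1e-8 * max(Mod(dspoke)))
})

test_that("zero-phase scene spokes obey conjugate symmetry across 180 degrees", {
  st <- tiny_static()
  img <- st$scene$image
  a <- nufft_forward(img, spoke_coords(35, 96))
  b <- nufft_forward(img, spoke_coords(215, 96))
  expect_lt(max(Mod(b - Conj(a))), 2e-2 * max(Mod(a)))
})

test_that("the DC sample equals the image sum of the coil-weighted scene", {
  ts <- tiny_ks()
  st <- tiny_static()
  c0 <- st$ks$readout_samples %/% 2 + 1
  expect_lt(Mod(st$ks$data[c0, 1, 1] - sum(st$scene$image)) /
              Mod(sum(st$scene$image)), 0.02)
  s <- sum(ts$scene$image * ts$maps[, , 3])
  expect_lt(Mod(ts$ks$data[c0, 1, 3] - s) / Mod(s), 0.02)
})
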