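# Shared fixtures, built once per test run and cached. Everything is
# generated in code (the simulator is deterministic), at reduced problem
# sizes chosen so the whole suite stays fast.

.fix <- new.env()

fix_get <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# tiny oscillating-flow data set: 96 px, 0.8 mm, 8.4 s, 8 coils
tiny_ks <- function() fix_get("tiny_ks", function() {
  cfgs <- default_configs("tiny")
  scene <- build_scene(cfgs$phantom)
  maps <- simulate_coil_maps(cfgs$phantom$n_coils, cfgs$phantom$matrix_size)
  list(ks = simulate_kspace(scene, cfgs$waveform, maps, cfgs$acq),
       scene = scene, maps = maps, cfgs = cfgs)
})

# static scene (zero flow), single uniform coil
tiny_static <- function() fix_get("tiny_static", function() {
  cfgs <- default_configs("tiny", duration = 6)
  scene <- build_scene(cfgs$phantom)
  list(ks = simulate_kspace(scene, function(t) 0 * t, NULL, cfgs$acq),
       scene = scene, cfgs = cfgs)
})

# disc-band-limited Cartesian oracle of an image (radial k-space coverage)
bandlimit_disc <- function(img) {
  n <- nrow(img)
  k <- c(0:(n / 2 - 1), -(n / 2):-1) / n
  K <- sqrt(outer(k^2, k^2, "+"))
  fft(fft(img) * (K <= 0.5), inverse = TRUE) / n^2
}

nrmse <- function(est, ref, mask = TRUE) {
  sqrt(mean(Mod(est[mask] - ref[mask])^2)) / sqrt(mean(Mod(ref[mask])^2))
}

# combine per-coil images with given maps (matched filter)
coil_combine <- function(imgs, maps) {
  acc <- 0i
  for (c in seq_len(dim(maps)[3])) acc <- acc + Conj(maps[, , c]) * imgs[, , c]
  acc
}

# slow reference for 1D TV denoising: high-precision generic optimizer
tv_oracle <- function(y, lam) {
  f <- function(x) 0.5 * sum((x - y)^2) + lam * sum(abs(diff(x)))
  o <- stats::optim(y, f, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-14))
  stats::optim(o$par, f, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-14))$par
}

# full-scale baseline pipeline (CG-SENSE + CS lambda 1e-6), computed once;
# this is the expensive fixture behind the numerical-model anchor tests
baseline_report <- function() fix_get("baseline_report", function() {
  cfgs <- default_configs("baseline")
  scene <- build_scene(cfgs$phantom)
  maps <- simulate_coil_maps(cfgs$phantom$n_coils, cfgs$phantom$matrix_size)
  ks <- simulate_kspace(scene, cfgs$waveform, maps, cfgs$acq)
  run_phantom_analysis(ks, list(recon_config("cg-sense"),
                                recon_config("cs", lambda = 1e-6)))
})

# reduced-scale sweep point: simulate + CS-reconstruct + Q ratios
sweep_point <- function(..., lambda = 1e-6) {
  cfgs <- default_configs("tiny", ...)
  scene <- build_scene(cfgs$phantom)
  maps <- simulate_coil_maps(cfgs$phantom$n_coils, cfgs$phantom$matrix_size)
  ks <- simulate_kspace(scene, cfgs$waveform, maps, cfgs$acq)
  run_phantom_analysis(ks, list(recon_config("cs", lambda = lambda)))$table
}
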