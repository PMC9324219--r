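# aqueflow

Real-time golden-angle radial flow MRI of cerebrospinal fluid, end to end
and in silico: a multicoil numerical flow phantom, radial k-space
simulation, CG-SENSE and compressed-sensing (temporal total-variation)
reconstruction, phase-difference velocity mapping, and the flow-analysis
and agreement-statistics layer used to validate such a method.

## The problem

CSF moves through the cerebral aqueduct (a 1–3 mm channel) in oscillations
driven by the heart beat (~1 Hz) and by respiration (~0.25 Hz). Breathing
is aperiodic, so respiratory flow cannot be recovered by gated imaging; it
takes *real-time* velocity mapping with sub-millimetre spatial resolution.
The method implemented here acquires one radial k-space spoke per TR
(10.5 ms), with the two velocity encodings of a pair in consecutive TRs
and the spoke angle advancing by the golden angle (111.246°) every second
TR; 8 spoke pairs form one 168 ms frame. Images x are reconstructed from
the heavily undersampled per-frame data d by solving

    min_x || W^1/2 (F_r S x − d) ||₂² + λ || T x ||₁

with F_r the radial NUFFT, S the coil sensitivities, W the radial density
compensation, and T the temporal finite-difference operator (λ = 0 is
CG-SENSE; λ > 0 is compressed sensing with temporal total variation,
solved by monotone FISTA with an exact taut-string TV prox). Velocity
follows by complex division of the two encodings:
v = Arg(x₊ conj(x₋)) · VENC/π.

Accuracy is scored by spectral amplitude ratios: Q_R (Q_C) is the
respiratory (cardiac) FFT component amplitude of the reconstructed
aqueduct flow curve divided by that of the programmed reference waveform;
1 means the oscillation is quantified exactly, below 1 it is
underestimated.

The package is aimed at MR-physics and neuroimaging-methods researchers
who want to study, stress or extend this class of acquisition without a
scanner: every stage is a documented, tested R function.

## Worked example

A reduced-scale run of the whole chain (96 px, 8.4 s; a full-scale run is
identical with `default_configs("baseline")` and takes a few minutes per
reconstruction):

```r
library(aqueflow)

cfgs  <- default_configs("tiny")        # phantom + waveform + acquisition
scene <- build_scene(cfgs$phantom)
maps  <- simulate_coil_maps(8, cfgs$phantom$matrix_size)
ks    <- simulate_kspace(scene, cfgs$waveform, maps, cfgs$acq)
ks
#> <radial_kspace> 96 samples x 800 spokes x 8 coils
#>   TR 10.5 ms, VENC 15 cm/s, 8 spokes/frame, duration 8.4 s

rep <- run_phantom_analysis(ks, list(recon_config("cg-sense"),
                                     recon_config("cs", lambda = 1e-6)))
rep
#> <phantom_report>
#>      mode lambda   q_r   q_c  r_rt r_ref   c_rt c_ref
#>  cg-sense     NA 0.975 0.932 0.144 0.147 0.0981 0.105
#>        cs  1e-06 0.922 0.877 0.136 0.147 0.0922 0.105
```

Each row is one reconstruction variant; `q_r`/`q_c` are the respiratory
and cardiac amplitude ratios against the programmed waveform, and the
`*_rt`/`*_ref` columns are the underlying component amplitudes in mL/s. At
this mildly undersampled reduced scale both ratios are close to 1; at the
default scale (240 px, ~47× undersampled per frame, 20 s) the same
pipeline gives Q_R ≈ 0.78 for CG-SENSE and ≈ 0.74 for CS at λ = 10⁻⁶ —
the respiratory component is recovered with a modest underestimation,
while raising λ to 10⁻³ overshoots it. The cardiac ratio is consistently
below the respiratory one: temporal regularization and 168 ms frames damp
the faster oscillation more.

Downstream analysis on any velocity series:

```r
vel  <- velocity_map(cs_temporal_tv(normalize_kspace(ks), maps, 1e-6))
flow <- roi_flow(vel, scene$aqueduct_mask)
flow_volumes(flow)                       # cranial / caudal / net, mL/min
lowpass_zero_phase(flow)                 # respiratory-only flow (40 dB stopband)
icc_agreement(cbind(scan1 = c(1.2, 0.8, 1.0, 1.4),
                    scan2 = c(1.1, 0.9, 1.1, 1.3)))
#> <agreement_result> ICC(2,1) = 0.889 (strong agreement)
#>   bias 8.33e-17 [LoA -0.226, 0.226]
```

A thin CLI over the same functions is installed at
`system.file("cli/aqueflow", package = "aqueflow")` with subcommands
`simulate | recon | analyze | sweep | stats | fixtures`.

## Package layout

| file | contents |
|---|---|
| `R/trajectory.R` | golden angles, spoke coordinates, Ram-Lak weights, frame binning |
| `R/phantom.R` | scene, waveform, coil maps, k-space simulator |
| `R/nufft.R`, `src/nufft.cpp` | gridding NUFFT, encoding operator, solvers (FFTW3) |
| `R/preprocess.R` | echo-shift/zeroth-order phase corrections, normalization, coil compression |
| `R/recon.R` | gridding, Walsh maps, CG-SENSE, temporal-TV CS, velocity mapping |
| `R/flow.R` | flow curves, Q ratios, FIR filtering, volumes, coherence, ROI tracking |
| `R/stats.R` | ICC(2,1), Bland–Altman, Dice, ANOVA, regression |
| `R/experiments.R` | baseline configs, parameter sweeps, fixtures |
| `R/io.R` | HDF5 k-space, NIfTI velocity maps, CSV/JSON |
| `vignettes/csf-realtime-flow.Rmd` | models, solvers, design choices, limitations |
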