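---
title: "Real-time golden-angle radial CSF flow imaging: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time golden-angle radial CSF flow imaging: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Cerebrospinal fluid (CSF) moves through the cerebral aqueduct — a channel of
only 1–3 mm diameter — in oscillations driven by the heart beat (roughly
1 Hz) and by respiration (roughly 0.25 Hz). Because breathing is not
periodic, respiratory-driven flow cannot be recovered by cardiac-gated
imaging; it requires *real-time* velocity mapping: continuous acquisition
with enough spatial resolution to resolve a millimetre-scale vessel and
enough temporal resolution to follow the oscillations.

`aqueflow` implements, end to end and in silico, a real-time phase-contrast
method built on a golden-angle radial gradient-echo acquisition with
through-plane velocity encoding, reconstructed either by CG-SENSE or by
compressed sensing with a temporal total-variation penalty. The package
contains:

1. a numerical flow phantom (a modified Shepp-Logan scene with a small
   velocity-phase-modulated "aqueduct" disc) and a multicoil radial k-space
   simulator;
2. the reconstruction chain: phase corrections, coil compression, gridding,
   Walsh coil-map estimation, CG-SENSE and temporal-TV compressed sensing,
   and velocity mapping by complex division;
3. the analysis layer: aqueduct flow curves, spectral accuracy indices
   (Q_R, Q_C), respiratory flow isolation by zero-phase FIR filtering,
   cranial/caudal/net flow volumes, magnitude-squared coherence with a
   respiratory trace, and agreement statistics (ICC(2,1), Bland–Altman,
   Dice).

# Acquisition model

Each repetition (TR, default 10.5 ms) acquires one radial spoke of k-space.
The two velocity encodings of a spoke pair are acquired in consecutive TRs
with alternating sign of the flow-encoding gradient, and the spoke angle
advances by the golden angle, 180°·(√5−1)/2 = 111.246°, every second TR, so
both encodings of a pair share an angle. Eight spoke pairs are binned into
one reconstructed time frame: 8 spokes × 2 encodings × 10.5 ms = 168 ms per
frame.

Velocity encodes into image phase symmetrically: each encoding contributes
±(π/2)·v/VENC, so the phase *difference* between encodings is π·v/VENC and
v = VENC (15 cm/s by default) maps to a phase difference of exactly π. This
split is the standard phase-contrast convention; only the difference is
physically observable.

The simulator evaluates the programmed velocity waveform

v(t) = A_r sin(2π f_r t + φ_r) + A_c sin(2π f_c t + φ_c)

once per TR (the velocity is frozen during one readout), sets the uniform
phase of the aqueduct disc accordingly, and samples the coil-weighted scene
along the spoke with a nonuniform FFT. Because the disc phase is spatially
uniform within a TR, the scene is decomposed once into static-background
and disc parts and only the modulation factor changes per TR — an exact
algebraic shortcut, not an approximation. No noise is added; determinism is
bit-exact.

Default waveform amplitudes are A_r = 3.02 cm/s and A_c = 2.76 cm/s, the
respiratory- and cardiac-component amplitudes of the physical pump-phantom
validation experiment that the numerical model emulates; f_r = 15
cycles/min and f_c = 60 bpm at baseline.

# Problem sizes

The default phantom geometry is a 240 × 240 matrix over a 192 mm field of
view (0.8 mm pixels, inside the 0.5–0.9 mm range of in-plane resolutions
used in the phantom validation experiments), 8 receive coils, and a 20 s
acquisition (952 spoke pairs, 119 frames). At 8 spokes per frame the
acquisition is ~47× undersampled relative to the radial Nyquist criterion
(π/2 · 240 ≈ 377 spokes), which is the regime the reconstruction methods
are designed for. A reduced "tiny" geometry (96 px, 0.8 mm, 8.4 s) with the
same undersampling structure backs the fast tests; the methods-level
conclusions (trends, orderings) are checked there, the quantitative anchors
at the default scale.

The aqueduct disc sits at (0, −20) mm on the uniform 0.2-intensity tissue
plateau of the Shepp-Logan head, with magnitude 0.8 — CSF is several-fold
brighter than surrounding tissue in long-TR gradient-echo flow imaging, and
the contrast matters: velocity estimates in edge pixels are pulled toward
zero by partial-volume mixing with (zero-phase) tissue in proportion to the
tissue's relative signal.

Synthetic coil sensitivities are eight loop-like elements on a circle just
outside the FOV, each a Lorentzian magnitude fall-off with a slowly varying
phase: smooth, deterministic, and with root-sum-of-squares bounded away
from zero everywhere, which is all the reconstruction assumes of them.

# Reconstruction

## Gridding and coil maps

The full 20 s of data (both encodings pooled — the static anatomy dominates
and the pooling doubles the angular coverage) is gridded per coil with
Ram-Lak (|k|) density compensation; the k = 0 sample, acquired once per
spoke, carries the area-equivalent weight 1/(4·n_samples). Coil maps are
then estimated with the Walsh method: the per-pixel dominant eigenvector of
the local coil covariance over an 8-pixel sliding window (box filtering +
power iteration), normalized to unit root sum of squares and phase-referenced
to the first coil. Velocity maps are unaffected by the maps' phase
ambiguity because both encodings are reconstructed with the same maps.

A note on validating the gridding step: any reconstruction from radial
k-space confined to |k| ≤ 0.5 cycles/pixel — including the ideal Cartesian
inverse FFT with a disc mask — differs from a sharp-edged scene by
Gibbs ringing at the ~0.1 NRMSE level. Gridding accuracy is therefore
assessed against the disc-band-limited Cartesian oracle (agreement < 0.05
NRMSE at 2× readout oversampling), not against the raw scene.

## Phase corrections

Following standard radial practice, spoke-dependent echo shifts are
corrected first. The shift estimator uses the coil-combined k-space
magnitude envelope: for an unshifted spoke the envelope is symmetric about
k = 0 regardless of where the object sits in the FOV, so the position of
its (log-parabolically interpolated) peak is a robust shift estimate, while
phase-slope estimators read the object's spatial centroid as a spurious
shift on asymmetric scenes. Two refinement passes bring residuals below
0.01 samples. A zeroth-order correction then aligns the k = 0 phase of all
spokes within each encoding. On ideal simulated data both corrections are
no-ops to within numerical tolerance — which is itself a useful check.

## CG-SENSE

With coil maps S, per-frame radial NUFFT F_r and data d, CG-SENSE solves
the weighted least-squares problem ‖W^{1/2}(F_r S x − d)‖₂² per frame by
conjugate gradients on the normal equations, from zero initialization.
W is the Ram-Lak density compensation, applied as √W on both sides — the
usual k-space preconditioning for radial CG-SENSE, without which CG needs
many times more iterations on strongly non-uniform sampling. The iteration
cap is 100 (the value observed to give convergence in this setting), with
early stopping at a 10⁻⁶ relative residual.

## Compressed sensing with temporal total variation

The CS reconstruction minimizes

‖W^{1/2}(F_r S x − d)‖₂² + λ‖Tx‖₁

jointly over all frames of one encoding, where T is the first-order
non-periodic temporal finite difference (unit frame spacing) and λ refers
to data normalized by the largest k-space sample magnitude. The ℓ₁ norm is
applied to real and imaginary parts of the temporal differences separately
(anisotropic complex TV); with phase differences well below π this behaves
like the isotropic variant while admitting an exact scalar prox.

The solver is monotone FISTA: a proximal-gradient method with Nesterov
momentum and a per-iteration objective comparison that keeps the better of
the candidate and the previous iterate, so the objective trace is
non-increasing by construction (recorded in the result's diagnostics). The
step size is 1/L with L estimated by per-frame power iteration (10 steps,
deterministic start, 5% safety margin). The TV prox is evaluated exactly,
pixel by pixel along time, by a taut-string algorithm; the same routine is
exported as `tv_denoise()` and tested against an independent optimizer.
One hundred outer iterations are used, matching the CG-SENSE budget.
Solver internals are single precision (as is conventional for MRI
reconstruction toolboxes); the exported NUFFT and encoding-operator API is
double precision and passes adjoint tests at 10⁻⁶.

The NUFFT itself is Kaiser-Bessel gridding on a 1.25× oversampled FFTW
grid with kernel width 4 (Beatty's β), with exact adjoint pairing between
the interpolation and spreading steps — important because CG and FISTA
assume an adjoint-consistent operator.

## Velocity mapping

Each encoding is reconstructed separately and velocity follows by complex
division: v = Arg(x₊ · conj(x₋)) · VENC/π, with magnitude |x₊ · conj(x₋)|^{1/2}
kept for ROI work. No velocity anti-aliasing is applied; programmed
velocities stay well below VENC.

# Analysis layer

Background phase is corrected per frame by subtracting a first-order
polynomial (plane) fitted to static-tissue pixels. The aqueduct flow curve
is Σ v·A over the ROI (ground-truth disc mask for simulated data),
converted to mL/s. The accuracy indices are FFT amplitude ratios: Q_R (Q_C)
is the respiratory (cardiac) component amplitude of the real-time curve
divided by that of the reference — in simulation, the programmed analytic
waveform times the true disc area, sampled at the frame timestamps. (A
gated reference scan exists only on physical hardware; in the numerical
model the analytic waveform is the ground truth.) Component
amplitudes are single-sided 2|FFT|/N values at the bin nearest the target
frequency, refined by three-point quadratic interpolation when the
frequency falls between bins; no window or detrending is applied (both
signals share the sampling grid, so residual leakage largely cancels in the
ratio).

Respiratory flow isolation uses an equiripple FIR low-pass (passband
≤ 0.5 Hz at 0.1 dB ripple, stopband ≥ 0.75 Hz at 20 dB, minimum order
meeting the spec), applied forward and backward — zero phase and 40 dB
total stopband attenuation — with reflect-padding by one filter length.
Flow volumes split frames into positive (cranial) and negative (caudal)
flow, each summed, divided by scan duration, in mL/min; net = cranial +
caudal holds identically. Coherence with a respiratory trace is Welch
magnitude-squared coherence with 8 segments and 50% overlap (Hamming
window), reported at the peak of the bellows power spectral density.

Agreement statistics follow the usual definitions: Shrout–Fleiss ICC(2,1)
absolute agreement from two-way ANOVA mean squares with qualitative labels
at 0.30/0.50/0.70/0.90; Bland–Altman bias ± 1.96 SD; Dice 2|A∩B|/(|A|+|B|)
(defined as 1 for two empty masks); one-way ANOVA; ordinary least squares.
Two degenerate-input conventions: identical constant groups yield F = 0,
p = 1 (zero within-group variance with *differing* means is an error), and
constant y in regression yields slope 0, R² = 0.

# What the simulation does and does not establish

The generator reproduces the geometry, timing, encoding and undersampling
structure of the real acquisition, with modeled coils and no noise. Passing
tests therefore demonstrate the *methodological* behavior of the
reconstruction — how temporal regularization trades temporal fidelity
against artifact suppression, how vessel size and temporal resolution
limit spectral accuracy — under ideal conditions. They do not capture
thermal noise, relaxation and flip-angle weighting, off-resonance or B₀
drift, gradient-delay trajectory errors (the corrections are exercised on
injected errors only), in-flow enhancement, or the spatial complexity of
real anatomy; quantitative indices from real scanners will differ, and the
known direction of that difference is downward: noise-free CG-SENSE
indices of ≈0.8, as measured here, sit well above what the same
reconstruction achieves on noisy physical-phantom data.

Known limitations, deliberately accepted: an O(N²)-worst-case (typically
linear) taut-string TV prox, fine at a few hundred frames; ICC limited to
the two-measurement design used here; the tracking is integer-pixel rigid
translation; λ is not transferable between packages — its effective scale
depends on the density weighting and TV normalization conventions, so
quantitative agreement of Q values at a *given* λ with other
implementations is only approximate, while trends across λ are robust.

# Numerical choices at a glance

| choice | value | why |
|---|---|---|
| NUFFT oversampling / kernel | 1.25 / width 4, KB (Beatty β) | ~10⁻³ accuracy at tractable grid sizes |
| density compensation | \|k\|, DC weight 1/(4·n_samples), mean-normalized | annulus-area quadrature per spoke |
| CG/FISTA iterations | 100 (CG early-stops at 10⁻⁶) | convergence at these problem sizes |
| FISTA step | 1/(1.05·2·max λ_max per frame) | power-iteration estimate, safety margin |
| λ default | 10⁻⁶ on max-normalized data | in vivo default of the method |
| Walsh window | 8 px | smooth maps at 0.8 mm pixels |
| FIR design | Parks–McClellan, minimum even order | stated band specs, nothing else |
| solver precision | single (API double) | standard for MRI recon; memory-bound solvers |
| Dice on empty masks | 1 | identical-delineation convention |

# Reproducing the headline numbers

`scripts/acceptance.R` recomputes from scratch, with the installed package:
the golden-angle increment, the achieved double-pass FIR stopband
attenuation, and the baseline-phantom Q_R for CG-SENSE and for CS at
λ = 10⁻⁶ (simulate → preprocess → Walsh maps → reconstruct → ROI flow →
spectral ratio). See the README for invocation.
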