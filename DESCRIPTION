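Package: aqueflow
Title: Real-Time Golden-Angle Radial Flow MRI: Simulation, Reconstruction
    and CSF Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical simulation and reconstruction pipeline for real-time
    velocity-encoded golden-angle radial MRI of cerebrospinal-fluid flow in
    small passageways such as the cerebral aqueduct. Provides a multicoil
    numerical flow phantom (modified Shepp-Logan scene with a
    velocity-phase-modulated aqueduct), golden-angle radial trajectories with
    density compensation, a Kaiser-Bessel gridding NUFFT backed by FFTW3,
    CG-SENSE and compressed-sensing (temporal total-variation) image
    reconstruction, phase-difference velocity mapping, flow-curve extraction
    with spectral amplitude-ratio accuracy indices (Q_R, Q_C), zero-phase FIR
    respiratory flow isolation, flow volumes, magnitude-squared coherence, and
    agreement statistics (ICC(2,1), Bland-Altman, Dice).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    signal,
    rhdf5,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: FFTW3 (libfftw3)
Config/testthat/edition: 3
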