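Package: cpmgpulse
Title: Phase-Relaxed Multidimensional RF Pulse Design for Inner-Volume
    Fast-Spin-Echo MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of multidimensional, multi-channel (parallel-transmit)
    radiofrequency excitation pulses for inner-volume fast-spin-echo (FSE)
    imaging. Implements the small-tip-angle spatial-domain least-squares
    design with separate weighting of the CPMG and non-CPMG components of
    the target excitation, so that residual excitation error is biased onto
    the non-CPMG axis where the refocusing train suppresses it. Includes 3D
    spherical-shells and 2D spiral excitation k-space trajectories with
    time-optimal slew- and amplitude-limited gradient waveform generation,
    gradient impulse response (GIRF) modelling and predicted k-space,
    time-optimal VERSE peak-amplitude reduction with iterative re-design,
    a hard-pulse Bloch simulator, an extended-phase-graph (EPG) FSE
    simulator with pseudo-steady-state refocusing sweeps, synthetic field
    map and phantom generation, and trajectory evaluation via point-spread
    surrogates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
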