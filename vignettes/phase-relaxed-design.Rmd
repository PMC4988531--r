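---
title: "Phase-relaxed pulse design for inner-volume FSE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-relaxed pulse design for inner-volume FSE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgpulse)
```

# The problem

Inner-volume imaging excites only a small sub-volume so that a small field
of view can be encoded without aliasing. With fast-spin-echo (FSE)
readouts, two properties of the sequence do a lot of work for free: spins
never excited produce no echo at all (given spoiling of the refocusing
FIDs), and spins excited with the *wrong phase* — transverse magnetization
parallel to the refocusing axis's perpendicular, the non-CPMG component —
produce echoes that decay rapidly when the refocusing flip angles are well
below 180°. This package designs multidimensional, multi-channel
excitation pulses that exploit the second property deliberately: the
least-squares design is weighted so that the unavoidable residual
excitation outside the target volume lands preferentially in the non-CPMG
component, where the echo train suppresses it.

Package-wide phase convention: refocusing pulses rotate about the rotating
frame y-axis. In the complex representation used for both targets and
simulated flip angles, the imaginary part is the CPMG component
(magnetization along +y) and the real part the non-CPMG component (+x).

# The design model

The small-tip approximation (STA) linearizes the Bloch equation so the
complex transverse flip angle is a Fourier-like sum over the RF samples:

$$ m(r) = i\gamma\,\Delta t \sum_{c}\sum_{j} S_c(r)\, b_c(t_j)\,
   e^{\,i k(t_j)\cdot r + i\Delta\omega(r)(t_j - T)} $$

with per-channel transmit sensitivities $S_c$, off-resonance
$\Delta\omega$, and the excitation k-space
$k(t) = -\gamma\int_t^T G(\tau)\,d\tau$, which ends at the origin at the
end of the pulse. Off-resonance phase is referenced to the end of the
pulse for the same reason. `build_system_matrix()` assembles this linear
map as a dense complex matrix; `rf_sample_kspace()` supplies k-space
samples at the effective time of each RF sample under the hard-pulse
discretization, which makes the linear prediction and the Bloch simulator
agree to discretization order (verified at a 5° target to below 2%
relative RMS).

## Phase relaxation

Splitting the system into real and imaginary blocks allows the two
components to be weighted separately:

$$ \begin{bmatrix} w_i\,\mathrm{Im}(m) \\ w_r\,\mathrm{Re}(m) \end{bmatrix}
 = \begin{bmatrix} w_i\,\mathrm{Im}(A) & w_i\,\mathrm{Re}(A) \\
                   w_r\,\mathrm{Re}(A) & -w_r\,\mathrm{Im}(A) \end{bmatrix}
   \begin{bmatrix} \mathrm{Re}(b) \\ \mathrm{Im}(b) \end{bmatrix} $$

with $w_i = 1$ fixed and $w_r \in [0,1]$. The design solves
$\min_b \|A_{sw} b - m_{sw}\|^2 + \lambda \|b\|^2$. At $w_r = 1$ this is
the ordinary complex least-squares design; lowering $w_r$ buys CPMG
fidelity at the cost of non-CPMG error, which the echo train then
suppresses. `lcurve_study()` tabulates both error axes against peak RF
amplitude; the monotonicity of the trade-off in $w_r$ is tested against a
dense-algebra oracle.

Numerical choices: the solver is conjugate gradient on the normal
equations, relative-residual tolerance $10^{-6}$, iteration cap with a
warning (the best iterate is returned). Multiple $\lambda$ values are
solved independently rather than with a multishift method; for the
problem sizes used here the simplicity is worth more than the shared
Krylov space. $\lambda$ is dimensionless in this package: it is applied
relative to the mean squared column norm of the weighted system matrix.
This keeps equal values comparable across grids, rasters and channel
counts, and it is why regularization values quoted for other
implementations (which depend on their units for $A$ and $m$) do not
transfer numerically. Target flip angles of 90° are designed with the STA
despite being outside its formal validity; spiral and shells trajectories
are close to "linear class" and tolerate this well, which the Bloch
comparisons in the test suite confirm at small tip and which degrades
gracefully at 90°.

Designs run on a decimated mesh (default 5.5 mm, configurable) and,
optionally, on a time-decimated RF raster (`time_decimation`), with the
solved RF interpolated back to the gradient raster. Decimation is by
nearest-voxel subsampling; an interpolating scheme would smooth the maps,
and smoothness assumptions belong to the map generator, not the design.

# Trajectories and gradients

`shells_3d()` builds concentric spherical spirals traversed outer to
inner, so the k-space centre — the effective centre of the excitation —
is sampled last, which is what makes these trajectories suitable for
spin-echo excitation. Shell radii are spaced by the radial under-sampling
factor times the Nyquist spacing $2\pi/\mathrm{FOV}$; within each shell
the polar turn spacing is the angular under-sampling factor times the
same Nyquist spacing, with a constant polar rate and the azimuth swept
proportionally (the classic spherical-spiral construction admits
variants; this one is fixed here and documented by the code). Successive
shells alternate pole-to-pole direction and are rotated about the x-axis
by the requested inter-shell offset. `spiral_2d()` is the matching 2D
Archimedean spiral, with an optional variable-velocity profile that
affects timing only.

`time_optimal_gradients()` converts a curve to the minimum-duration
waveform under amplitude and slew limits by the standard two-pass
construction: the speed along the arc-length parameterization is capped
by $\gamma G_{max}$ and by $\sqrt{\gamma S_{max}/\kappa}$ (curvature
$\kappa$), and forward/backward passes from rest enforce the tangential
acceleration budget. Small safety margins (0.5–1%) keep the discretized
output strictly inside the limits; gradients are recovered from the
k-space samples by central differences so that trapezoidal re-integration
reproduces the trajectory (tested to below 1% of $k_{max}$). For the
six-shell trajectory with $k_{max} = 280$ rad/m, under-sampling factors
1.75/3.21 relative to a 220 mm FOV and a 30° inter-shell offset, the
waveform duration at the 200 T/m/s and 40 mT/m limits is about 10.6 ms
on the default 6.4 µs raster — within the sub-15 ms regime these designs
target. Exact correspondence with any particular published duration is
not expected, since the shell densification formula admits variants.

# Gradient impulse response

The gradient chain is modelled as a per-axis LTI system. `apply_girf()`
performs causal zero-padded convolution truncated to the input duration;
`predicted_kspace()` integrates the filtered waveform backwards from the
end of the pulse, so $k_H(T) = 0$ by construction. `estimate_girf()` is a
frequency-domain least-squares estimator with Tikhonov regularization
toward the identity response, so spectrally empty bins degrade to
identity and are flagged; the usable frequency resolution is the
reciprocal of the (non-quiet) test-waveform duration. A synthetic
delay-plus-low-pass response (`girf_synthetic()`) ships as a test fixture
and demo stand-in; it is synthetic and describes no physical scanner.
Only per-axis self-terms are modelled; cross-terms and B0 terms are out
of scope.

# VERSE

`time_optimal_verse()` re-times the waveform along its own k-space path
so the peak RF amplitude over channels is capped. The invariant is that
RF per unit arc length is preserved, which leaves the on-resonance
small-tip profile unchanged; the speed is additionally capped at
$v \le \gamma' b_{limit}/\max_c|\beta_c(s)|$ and forward/backward passes
keep the deceleration slew-feasible without re-touching the input's own
ramps. Discretely, each input sample's RF area is spread uniformly over
its stretched interval and re-integrated over the output raster windows,
which preserves the cumulative RF-versus-arc profile exactly at window
boundaries and reduces to the identity when no stretching is needed.
Samples where the gradient is (near) zero but RF plays — the terminal
k-space-centre portion of these pulses — cannot be re-parameterized in
arc length and are dilated in time instead, preserving the RF integral;
RF during zero-gradient dwell is allowed. The output never contains an
out-of-limit sample.

The profile-preservation guarantee is a continuum statement: it holds to
the extent the discrete waveform resolves its own phase evolution. The
test suite verifies ≤1% on-resonance Bloch RMS difference on a
well-resolved test pulse; heavily under-sampled or noise-like RF (e.g.
an under-regularized solution) has no continuum limit to preserve, which
is one practical reason the re-design loop follows every VERSE step.

The `design_pulse()` loop mirrors the standard re-VERSE procedure: after
each solve, if the peak exceeds the hard limit (default 11 µT), VERSE
targets the lower attenuation limit (default 8 µT) and the design is
repeated on the GIRF-predicted k-space of the stretched gradients, for at
most five iterations; a still-over-limit result is returned flagged.

# Spin simulation

`bloch_simulate()` integrates each voxel through the pulse as a sequence
of half-precession / RF rotation / half-precession steps (relaxation
neglected during the pulse). `equivalent_flip()` converts magnetization
to the complex flip angle
$\alpha(r) = \cos^{-1}(M_z/M_0)\,e^{i\angle M_{xy}}$, directly comparable
with the design target.

`epg_fse()` is a full complex configuration-state EPG simulation
($F_k, F_{-k}, Z_k$), required because non-CPMG excitation breaks the
real-state shortcut. One unit of gradient dephasing is applied per half
echo spacing, relaxation over each half interval, refocusing about y, and
the echo is read from $F_0$; refocusing FIDs are assumed perfectly
spoiled. The engine is vectorized over voxels, which `spatial_epg()` uses
to produce per-echo images of the CPMG and non-CPMG parts separately
(whole-volume single-tissue, CSF by default, with the slowest-decaying
signal and hence the conservative case). Equivalence with a brute-force
512-isochromat Bloch ensemble is tested to $10^{-4}$ in echo magnitude
across excitation phases, sweeps and tissues.

## The pseudo-steady-state sweep

Variable refocusing angles are generated by `pss_sweep()` as a one-ahead
sequential EPG inversion: each flip angle is found one pulse ahead of its
echo, as the root of a demanded echo-amplitude course. The demanded
course approaches the pseudo-steady-state plateau geometrically in
squared amplitude,
$I_n^2 = S_\infty^2 + (I_1^2 - S_\infty^2)\,\rho^{\,n-1}$, with
$I_1 = 1 - \kappa(1 - S_\infty)$, and the plateau $S_\infty$ is solved
self-consistently so that the generated angles converge exactly to the
requested asymptote. The published description of the one-ahead recursion
leaves the exact update rule to its original reference, which admits
variants; the two shape constants ($\kappa = 0.2452$, $\rho = 0.29$) are
therefore fixed once against the published product sweep for a 35°
asymptote — 139°, 74°, 50°, 41°, then constant 35° — which this
implementation reproduces to within a degree and treats as its
conformance fixture. The same constants produce a sensible entry for any
asymptote (for 120°: 165°, 138°, 125°, 121°, then 120°), monotone
convergence within about five pulses, and the exact fixed point at 180°.

## Suppression factors

`xi_factor()` computes $\Xi$, the ratio of mean CPMG to mean non-CPMG
echo magnitudes over the ten central echoes of a 100-echo train (echoes
46–55, 1-based, matching linear phase-encode ordering); it is floored at
1 with a flag. The imaging sequence's initial dummy echoes are a labelling
concern of `spatial_epg()` only and do not shift this window. For CSF
(T1/T2 = 3651/1429 ms) at 4 ms echo spacing the package computes
$\Xi = 18.0$ at the 35° asymptote and $12.9$ at 120°; ideal 180°
refocusing without relaxation gives exactly 1. `suppression_factors()`
combines flip-angle contrast with $\Xi$:
$\Sigma_{nonCPMG} = [\sin(\mathrm{Im}\,\alpha_{in}) /
\sin(\mathrm{Re}\,\alpha_{out})]\,\Xi$, e.g. 98 for a 90° inner volume,
10° non-CPMG residual and $\Xi = 17$.

# Synthetic data

`make_phantom_maps()` emulates what the design pipeline needs from real
calibration data without any electromagnetic simulation: per-channel
complex sensitivities as a birdcage-like low-order harmonic model (smooth
magnitude peaked toward each channel's azimuth, azimuthal phase ramps,
small seeded random harmonic perturbations), a smooth low-order
polynomial off-resonance field scaled to a requested peak value (50 Hz
default, typical of a shimmed head at 3 T) with optional focal Gaussian
lesions, and a spherical object mask. Defaults follow the reference
experimental setup where one exists: 8 transmit channels, 220 mm FOV,
60 mm cube and 55 mm heart targets with 6 mm and 3 mm Gaussian
apodization, 90° targets, 11/8 µT peak/attenuation limits, 40 mT/m and
200 T/m/s gradient limits, 5.5 mm design mesh, 100-echo trains at 4 ms
spacing with the GM/WM/CSF relaxation table.

What the generator does not emulate: coil coupling and SAR (out of
scope), realistic B0 at air-tissue interfaces (only smooth plus focal
terms), receive coils, noise, or motion. Passing tests therefore
demonstrate correctness of the algorithms under smooth, well-conditioned
fields, not robustness to pathological in vivo field structure — the
known failure mode of coarse design meshes near strong B0 gradients
applies here exactly as it does with measured maps.

# Degenerate inputs and tie-breaks

Curves with cusps are handled by the curvature speed cap driving the
velocity toward zero rather than emitting an out-of-limit waveform; a
zero-extent shells trajectory collapses to a single point at the origin;
an empty design mask is rejected; `|Mz| > M0` is clamped with a warning
in `equivalent_flip()`; a zero denominator in `xi_factor()` returns
`Inf` with a flag; suppression-ratio inner regions that contain no voxel
centre on coarse grids fall back to the nearest masked voxel.

# Problem sizes

The test suite and the demo pipeline run at reduced sizes chosen so a
full run takes about a minute of simulation work: 2D design problems on
16–24 voxel grids, 3D demo on a 20³ grid with an 11 mm design mesh, four
shells at $k_{max} = 160$ rad/m, a 12.8 µs raster with 4× RF time
decimation, and 100-echo EPG trains. These sizes exercise every code path
at the same parameter values a full-size design would use; only grid and
trajectory extent differ.

# Known limitations

- The STA is used at 90°; no large-tip or optimal-control refinement.
- The GIRF models per-axis self-terms only.
- The EPG neglects diffusion and imperfect spoiling (no FID artifacts).
- The one-ahead sweep's update rule is a calibrated reconstruction, not a
  transcription of the original recursion.
- `lambda` and published regularization values are not numerically
  interchangeable (deliberately; see above).
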