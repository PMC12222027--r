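---
title: "Models and methods behind flagmotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flagmotor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagmotor)
```

flagmotor implements the quantitative models used to reason about rotary
flagellar motors observed in situ: cyclic-symmetry analysis of density
maps, the concentric-ring stoichiometry of the basal disk, the additive
stator torque model, and dwell-position counting from bead-rotation
assays. This vignette explains each model, its assumptions, the tunable
parameters, and the numerical and design choices made where more than one
reasonable implementation exists. All empirical statements below are the
ones the package's own tests compute.

## Conventions and units

Density maps are 3D voxel grids with isotropic voxel size in Angstrom; the
symmetry axis is +z through the geometric centre of the grid, axes are
right-handed, and angles are counter-clockwise viewed from +z. Bead
trajectories are in nanometres and seconds; stator mechanics uses pN and
nm (torque in pN nm). Lengths cross the Angstrom/nm boundary only through
`angstrom_to_nm()` / `nm_to_angstrom()` so units cannot mix silently.

## Synthetic phantoms and trajectories

The generators produce data with exactly the statistical structure the
analysis assumes, which is what makes every downstream stage testable at
desk scale:

* `make_ring_phantom()` sums `n` isotropic Gaussian subunits on a circle —
  an idealized C_n ring. Blobs are truncated at 4 sigma (neglected mass
  < 0.03%); a ring whose radius plus 3 sigma exceeds the grid half-extent
  is rejected rather than silently clipped.
* `make_concentric_disk_phantom()` places one blob per protomer for every
  ring of a `disk_lattice_model`, so only the innermost ring shares the
  global symmetry — reproducing a disk whose outer rings are
  symmetry-mismatched with the scaffold.
* `make_cylinder_phantom()` is a Gaussian shell in radius, uniform in
  azimuth, boxcar in z: the azimuthally featureless limit against which
  the symmetry detector must report "none".
* `make_half_maps()` adds two independent white Gaussian noise fields at a
  requested signal-to-noise variance ratio. Real cryo-EM noise is
  structured; white noise is sufficient to exercise the FSC machinery and
  is not claimed to model micrographs.
* `simulate_stepping_trajectory()` steps a rotor around a lattice of
  `n_steps_per_rev` dwell angles with exponential waits (mean
  `1/step_rate`), instantaneous transitions and immediate bead relaxation
  (no kinetic parameters are modelled), places the bead on an elliptical
  orbit and adds Gaussian localization noise per coordinate.

Defaults emulate a de-energized, slowly rotating motor watched with a
high-speed camera: 26 dwells per revolution, 1,000 frames/s, a step rate
of 50/s (20-frame mean dwell, about two revolutions per second), a
150 x 90 nm orbit, 20 nm localization noise, and no back-steps. The
stepping rate is a free parameter: no proton-motive-force decay model is
attempted. All generators are pure functions of their parameters and
seed, restore the caller's RNG state, and are bit-reproducible.

What passing tests on these phantoms does *not* show: performance on real
maps with structured noise, masking effects, partial occupancy, or on
assays with drift and photobleaching — trajectories are assumed
stationary.

## Cyclic symmetry from azimuthal power spectra

`azimuthal_power_spectrum()` resamples the map on polar rings inside a
cylindrical annulus (trilinear interpolation; radial and axial step one
voxel; `4 * k_max` azimuthal samples for anti-aliasing), averages to a 1D
azimuthal signal, and returns `S(k) = |c_k|^2`. A request above the
azimuthal Nyquist limit of the resampling (`pi * r_min / voxel`) errors.

`detect_cyclic_symmetry()` reports the harmonic of maximal power if it is
significant, with two guards:

* **Significance** is peak power in units of the spectrum's median
  absolute deviation above its median. The null distribution of spectral
  power is approximately exponential, so its tail is heavy: calibration
  on 1,000 pure-noise maps at the default phantom geometry put the
  largest null score at 38 MADs. The default cut is therefore **40
  MADs** — a few-sigma rule would fire on essentially every noise map.
  Genuine blob rings score six or more orders of magnitude higher, so the
  cut position is uncritical for real signals.
* **A relative power floor** (`1e-4` of the squared azimuthal mean)
  prevents an azimuthally uniform map from being called symmetric on the
  basis of grid-interpolation ripple, which is tiny but non-random
  (4-fold, from grid anisotropy).

Because a ring of discrete subunits puts power at its fundamental and all
multiples, the argmax can land on an overtone; the call is resolved down
to the smallest significant divisor of the argmax of which every
significant peak is a multiple. The detector recovers every order n in
2..41 on noiseless phantoms at the default geometry and is invariant to
rotation about z and to uniform density scaling.

## Lathing and radial profiles

`impose_cyclic_symmetry()` averages n in-plane rotations (bilinear
resampling). `cylindrical_average()` computes the exact azimuthal mean by
polar regridding: rings at half-voxel radial steps and 256 azimuthal
samples, averaged and mapped back by linear interpolation in radius. The
discrete 360-rotation average is retained in the test suite as an
independent oracle; the two agree within 1% of the map maximum, and both
conserve total density within 0.5%. Interpolation makes repeated
application smooth the map slightly, so idempotence holds to a few
percent of the peak, not exactly.

`radial_density_profile()` averages over azimuth and an axial band per
radial annulus (bin width one voxel), and `peak_radius()` refines the
argmax by parabolic interpolation through three bins — sub-voxel accuracy
on smooth walls (the 62 A shell phantom reads within half a voxel). A
constant profile has no peak and errors.

## Fourier shell correlation

`fsc_curve()` computes the per-shell normalized cross-correlation of the
Fourier transforms on cubic grids (shell width one reciprocal voxel), and
`resolution_at_threshold()` interpolates the first crossing below the
threshold (0.143 half-map, 0.5 map-model), returning the Nyquist bound
flagged "not crossed" when the curve never drops. No masking or
phase-randomization correction is applied. Two numerical notes: FSC of a
map with itself is exactly 1 by construction, and recovery of a known
band limit is only sharp when the underlying map still has spectral power
near the cutoff — the validation phantom therefore uses blobs with sigma
comparable to the voxel size (64^3 grid, 2 A voxels, 16 A cutoff, SNR 50,
estimate within 15%).

## Disk lattice stoichiometry

The basal disk is modelled as closed concentric circles (not a spiral)
with a constant arc length per protomer, fixed by the innermost ring:
`s = 2 pi R1 / n1`. Ring i at radius `R_i = R1 (1 + s_r (i-1))` then
carries `round(n1 R_i / R1)` protomers (round-half-to-even; the model is
scale-free in R1). Neither the inner radius nor the radial spacing is
printed in the source literature; the packaged spacing ratio
`s_r = 0.216` is a derived constant chosen so the model reproduces the
published increment of 11 protomers per ring from an inner ring of 51
(17 trimers), and it is overridable everywhere. A brute-force packing
oracle (largest n whose arc is at least `s (1 - 1/(2n))`) agrees exactly
with the rounding formula across 1,000 random models in the tests. The
symmetry of rings beyond the first is treated as unknown; the +11
increment is taken as exact.

`symmetry_mismatch()` and `mesh_registry()` capture the arithmetic of the
cogwheel picture: 17 stator pentamers against a 38-tooth C-ring have
gcd 1, so all 17 cogs would need distinct rotational registries to mesh
simultaneously, whereas a commensurate pair (17 against 34) meshes
identically.

## Additive stator torque

Maximum torque is `tau = N F r` — stator count times per-stator
tangential force times contact radius — with additivity taken as exact;
no load-line or duty-ratio correction is modelled. The packaged constants
are N = 17 (vs 11), F = 7.3 pN, and contact radii r = 26.5 nm (vs
20.0 nm). The radii are *derived* constants (reverse-computed from the
published torque predictions of 3,288 and 1,606 pN nm), clearly labelled
as such in the default config, and meant to be replaced by radii measured
from maps (`peak_radius()`, converted with `angstrom_to_nm()`) when
available. `infer_stator_force()` is the exact algebraic inverse;
`compare_motors()` decomposes a torque ratio into N, F and r factors.

## Bead-assay step detection

The pipeline is: orbit ellipse -> rotor angle -> (smoothing) -> weighted
angular power spectrum and wrapped KDE -> dwell count.

**Orbit fitting.** The algebraic conic fit (Fitzgibbon / Halir-Flusser)
is exact on noiseless data but biased at assay noise levels: 20 nm of
localization noise on a 150 x 90 nm orbit inflates the fitted axes by
several percent. An axis-ratio error beta phase-modulates the extracted
angles at `2 theta`, which multiplies the dwell signal by Bessel factors
and moves power into k +/- 2 sidebands — enough to miscall a 40-dwell
lattice as 38. Two measures remove the bias: the fit runs on a
boxcar-smoothed copy of the trajectory (the bead dwells, so time-averaged
positions lie on the orbit with noise reduced by sqrt(window); default 15
frames), and `refine_orbit_ellipse()` then iterates a linear regression
of the positions on `(1, cos theta, sin theta)` of the current angle
estimates.

**Angle smoothing.** At the default conditions the per-frame angular
noise (~0.19 rad) is comparable to a 26-dwell step (0.24 rad), so the
spectrum of raw angles is damped by `exp(-k^2 sigma^2 / 2)` — about 1e-8
at k = 26 — and no recording length can recover it. Averaging the
unwrapped angles over a window shorter than a dwell lifts the damping
while preserving the lattice. Since the dwell time is unknown a priori,
the window is chosen from {3, 5, 9, 15, 25} frames to maximize the peak
spectral significance.

**The spectrum and its null.** `S(k)` is the squared magnitude of the
weighted empirical characteristic function; with frame-duration weights
dwells are weighted by the time spent in them, and S is bounded in [0,1],
exactly invariant to a global angle offset ("phase-invariant"), and equal
to 1 for a point mass. Two properties of real recordings colour its
null: a finite number of revolutions leaves Gamma-distributed occupancy
fluctuations that put power at low harmonics with the same damping
envelope as a true lattice, and residual orbit error concentrates power
at the first few harmonics. Significance is therefore scored on a
locally whitened spectrum (power divided by a running-median background,
in MAD units above the median), and the default search range starts at
k = 5 — the same argument that excludes k = 1 as orbit-centring error
applies to the lowest harmonics generally. The significance cut of 70
was calibrated on 1,000 steady-rotation null trajectories passed through
the identical adaptive pipeline (no false positives; largest null scores
near 50), while genuine lattices at default conditions score from ~150
(40 dwells) to >1,000 (26 dwells).

**The KDE estimator.** The wrapped von Mises density (concentration
`kappa = 4 n^2`, i.e. a kernel sd of `1/(2n)` radians, narrow relative
to the dwell spacing `2 pi / n`) is computed exactly in the Fourier
domain on a 1024-point grid, so rotating the angles rotates the profile
exactly. Under the uniform null the pointwise variance of the estimate
has a closed form, `Var = sum_k rho_k^2 sum_j w_j^2 / (2 pi^2)` (with
rho the kernel's Bessel ratios and w the normalized weights), inflated
by the smoothing window to account for frame correlation. A profile
whose maximal excess over `1/(2 pi)` clears 4 null SEs is searched for
local maxima; peaks above one null SE and a tenth of the maximal excess
are counted, a gentle gate because dwell occupancies genuinely fluctuate
between revolutions. The spectral estimator is primary; KDE peak counts
are reported alongside, not reconciled.

**Performance envelope.** Across lattices of 10 to 40 dwells at the
default conditions (1e5 frames, 20 nm noise, 20 seeds per n), the
spectral estimator recovered the true count exactly in all 620 runs at
build time; the test suite re-runs this sweep. Errors, when the margin
is thinned (shorter recordings), appear as +/- 1 — consistent with a
25-to-27 spread around a true 26.

## Pipeline, I/O, CLI

MRC2014 support is deliberately minimal: mode 2 (float32), isotropic
voxels, standard axis order; anything else errors by name, and truncated
files error rather than yield partial maps. Trajectories are `t,x,y` CSV
at 9 significant digits. `run_pipeline()` executes a declared stage list
from YAML or a list, with all seeds fixed from the config and every
record carrying the package version, seed and input echo; re-running a
config reproduces outputs exactly (timestamps aside). The `flagmotor`
CLI script in `inst/cli/` is a thin wrapper over these functions that
prints JSON to stdout and exits non-zero with a one-line message on
error.

## Known limitations

* No cryo-EM image formation, masking, sharpening or denoising; FSC on
  phantoms says nothing about map post-processing pipelines.
* The disk model cannot distinguish concentric rings from a tight spiral;
  the spiral alternative is noted but not implemented.
* Torque additivity and static stator occupancy are assumptions, not
  fits; duty-ratio physics is represented only by the mesh-registry
  arithmetic.
* Step detection assumes a stationary orbit (no drift correction) and
  counts dwell positions per revolution; it does not estimate stepping
  kinetics or detect individual step times.
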