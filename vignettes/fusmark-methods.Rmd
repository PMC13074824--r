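---
title: "Methods: acoustic holography, PRF thermometry and volumetry in fusmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic holography, PRF thermometry and volumetry in fusmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusmark)
```

fusmark quantifies how a small implanted object — a breast biopsy marker —
perturbs MR-guided focused ultrasound (MRgFUS) therapy, along the four
measurement chains such a study uses: acoustic field reconstruction from
hydrophone scans, PRF-shift MR thermometry with CEM43 thermal dose,
signal-void artifact segmentation, and gross-pathology volumetry. Every
chain can be driven end to end by the package's synthetic-physics
generators, so each stage is verifiable against known ground truth. This
vignette records the models, the defaults and the numerical choices.

## Acoustic forward model

The source is a spherically curved bowl (default: 1 MHz, 13 cm radius of
curvature, 15.4 cm aperture) radiating into water (c = 1482 m/s at 20 °C;
the package default stays with water because hydrophone scans are made in
a water tank, not in the gelatin whose sound speed is 1549 m/s). Fields
are computed by the Rayleigh–Sommerfeld integral over the discretized
bowl surface,

$$p(\mathbf r) = \frac{-ik}{2\pi}\sum_j \frac{e^{ikR_j}}{R_j}\,\Delta S_j ,$$

in units of $\rho c u_0$. The surface is discretized into equal-area
rings (default ≥ 40 000 patches); because patch areas sum exactly to the
spherical-cap area, the on-axis focal value converges essentially to
machine precision, and tests verify both the focal value and off-focus
axial points against the closed-form bowl solution, plus the < 0.1 %
change under halving the discretization.

A biopsy marker in the beam is modelled as a *thin complex-transmission
screen*: a disc that multiplies the incident pressure by
$t\,e^{i\phi}$, $0 \le t \le 1$, inside its radius. The simulator
propagates source → screen plane by the Rayleigh integral, applies the
transmission, and continues screen → measurement plane with the angular
spectrum method. This deliberately ignores full-wave scattering,
reflection and mode conversion — the screen reproduces the geometric
shadowing and diffraction that dominate focal-spot degradation, which is
what the downstream metrics measure. A screen of zero radius or unit
transmission is recognized as a no-op and reuses the control field
exactly.

## Angular-spectrum projection

`project_plane()` implements the spatial planar projection: the measured
plane is decomposed by 2D FFT into plane waves, each multiplied by the
transfer function $H = e^{ik_z\Delta z}$ with
$k_z = \sqrt{k^2 - k_x^2 - k_y^2}$, and resynthesized at each target
plane over (by default) a 2 × 2 × 4 cm volume at 0.5 mm sampling
(81 planes), mirroring a 41 × 41, 0.5 mm hydrophone raster.

Numerical choices:

* **Evanescent components are zeroed**, not decayed. Validation includes
  *backward* projection (a far-field scan projected toward the source),
  where evanescent amplification is unstable; zeroing is the standard
  acoustic-holography practice.
* **Zero padding**, default `pad_factor = 2` per axis, suppresses the
  circular-convolution wraparound of the FFT. The projection-validation
  tests use `pad_factor = 4`.
* **Δz = 0 returns the measured plane unchanged** — the measurement is
  the best estimate of itself; no spectral round trip is applied.
* A **coverage warning** fires when the maximum projection distance
  exceeds twice the padded window half-width, the regime where the
  finite aperture angularly under-covers the target plane.

Verification: a uniform plane is an exact eigenfunction
(`pad_factor = 1`, error 0); +Δz/−Δz round trips recover an
evanescent-free field to 10⁻⁶; propagating-band power is conserved to
10⁻⁶; and projections of the focal-plane scan to ±6 mm agree with
directly simulated planes with normalized RMSD ≈ 1 % — the package's
noiseless analogue of validating a projection code against repeated
physical scans at axial offsets.

## Focal-spot metrics

`focus_metrics()` compares a test volume against its control:
fractional peak change; *focus volume* — the largest contiguous region
above half that volume's own maximum (each volume uses its own
half-maximum); displacement between the two peaks; and insertion loss
$-20\log_{10}(p_\text{test}/p_\text{control})$.

* **Contiguity** is 6-connected (face adjacency) by default throughout
  the package, configurable to 18 or 26.
* **Peak position** is the voxel argmax, ties broken by the first
  occurrence in column-major (raster) order. An optional 3-point
  parabolic sub-voxel refinement exists but is off by default, since
  the source texts for such metrics do not define peak-vs-centroid
  conventions and the voxel argmax is reproducible.
* **Insertion loss** is computed on volume peaks by default. Because
  "in-plane" loss is ambiguous (plane peaks vs integrated power), a
  plane-peak variant is provided behind
  `insertion_loss_mode = "plane"`; integrated-power loss is deliberately
  not guessed at.
* The RMSD between volumes is normalized by the **reference peak** by
  default; reference-RMS and joint-peak normalizations are selectable,
  since "normalized RMSD" admits all three readings.

## MR thermometry

The PRF chain is: complex baseline average → per-frame principal-value
phase difference → linear conversion
$\Delta T = \Delta\phi / (2\pi\,\gamma\,\alpha\,B_0\,\mathrm{TE})$,
with defaults γ = 42.577 MHz/T, α = −0.01 ppm/°C, B₀ = 3 T, TE = 12 ms
and 2.16 s per dynamic — the standard water PRF coefficient and a 3 T
segmented-EPI thermometry readout. With this sign convention heating
*lowers* phase; `phase_sign` flips it for scanners with the opposite
convention. No temporal unwrapping is applied: at 2.16 s dynamics the
expected per-frame change is far below π, and a warning is logged
whenever any frame-to-frame step exceeds π/2.

The **SNR mask** (construction unspecified in the protocols this
emulates, so defined here) keeps voxels whose time-mean magnitude
strictly exceeds k·σ, k = 5 by default, with σ the per-channel noise sd
estimated from a signal-free region; a temporal variant estimates σ from
frame-to-frame complex differences in any static region, for
acquisitions (and synthetic phantoms) with no signal-free background.

**CEM43** uses the standard piecewise rate, R = 0.5 at or above 43 °C
and 0.25 below, integrated rectangularly at the dynamic interval, in
minutes; dose is additive across concatenated sonications via the
`prior` argument. Threshold conventions follow the wording they encode:
the 240 CEM43 ablation volume is *inclusive* ("at least") and
contiguous (largest connected component); the > 10 °C treatment-volume
proxy is *strict* ("greater than") and deliberately noncontiguous —
every qualifying voxel counts. The proxy uses the temporal maximum of
ΔT by default (`statistic = "per_frame"` exposes the alternative, since
either reading of a per-study statistic is defensible).

## Synthetic MR series

`simulate_mrti_series()` generates complex frames with: uniform phantom
magnitude; a marker signal void (zero magnitude within `void_radius`,
one-voxel smooth roll-off); static dipole phase
$A\,(3\cos^2\theta - 1)/r^3$ about the B₀ axis — a far-field
point-dipole pattern with a single amplitude constant rather than SI
susceptibility constants, because downstream code needs a realistic
spatial pattern, not a calibrated Δχ; optional temperature-dependent
scaling of that amplitude by the marker-adjacent ΔT (emulating
temperature-dependent marker susceptibility); PRF phase from the heat
field; and circular complex Gaussian noise at
σ = mean magnitude / SNR per channel.

Heating is an instantaneous anisotropic Gaussian deposit evolved by the
exact heat-kernel solution

$$\Delta T(\mathbf r,t) = \Delta T_0 \prod_a
\sqrt{\tfrac{\sigma_a^2}{\sigma_a^2 + 2Dt}}\;
\exp\!\Big(-\sum_a \tfrac{r_a^2}{2(\sigma_a^2+2Dt)}\Big),$$

with D = 0.143 mm²/s (a milk-gelatin phantom value) by default. The
returned ground-truth frames let tests assert recovery: noiseless series
reproduce ΔT to 10⁻⁶ °C, and at SNR 50 the RMS error at the true peak
voxel sits at about 1.0 × the analytic phase-noise bound
$\sigma_{\Delta T} = \sqrt{1 + 1/B}\,/\,(\mathrm{SNR}\,\cdot 2\pi\gamma|\alpha|B_0\mathrm{TE})$
for B baseline frames.

What the generator does *not* emulate: intravoxel dephasing physics of
the signal void (the void is carved geometrically), B₀ drift, motion,
fat signal, and acoustic-thermal coupling (sonication "power" simply
scales the deposit's peak ΔT, 0.625 °C/W by default so the study's 24 W
point sonications give a 15 °C peak rise). Passing tests therefore
demonstrate the correctness of the *measurement chain*, not the fidelity
of any scanner.

## Signal-void segmentation

`segment_signal_void()` encodes the noise-referenced rule: threshold at
125 % of the mean of a user-identified no-signal region, candidates are
voxels *strictly below* the threshold inside the phantom mask, and the
void is the largest connected component — the reproducible stand-in for
an interactive "select the contiguous region" step; a `seed_point`
override handles multi-void images. Because the threshold scales with
the noise mean, segmentation is invariant under positive rescaling of
the image. Extent per axis is the maximum number of mask voxels on any
line parallel to that axis times the spacing (the literal
voxel-counting reading); a bounding-box variant is exposed because the
phrase admits both. Strict-vs-inclusive at the exact threshold is
documented as strict and tested.

## Gross-pathology volumetry

The ablated volume of a serial slice stack is
$V = \sum_i A_i t_i$ with first-order (GUM) propagation under
independence,
$u(V)^2 = \sum_i \big(t_i^2 u(A_i)^2 + A_i^2 u(t_i)^2\big)$ — the
propagation formula itself is not specified by the protocols this
mirrors beyond "independent components", so the GUM form is the natural
completion. Slices with zero area contribute nothing. When no
repeat-based area uncertainty is available, a boundary heuristic is
used: $u(A) = n_\text{boundary} \times \text{pixel area}/\sqrt{12}$,
reflecting that annotation uncertainty concentrates in a one-pixel band
at the boundary. This module works in bench units — mm/pixel, mm
thickness, cm² areas, cm³ volumes — because that is how slice
photographs and caliper logs arrive.

The generator slices an ellipsoid at ~1.5 mm (deli-slicer scale) with
per-slice thickness jitter (default sd 0.1 mm, a caliper
repeat-measurement scale) and fractional area jitter (default 5 %, an
annotation-spread scale); the mask is the cross-section at each slab's
mid-depth. Tests verify the analytic u(V) against a 10⁵-draw Monte
Carlo (within 5 %) and a coverage property: over 200 seeded replicates,
the estimate falls within 2 u(V) of the true ellipsoid volume in well
over 90 % of cases. One caveat found during design: a half-max or
threshold sphere centred *exactly* on a voxel centre is a degenerate
alignment whose lattice-point count can deviate anomalously (+5.4 % for
the 2.35 mm radius used in the hot-volume test); volumetric fixtures
therefore centre features on a voxel corner, the generic case.

## Experiment drivers and reproducibility

`run_acoustic_experiment()` reproduces the marker-vs-control design: six
marker positions (focal plane and 7 mm far-field; centred and 3 mm
lateral along each transverse axis), each simulated as a screened scan,
projected, and tabulated against the shared control. The scan plane
sits downstream of every marker plane (default +12 mm), as on a bench
where the hydrophone scans past the phantom and the volume is
reconstructed by back-projection. `run_thermometry_experiment()` runs
paired marker/control arms per sonication — shared heating and noise
seeds, marker-arm dipole/void/susceptibility — through the full mask →
phase → ΔT → CEM43 chain. Every run can write a manifest (config YAML,
its MD5, seeds, package version); repeated runs with the same config are
byte-identical, which the tests assert on the CSV hashes.

Problem sizes in the shipped tests and acceptance script — 41 × 41
scan planes, 2500–40 000 source patches, 17³–61³ voxel grids, 100–200
replicates — were chosen so the full verification chain runs in well
under a minute per module on a single core while keeping discretization
error far below the tolerances being asserted.

## Known limitations

* The acoustic model is linear and lossless: no nonlinearity, no
  attenuation, no full-wave marker scattering. A 256-element array is
  approximated as a continuous bowl, so printed free-field spot sizes of
  a real array are not exactly reproduced.
* Thermometry omits multi-baseline/referenceless methods, fat
  correction, motion, and any susceptibility-artifact correction — the
  chain measures what a standard PRF pipeline would measure, including
  its artifacts.
* The noise-region choice for SNR masks and segmentation thresholds is
  the user's; automatic background detection is out of scope.
* Gross-pathology masks are consumed as given; annotation/classifier
  training and slice registration are out of scope.
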