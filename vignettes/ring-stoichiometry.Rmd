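---
title: "Symmetry and stoichiometry analysis of flagellar motor components"
author: "ringstoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry and stoichiometry analysis of flagellar motor components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringstoich)
```

## The scientific problem

The bacterial flagellar motor is a stack of coaxial protein rings whose
cyclic symmetries disagree with one another. In high-torque motors such as
that of *Campylobacter jejuni*, a 17-fold periplasmic scaffold positions a
widened ring of stator complexes around a 38-fold C-ring, while the
outer-membrane bushing (the LP-ring) retains a 26-fold symmetry and the
innermost ring of the ~100 nm basal disk carries 51 protomers — 17 trimeric
repeats. Working out these stoichiometries from cryo-EM density maps, and
cross-checking the LP-ring count against single-molecule bead-rotation
recordings, involves a family of small bespoke analyses that this package
implements as tested, reusable functions:

* **Cylindrical-coordinate map analysis** — lathing (azimuthal averaging),
  Cn symmetrization, azimuthal power spectra of annular regions, radial
  feature measurement, low-pass filtering and Fourier shell correlation
  (FSC).
* **Ring lattice geometry** — bending a linear oligomer repeat onto a closed
  arc, predicting concentric-ring protomer counts from circumference ratios,
  and the gcd arithmetic of symmetry-mismatch registration.
* **Bead dwell analysis** — ellipse-corrected angle extraction from
  tethered-bead x,y trajectories, occupancy-weighted circular kernel density
  estimation, and dwell counting from the angular power spectrum.
* **Synthetic data** — phantom density volumes and stepping-bead
  trajectories with exactly the statistical structure the analyses assume,
  so every stage is testable without any experimental download.

## Density volumes and their cylindrical analysis

A `DensityVolume` is a cubic-voxel grid (even box) whose assumed symmetry
axis is the z grid line through the box centre. `resampleCylindrical()`
interpolates it onto an (r, θ, z) grid whose θ count is a power of two
(default 256) so the per-(r, z) azimuthal DFT is a plain FFT; samples whose
pre-image leaves the box are flagged `NA`, never zero-filled.

The azimuthal power spectrum of an annulus is

$$P(m) \;=\; \sum_{r,z \in \text{annulus}} r \, \lvert F_m(r,z)\rvert^2 ,$$

area-weighted by r and normalized so that the power over harmonics $m \ge 1$
sums to one; the $m = 0$ (azimuthal mean) term is kept unnormalized so that
flatness — e.g. of a lathed map — can be judged against it.
`detectSymmetry()` reports the argmax over a harmonic window (default
10–50, bracketing the orders 17, 26, 38 and 51 that matter for flagellar
motors while excluding low-order shape artifacts), with ties broken toward
the smaller order, together with a peak-to-median confidence ratio so flat
spectra yield an explicit "no call" rather than a spurious order.

**Confidence calibration.** The confidence of a genuine ring at the bundled
study conditions is two orders of magnitude above the no-call threshold
(1.5), while pure-noise annuli sit near 1.2. The calibration assumes the
annulus radii satisfy $r \gtrsim m_{\max} \cdot \text{voxel}/\pi$: at
smaller radii the azimuthal samples are coarser than the voxel pitch, the
interpolated noise becomes azimuthally correlated, and its spectrum tilts
toward low harmonics. The bundled annuli respect this bound.

**Lathing** maps the volume to its azimuthal average. Every voxel
contributes at its *exact* radius through linear "hat" binning at the voxel
pitch, and the resulting (r, z) profile is interpolated back with the same
basis. The azimuthal mean itself is therefore exact; the only error is the
radial hat-basis smoothing, which also bounds the non-idempotence of the
operation. The same machinery drives `radialProfile()`, whose highest local
maximum `estimateFeatureRadius()` refines with a three-point parabola
(clamped to ±half a bin) for sub-voxel radii such as the 62 Å versus 51 Å
β-collar comparison.

**Cn symmetrization** averages the n in-plane rotated copies of the volume
(bilinear per-slice interpolation; samples rotated in from outside the box
are filled with zero, which only affects the corners). Lathing equals the
large-n limit of symmetrization; the suite asserts their agreement at
n = 360.

**FSC** is the per-shell normalized cross-correlation of Fourier
coefficients, with shells one Fourier voxel wide out to Nyquist.
`resolutionAt()` interpolates the first downward crossing of a threshold
(0.5 map-model, 0.143 half-map, exported as named constants); a curve that
never crosses is reported at the Nyquist resolution with `crossed = FALSE`.
`scoreRingFit()` rasterizes a pseudo-atomic model on the target grid,
applies a soft spherical mask around the model to both maps (raised-cosine
edge, default 12 Å), and reports the 0.5-crossing — the protocol used to
rank candidate ring stoichiometries against a map.

### Interpolation tolerances

All resampling is trilinear (reducing to bilinear in-plane because z samples
coincide with voxel planes). With features whose Gaussian width is about two
voxels — the sharpest the bundled fixtures use — measured invariance errors
(rotation of a Cn phantom by 2π/n, symmetrization idempotence, lathe
idempotence, lathe versus C360) are a few percent of the peak density in
max-norm and 1–3 % of the map standard deviation in RMS. The tests assert
these bounds per operation (5–8 % of peak in max-norm, 3–8 % of sd in RMS)
rather than a single blanket figure: a one-size tolerance of 1 % of sd is
not attainable in max-norm for linear interpolation at this feature
sharpness, and asserting it would either fail honestly or force artificially
smooth fixtures.

## Ring lattice geometry

`bendToArc()` places n rigid copies of a protomer (blobs in the oligomer
frame: x tangential, y radial, z axial) at radius $r = n \cdot
\text{rise}/(2\pi)$, protomer k rotated by $2\pi k/n$; an optional lattice
twist rotates protomer k by $k\,\tau$ about its local tangent. Closure is
exact by construction, and the neighbour chord $2r\sin(\pi/n)$ tends to the
rise as n grows (within 0.5 % already at n = 51). All bending distortion is
implicitly absorbed by the interfaces: protomers are never deformed, which
reproduces the geometric step of arc-fitting without any atomistic
re-refinement.

`predictRingCounts()` implements the circumference-ratio stoichiometry
model: the first ring (n₁ protomers at radius r₁) fixes the protomer arc
width $w = 2\pi r_1/n_1$, and ring k carries $\mathrm{round}(2\pi r_k/w)$
protomers. Rounding is half-away-from-zero, and counts whose fractional
part falls within 0.05 of one half are flagged `nearHalf` so the rounding
model's ties stay visible. With radial spacing $\Delta r = 11\,w/(2\pi)$
every ring gains exactly 11 protomers — the arithmetic behind a 51, 62, 73,
… progression of basal-disk rings. Neither the effective arc width w nor
the physical ring spacing is dictated by the package: fixtures choose them
freely, and only the increment logic is asserted.

`registerSymmetry()` is pure gcd arithmetic: with $g = \gcd(n_\text{ring},
n_\text{scaffold})$, a commensurate pair repeats every $n_\text{ring}/g$
ring protomers and contacts g of them per turn (51 against 17: every third
protomer, 17 contacts), while $g = 1$ pairs (26 against 17 — the LP-ring
against the scaffold) are flagged incommensurate.

## Bead dwell analysis

A tethered bead on a slowly rotating flagellar stub projects onto the
camera as an ellipse. `fitEllipse()` uses the numerically stable direct
algebraic least-squares conic fit (centred and scaled for conditioning,
eigen-decomposition of the reduced scatter system, constrained to an
ellipse), `toAngularTrace()` inverts centre, orientation and axis scaling
before taking the angle — removing the twice-per-revolution speed
modulation an uncorrected ellipse imposes — and unwraps. An uncorrected
mode is kept for sensitivity analysis.

`circularKde()` places a von Mises kernel on each wrapped angle, weighted
by its time step (occupancy weighting), on a 2048-point grid. The default
concentration is set so that the kernel FWHM is half the finest resolvable
dwell spacing, $(2\pi/50)/2$, via $\kappa = \ln 2 / (1 - \cos(\text{FWHM}/2))
\approx 1.4\times 10^3$; Bessel normalization uses the exponentially scaled
`besselI` so large κ stays finite.

`stepSpectrum()` evaluates the Fourier power of the occupancy-weighted
angular distribution at integer harmonics, $F_m = \sum_i w_i e^{-im\theta_i}$
with per-trace weight normalization, and combines traces by a weighted mean
with weight proportional to revolution count. The published description of
this analysis does not pin down the weighting; the package's reading —
samples weighted by occupancy time within a trace, traces by revolutions
across traces — is chosen because slow, de-energized segments carry the
dwell information while revolutions, not samples, measure how much
independent dwell structure a trace saw. This is an explicit interpretation
and may differ from the original authors' script. `countSteps()` then takes
the argmax over harmonics 10–50, reports a peak-to-median confidence, and
carries a subharmonic-alias diagnostic (power at n/2 exceeding power at n).
Its no-call threshold (15) is much higher than the volume detector's: a
single-trace spectrum averages far fewer independent cells than an annulus,
so occupancy fluctuations of a dwell-free trace produce peak-to-median
ratios approaching 10, while genuine dwell structure at the bundled
conditions scores near 100.

`phaseInvariance()` cross-correlates dwell densities between conditions
(FFT-based with parabolic sub-grid refinement), reduces each pairwise lag
modulo the dwell spacing 2π/N, and declares phase invariance when every lag
magnitude stays below π/N (with a half-grid-step guard against
discretization) — the criterion behind calling dwell positions stable
across de-energization levels.

## What the synthetic generators emulate — and what they do not

`makeMotorPhantom()` builds direct 3-D densities: protomer rings (an
asymmetric "L" of 3–10 Gaussian blobs, so azimuthal phase and handedness are
detectable and no nuisance symmetry survives), concentric-disk stacks, and
azimuthally featureless tubes, plus additive Gaussian noise and an optional
missing wedge (a zeroed double wedge about the tilt axis; the default
half-angle 33° corresponds to a ±57° tilt range). SNR is defined as the
signal-to-noise *power ratio over the box*: noise sd =
$\sqrt{\overline{s^2}/\text{SNR}}$. There is no image-formation model — no
CTF, dose weighting or projection — and no atomic detail or protomer
deformation. Passing the suite therefore demonstrates that the estimators
recover the parameters of data obeying their own assumptions at realistic
noise levels; it does not certify performance on real micrographs, where
heterogeneity, alignment error and structured background dominate. The
missing wedge is generated but deliberately not compensated in the
spectrum; it inflates low-order power, which the default m ≥ 10 window
avoids.

The standard phantom (box 192³ at 2 Å — matching the 1.75–2.2 Å/px scales
typical of such data — with a C26 ring at r = 60 Å, a C17 ring at
r = 110 Å, a C38 ring at r = 140 Å and a featureless rod, SNR 0.5, seed
20231009) defines the bundled study conditions; `standardAnnuli()` carries
the matching analysis windows. The exhaustive noise-free detector sweep
runs over n = 7…51 on 96³ boxes, and the robustness floor asserted by the
suite (correct C17 call at SNR 0.1, fixed seeds) is a regression bound on
these phantoms, not a universal claim.

`simulateBead()` makes the motor angle a continuous-time jump process over
N equally spaced dwells: exponential dwell times with mean
`meanDwellTime / deenergization`, strictly unidirectional steps of 2π/N
(the experimental strain deletes the switching response, so no
back-stepping is modelled), elastic-linkage angular noise per sample,
elliptical projection and localization noise. De-energization by CCCP is a
pure rate multiplier — no torque model. Defaults (N = 26, 20 ms mean dwell,
250 Hz for 30 s ≈ 57 revolutions, linkage sd 0.05 rad, localization sd 4 %
of the minor axis) are chosen as typical of de-energized bead recordings;
the end-to-end recovery property (N = 20…30, ≥ 9/10 seeded replicates) and
the dwell-time Kolmogorov–Smirnov law (α = 0.01 at ≥ 1000 dwells) pin the
generator to its stated contract.

## Degenerate inputs and edge behaviour

Collinear bead data are rejected by the ellipse fit; samples at the exact
orbit centre are flagged; traces under 10 revolutions warn and traces under
2 revolutions are excluded from spectra with a warning. Empty annuli, annuli
touching unsampled regions, empty z slabs, search windows outside the
profile support, non-power-of-two θ counts, sub-Nyquist low-pass targets and
mismatched FSC grids are all rejected with specific errors; a window with no
local maximum returns "not found" rather than erroring, and an all-zero
spectrum returns "no call". Components whose 3σ envelope crosses the box
edge abort phantom generation naming the component; `rasterize()` instead
truncates with a warning and count, since partial models against a larger
map are legitimate there.

## Design choices where the procedure was genuinely open

* **Symmetry axis** is assumed to be the box z-axis; refined maps are
  already aligned and phantoms are by construction. No axis refinement is
  applied by default.
* **Config serialization** uses YAML as the structured text format for
  pipeline configs and simulation specs.
* **Spiral basal disks** (proposed for *Wolinella*) are not generated; only
  closed concentric rings are modelled, and the package makes no claim
  about distinguishing the two.
* **Replay** (`replayMotorAnalysis()`) regenerates every headline quantity
  from the bundled conditions in one call with one master seed, recording a
  pass/fail per quantity (integers exact, collar radii within 1 Å), so the
  whole surface is exercised by a single deterministic entry point. Its
  negative control (a 13-dwell simulation against the 26-dwell expectation)
  checks that the harness can fail.

## Problem sizes

The bundled conditions run on one CPU in seconds to a few minutes: the
192³ standard phantom for symmetry detection and collar radii; 96³ boxes
for the detector sweep, ring-fit ordering and FSC properties; 48³ boxes
for the C360-lathe comparison; 24³ boxes for brute-force oracles; and
7 500-sample bead traces (110 of them in the end-to-end recovery
property). These sizes were chosen so that spectra and profiles average
over enough cells for stable statistics while a full suite run stays
interactive.

## Known limitations

Beyond the synthetic-data caveats above: the FSC assumes an unmasked,
untapered box (callers mask explicitly via `softSphericalMask()`); the
radial profile reports the azimuthal *mean*, so sparse high-contrast
features dilute with radius; `detectSymmetry()` assumes a single dominant
order per annulus and will not decompose superimposed symmetries; and the
MRC reader supports the common little-endian mode-2, x,y,z-ordered subset
only.
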