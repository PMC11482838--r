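# ringstoich

Rotational symmetry and ring stoichiometry analysis for bacterial flagellar
motor density maps and tethered-bead rotation assays.

## What this is for

The flagellar motor is a stack of coaxial protein rings whose cyclic
symmetries disagree: in high-torque motors such as *Campylobacter jejuni*'s,
a C17 periplasmic scaffold surrounds a C38 C-ring, a C26 LP-ring bushing,
and a basal disk whose innermost ring carries 51 protomers (17 trimeric
repeats), growing by 11 protomers per concentric ring. Determining these
stoichiometries from cryo-EM maps — and cross-checking the LP-ring count
against the number of dwell positions a slowly rotating bead visits — relies
on a family of small bespoke analyses. This package implements them as
tested R functions for structural microbiologists and single-molecule
biophysicists:

* **volume operations** — lathing (azimuthal averaging), Cn symmetrization,
  azimuthal power spectra over annuli, radial profiles with sub-voxel peak
  refinement, low-pass filtering, Fourier shell correlation, MRC mode-2 I/O;
* **ring geometry** — bending linear oligomer repeats onto closed arcs,
  circumference-ratio stoichiometry prediction, symmetry-mismatch
  registration arithmetic, map-model fit scoring;
* **bead assay** — ellipse-corrected angle extraction, occupancy-weighted
  von Mises kernel densities, dwell-count power spectra, phase-invariance
  verdicts;
* **synthetic data** — seeded multi-symmetry phantom volumes and
  stepping-bead trajectories, so every analysis is testable with no
  experimental data.

The core statistic for maps is the area-weighted azimuthal power spectrum of
an annulus,

    P(m) = sum over (r,z) of r * |F_m(r,z)|^2 ,

whose argmax over harmonics m = 10..50 is the detected cyclic order; for
bead traces it is the Fourier power of the occupancy-weighted angular
density, `F_m = sum_i w_i exp(-i m theta_i)`, combined across traces with
weights proportional to revolutions. Ring stoichiometry predictions follow
the circumference-ratio model `count_k = round(2*pi*r_k / w)` with
`w = 2*pi*r_1/n_1`, and registration of a ring against a scaffold is gcd
arithmetic (51 vs 17: one contact per 3 ring protomers, 17 contacts).

## Worked example

```r
library(ringstoich)

spec <- standardPhantomSpec()     # 192^3 voxels at 2 Å, SNR 0.5, seeded
spec
#> MotorPhantomSpec: 4 components, 192^3 voxels at 2 Å
#>   noise: SNR 0.5 (seed 20231009)

phantom <- makeMotorPhantom(spec)
cyl <- resampleCylindrical(phantom)
for (nm in c("scaffold", "cring", "lpring")) {
  det <- detectSymmetry(azimuthalPowerSpectrum(cyl, standardAnnuli()[[nm]]))
  cat(sprintf("%-9s C%-3d (confidence %.0f)\n", nm, det$n, det$confidence))
}
#> scaffold  C17  (confidence 418)
#> cring     C38  (confidence 715)
#> lpring    C26  (confidence 275)

registerSymmetry(51, 17)
#> RegistrationResult: C51 ring vs C17 scaffold
#>   commensurate: one contact per 3 ring protomers (17 contacts)

traj <- simulateBead(BeadSimSpec())   # 26 dwells, ~57 revolutions
res <- countStepsPipeline(traj)
cat(sprintf("dwell count: %d (confidence %.0f)\n", res$n, res$confidence))
#> dwell count: 26 (confidence 378)
```

The detected orders are the phantom's construction symmetries recovered
through the full analysis path (resampling, annular spectra, argmax with
confidence); the registration line is the arithmetic placing one scaffold
contact on every third protomer of a 51-mer ring; the dwell count is the
bead pipeline (ellipse fit, angle extraction, weighted spectrum) recovering
the simulated 26 dwell positions. Confidence is the peak-to-median power
ratio over the search window — values this far above the no-call thresholds
(1.5 for maps, 15 for traces) mean unambiguous calls.

`replayMotorAnalysis()` runs all of the above plus collar-radius recovery
from one config with one seed and returns a pass/fail record per quantity.

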