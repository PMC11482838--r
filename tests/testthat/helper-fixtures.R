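# Shared, lazily built fixtures. Everything is generated in code; nothing is
# read from disk.

.fixtureEnv <- new.env(parent = emptyenv())

cachedFixture <- function(name, build) {
  if (!exists(name, envir = .fixtureEnv))
    assign(name, build(), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

# Cylindrical resampling of the standard motor phantom at its bundled
# conditions (192^3 voxels, 2 Å, SNR 0.5, default seed).
standardCylMap <- function() {
  cachedFixture("stdCyl", function()
    resampleCylindrical(makeMotorPhantom(standardPhantomSpec())))
}

# Small two-ring phantom (C17 + C38) for closing the loop between the
# generator and the symmetry detector at desk scale.
twoRingPhantom <- function() {
  cachedFixture("twoRing", function() {
    p <- defaultProtomer(0.75)
    makeMotorPhantom(MotorPhantomSpec(list(
      RingComponent(p, RingLatticeSpec(17L, radius = 40, zCenter = 20,
                                       phase = 0.2)),
      RingComponent(p, RingLatticeSpec(38L, radius = 70, zCenter = -20,
                                       phase = 0.4))),
      boxSize = 96L, voxelSize = 2, noiseSd = 0))
  })
}

# Smooth single-tube phantom used for lathe/profile/filter checks.
smoothTube <- function(radius = 40, boxSize = 96L) {
  makeMotorPhantom(MotorPhantomSpec(
    list(TubeSpec(radius = radius, wallSigma = 4, zCenter = 0,
                  zHalfWidth = 24, amplitude = 1)),
    boxSize = boxSize, voxelSize = 2, noiseSd = 0))
}

# circular local maxima of a dwell density above a fraction of the peak
densityPeaks <- function(d, frac = 0.25) {
  dens <- d@density
  G <- length(dens)
  nb <- function(k) ((seq_len(G) - 1 + k) %% G) + 1
  which(dens > dens[nb(-1)] & dens >= dens[nb(1)] & dens > frac * max(dens))
}
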