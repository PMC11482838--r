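#' @import methods
#' @importFrom stats fft mvfft rnorm rexp runif median ks.test approx
#' @importFrom utils read.csv write.csv packageVersion
NULL

## ---- internal helpers -------------------------------------------------------

.isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.isPow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

## wrap into [0, 2*pi)
.wrap2pi <- function(theta) theta %% (2 * pi)

## wrap into (-pi, pi]
.wrapPi <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

## round half away from zero (base round() is round-half-even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

## voxel-centre coordinates along one axis, symmetry axis at 0 (index n/2 + 1)
.axisCoords <- function(n, voxelSize) ((seq_len(n) - 1) - n / 2) * voxelSize

.gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

## ---- volumes ----------------------------------------------------------------

#' Density volume on a cubic-voxel grid
#'
#' The container all map operations act on: a 3-D scalar density grid with a
#' physical voxel size. The assumed rotational symmetry axis is the z grid
#' line through the box centre (grid index `n/2 + 1` on x and y); the
#' azimuthal angle theta runs counter-clockwise from +x viewed from +z.
#'
#' @slot grid 3-D numeric array, all dimensions equal and even.
#' @slot voxelSize voxel edge length in ångström.
#' @slot origin physical coordinate of the first voxel corner (ångström),
#'   kept for MRC header round-trips; analyses use the centred frame.
#' @export
setClass("DensityVolume",
  representation(grid = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@grid)
    if (length(d) != 3L) return("grid must be a 3-D array")
    if (length(unique(d)) != 1L) return("voxels must be cubic: all box dimensions equal")
    if (d[1] %% 2L != 0L) return("box dimensions must be even")
    if (!all(is.finite(object@grid))) return("grid contains non-finite values")
    if (!.isScalarNum(object@voxelSize) || object@voxelSize <= 0)
      return("voxelSize must be a positive scalar")
    if (length(object@origin) != 3L) return("origin must have length 3")
    TRUE
  }
)

#' @param grid 3-D numeric array (cubic, even box).
#' @param voxelSize voxel edge length in ångström.
#' @param origin physical origin of the box corner; defaults to the centred
#'   convention, `-(n/2) * voxelSize` on each axis.
#' @return A [DensityVolume-class] object.
#' @rdname DensityVolume-class
#' @export
DensityVolume <- function(grid, voxelSize, origin = NULL) {
  if (is.null(origin)) origin <- rep(-dim(grid)[1] / 2 * voxelSize, 3L)
  new("DensityVolume", grid = grid, voxelSize = voxelSize, origin = as.numeric(origin))
}

setMethod("show", "DensityVolume", function(object) {
  n <- dim(object@grid)[1]
  cat(sprintf("DensityVolume: %d^3 voxels, %.3g Å/voxel (%.1f Å box)\n",
              n, object@voxelSize, n * object@voxelSize))
  cat(sprintf("  density range [%.4g, %.4g], sd %.4g\n",
              min(object@grid), max(object@grid), stats::sd(as.vector(object@grid))))
})

#' Cylindrical resampling of a density volume
#'
#' Values of a [DensityVolume-class] on a regular (r, theta, z) grid about the
#' box-centre z axis. The r and z spacings equal the voxel size; theta covers
#' [0, 2*pi) exactly once with a power-of-two number of samples. Samples whose
#' Cartesian pre-image falls outside the box are `NA` (flagged absent, never
#' zero-filled).
#'
#' @slot values numeric array `[nR, nTheta, nZ]`, `NA` where unsampled.
#' @slot r,theta,z axis coordinates (ångström / radians / ångström).
#' @slot voxelSize voxel size of the source volume.
#' @export
setClass("CylindricalMap",
  representation(values = "array", r = "numeric", theta = "numeric",
                 z = "numeric", voxelSize = "numeric"),
  validity = function(object) {
    nTheta <- length(object@theta)
    if (!.isPow2(nTheta) || nTheta < 256L)
      return("nTheta must be a power of two >= 256")
    if (!isTRUE(all.equal(dim(object@values),
                          c(length(object@r), nTheta, length(object@z)))))
      return("values dimensions must match the (r, theta, z) axes")
    if (any(object@r < 0)) return("r must be nonnegative")
    TRUE
  }
)

setMethod("show", "CylindricalMap", function(object) {
  cat(sprintf("CylindricalMap: %d r x %d theta x %d z samples, r <= %.1f Å\n",
              length(object@r), length(object@theta), length(object@z),
              max(object@r)))
})

#' Azimuthal symmetry power spectrum
#'
#' Power versus integer azimuthal harmonic order m for an annular region of a
#' cylindrically resampled volume. Power at m >= 1 is normalized to sum to one
#' when any is nonzero; m = 0 carries the (unnormalized) mean term and is
#' excluded from peak searches.
#'
#' @slot harmonics integer orders 0..nTheta/2.
#' @slot power nonnegative power per harmonic.
#' @slot annulus named numeric (rMin, rMax, zMin, zMax) in ångström.
#' @slot totalPower unnormalized total power over m >= 1, so flatness can be
#'   judged against the m = 0 (azimuthal mean) term.
#' @export
setClass("SymmetrySpectrum",
  representation(harmonics = "integer", power = "numeric", annulus = "numeric",
                 totalPower = "numeric"),
  validity = function(object) {
    if (length(object@harmonics) != length(object@power))
      return("harmonics and power lengths differ")
    if (any(object@power < 0)) return("power must be nonnegative")
    if (length(object@annulus) != 4L) return("annulus must be (rMin, rMax, zMin, zMax)")
    TRUE
  }
)

setMethod("show", "SymmetrySpectrum", function(object) {
  m <- object@harmonics
  keep <- m >= 1L
  top <- m[keep][which.max(object@power[keep])]
  cat(sprintf("SymmetrySpectrum: m = 0..%d over annulus r [%.1f, %.1f], z [%.1f, %.1f] Å\n",
              max(m), object@annulus[1], object@annulus[2],
              object@annulus[3], object@annulus[4]))
  cat(sprintf("  strongest harmonic (m >= 1): %d\n", top))
})

#' Fourier shell correlation curve
#'
#' Per-resolution-shell normalized cross-correlation of the Fourier
#' coefficients of two volumes on the same grid. Shells are one Fourier voxel
#' wide, non-overlapping, and exhaustive to Nyquist.
#'
#' @slot frequency shell-centre spatial frequency in 1/ångström.
#' @slot correlation correlation per shell, in [-1, 1].
#' @slot shellWidth shell width in 1/ångström (one Fourier voxel).
#' @slot voxelSize voxel size of the input volumes.
#' @export
setClass("FSCCurve",
  representation(frequency = "numeric", correlation = "numeric",
                 shellWidth = "numeric", voxelSize = "numeric"),
  validity = function(object) {
    if (length(object@frequency) != length(object@correlation))
      return("frequency and correlation lengths differ")
    if (any(object@correlation > 1 + 1e-9 | object@correlation < -1 - 1e-9,
            na.rm = TRUE))
      return("correlation must lie in [-1, 1]")
    TRUE
  }
)

setMethod("show", "FSCCurve", function(object) {
  cat(sprintf("FSCCurve: %d shells to Nyquist (%.3g 1/Å)\n",
              length(object@frequency), max(object@frequency)))
})

#' @export
setMethod("as.data.frame", "FSCCurve", function(x, ...) {
  data.frame(frequency = x@frequency, correlation = x@correlation)
})

#' @export
setMethod("as.data.frame", "SymmetrySpectrum", function(x, ...) {
  data.frame(harmonic = x@harmonics, power = x@power)
})

## ---- pseudo-atomic models ---------------------------------------------------

#' Pseudo-atomic model of Gaussian blobs
#'
#' A set of isotropic Gaussian blobs with per-blob amplitude and width, plus a
#' protomer/chain label. Stands in for atomic models in rasterization, ring
#' building, and map-model FSC scoring.
#'
#' @slot atoms data.frame with columns `x, y, z` (ångström), `amplitude`,
#'   `sigma` (ångström, > 0) and `label` (chain/protomer id).
#' @export
setClass("PseudoAtomModel",
  representation(atoms = "data.frame"),
  validity = function(object) {
    need <- c("x", "y", "z", "amplitude", "sigma", "label")
    if (!all(need %in% names(object@atoms)))
      return(paste("atoms needs columns:", paste(need, collapse = ", ")))
    if (nrow(object@atoms) < 1L) return("model must contain at least one blob")
    if (any(object@atoms$sigma <= 0)) return("sigma must be > 0 for every blob")
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) return("blob offsets must be finite")
    TRUE
  }
)

#' @param atoms data.frame of blob positions and parameters.
#' @return A [PseudoAtomModel-class].
#' @rdname PseudoAtomModel-class
#' @export
PseudoAtomModel <- function(atoms) {
  if (is.null(atoms$label)) atoms$label <- "A"
  new("PseudoAtomModel", atoms = atoms)
}

setMethod("show", "PseudoAtomModel", function(object) {
  cat(sprintf("PseudoAtomModel: %d blobs, %d chains\n",
              nrow(object@atoms), length(unique(object@atoms$label))))
})

#' Protomer building-block shape
#'
#' Blobs are expressed in the protomer frame: local x tangential (direction of
#' lateral oligomerisation), local y radial (outward once placed on a ring),
#' local z axial. The default fixture is an asymmetric "L" of blobs so that
#' azimuthal phase and handedness are detectable; real protomers (FlgP, FliF,
#' FliM) are proteins, and this shape only reproduces their lattice geometry.
#'
#' @slot blobs data.frame with columns `dx, dy, dz, amplitude, sigma`.
#' @slot label text label.
#' @export
setClass("ProtomerShape",
  representation(blobs = "data.frame", label = "character"),
  validity = function(object) {
    need <- c("dx", "dy", "dz", "amplitude", "sigma")
    if (!all(need %in% names(object@blobs)))
      return(paste("blobs needs columns:", paste(need, collapse = ", ")))
    if (nrow(object@blobs) < 1L) return("at least one blob required")
    if (any(object@blobs$sigma <= 0)) return("sigma must be > 0 for every blob")
    if (!all(is.finite(as.matrix(object@blobs[, c("dx", "dy", "dz")]))))
      return("blob offsets must be finite")
    TRUE
  }
)

#' @param blobs data.frame of blob offsets (ångström) and parameters.
#' @param label text label for the shape.
#' @rdname ProtomerShape-class
#' @export
ProtomerShape <- function(blobs, label = "protomer") {
  new("ProtomerShape", blobs = blobs, label = label)
}

#' Default asymmetric protomer fixture
#'
#' An "L" of Gaussian blobs extending along the tangential, radial and axial
#' directions with unequal arms and amplitudes, so that no rotation or
#' reflection of the protomer maps it onto itself.
#'
#' @param size linear scale factor applied to offsets and widths (1 gives a
#'   protomer roughly 12 ångström across, suited to rings with >= 14 ångström
#'   protomer spacing; use ~0.6 for crowded high-n rings).
#' @return A [ProtomerShape-class].
#' @export
defaultProtomer <- function(size = 1) {
  blobs <- data.frame(
    dx = size * c(0, 5.5, 0, 0, -3.0),
    dy = size * c(0, 0, 4.5, 0, 0),
    dz = size * c(0, 0, 0, 5.0, -4.0),
    amplitude = c(1.0, 0.8, 0.7, 0.9, 0.5),
    sigma = size * c(3.0, 2.5, 2.5, 2.5, 2.0)
  )
  ProtomerShape(blobs, label = "L-protomer")
}

## ---- lattice specs ----------------------------------------------------------

#' Geometric description of one protomer ring
#'
#' @slot nProtomers number of protomers (>= 1).
#' @slot radius ring radius in ångström (>= 0).
#' @slot zCenter axial position of the ring in ångström.
#' @slot phase azimuthal phase of protomer 0, radians in [0, 2*pi).
#' @slot tilt rotation of the protomer frame about the local tangent, radians.
#' @export
setClass("RingLatticeSpec",
  representation(nProtomers = "integer", radius = "numeric", zCenter = "numeric",
                 phase = "numeric", tilt = "numeric"),
  validity = function(object) {
    if (object@nProtomers < 1L) return("nProtomers must be >= 1")
    if (object@radius < 0) return("radius must be >= 0")
    if (object@phase < 0 || object@phase >= 2 * pi)
      return("phase must lie in [0, 2*pi)")
    TRUE
  }
)

#' @param nProtomers,radius,zCenter,phase,tilt see slot documentation.
#' @rdname RingLatticeSpec-class
#' @export
RingLatticeSpec <- function(nProtomers, radius, zCenter = 0, phase = 0, tilt = 0) {
  new("RingLatticeSpec", nProtomers = as.integer(nProtomers), radius = radius,
      zCenter = zCenter, phase = .wrap2pi(phase), tilt = tilt)
}

setMethod("show", "RingLatticeSpec", function(object) {
  cat(sprintf("RingLatticeSpec: C%d at r = %.1f Å, z = %.1f Å\n",
              object@nProtomers, object@radius, object@zCenter))
})

#' Stack of concentric protomer rings
#'
#' Houses the protomer arc width w and ring spacing of the circumference-ratio
#' stoichiometry model: when built from w, ring k carries
#' `round(2*pi*r_k / w)` protomers.
#'
#' @slot rings list of [RingLatticeSpec-class] with strictly increasing radii.
#' @slot arcWidth protomer arc width w in ångström (> 0).
#' @slot ringSpacing radial spacing between successive rings, ångström.
#' @export
setClass("DiskSpec",
  representation(rings = "list", arcWidth = "numeric", ringSpacing = "numeric"),
  validity = function(object) {
    if (length(object@rings) < 1L) return("at least one ring required")
    if (!all(vapply(object@rings, is, logical(1), "RingLatticeSpec")))
      return("rings must all be RingLatticeSpec")
    radii <- vapply(object@rings, function(r) r@radius, numeric(1))
    if (any(diff(radii) <= 0)) return("ring radii must be strictly increasing")
    if (object@arcWidth <= 0) return("arcWidth must be > 0")
    TRUE
  }
)

setMethod("show", "DiskSpec", function(object) {
  counts <- vapply(object@rings, function(r) r@nProtomers, integer(1))
  cat(sprintf("DiskSpec: %d concentric rings, counts %s (w = %.2f Å)\n",
              length(object@rings), paste(counts, collapse = ", "),
              object@arcWidth))
})

#' Featureless tube (lathed annulus) phantom component
#'
#' A cylindrical wall with Gaussian radial cross-section and a smoothly
#' tapered axial extent; azimuthally featureless by construction. Used for
#' the rod and for beta-collar-like test tubes.
#'
#' @slot radius wall-centre radius in ångström.
#' @slot wallSigma Gaussian wall half-width in ångström.
#' @slot zCenter,zHalfWidth axial centre and half-extent in ångström.
#' @slot amplitude peak density.
#' @slot label text label.
#' @export
setClass("TubeSpec",
  representation(radius = "numeric", wallSigma = "numeric", zCenter = "numeric",
                 zHalfWidth = "numeric", amplitude = "numeric", label = "character"),
  validity = function(object) {
    if (object@radius < 0) return("radius must be >= 0")
    if (object@wallSigma <= 0) return("wallSigma must be > 0")
    if (object@zHalfWidth <= 0) return("zHalfWidth must be > 0")
    TRUE
  }
)

#' @param radius,wallSigma,zCenter,zHalfWidth,amplitude,label see slots.
#' @rdname TubeSpec-class
#' @export
TubeSpec <- function(radius, wallSigma = 5, zCenter = 0, zHalfWidth = 30,
                     amplitude = 1, label = "tube") {
  new("TubeSpec", radius = radius, wallSigma = wallSigma, zCenter = zCenter,
      zHalfWidth = zHalfWidth, amplitude = amplitude, label = label)
}

#' Protomer ring phantom component
#'
#' @slot shape the [ProtomerShape-class] placed at each lattice point.
#' @slot ring the [RingLatticeSpec-class] describing the lattice.
#' @export
setClass("RingComponent",
  representation(shape = "ProtomerShape", ring = "RingLatticeSpec"))

#' @param shape,ring see slot documentation.
#' @rdname RingComponent-class
#' @export
RingComponent <- function(shape, ring) new("RingComponent", shape = shape, ring = ring)

#' Concentric-disk phantom component
#'
#' @slot shape the [ProtomerShape-class] placed at each lattice point.
#' @slot disk the [DiskSpec-class] describing the ring stack.
#' @export
setClass("DiskComponent",
  representation(shape = "ProtomerShape", disk = "DiskSpec"))

#' @param shape,disk see slot documentation.
#' @rdname DiskComponent-class
#' @export
DiskComponent <- function(shape, disk) new("DiskComponent", shape = shape, disk = disk)

setClassUnion("PhantomComponent", c("RingComponent", "DiskComponent", "TubeSpec"))

#' Specification of a multi-symmetry motor-like phantom volume
#'
#' Emulates a symmetry-mismatched flagellar motor: coaxial components of
#' distinct cyclic symmetries plus azimuthally featureless tubes, with
#' additive Gaussian noise and an optional missing wedge.
#'
#' @slot components list of [RingComponent-class], [DiskComponent-class] or
#'   [TubeSpec-class].
#' @slot boxSize box edge in voxels (even).
#' @slot voxelSize voxel size in ångström.
#' @slot noiseSd additive Gaussian noise sd in density units (ignored when
#'   `snr` is finite).
#' @slot snr if finite, noise sd is derived as (signal RMS over the component
#'   support) / snr; `NA` means use `noiseSd` directly.
#' @slot wedgeHalfAngle missing-wedge half-angle in degrees about the y tilt
#'   axis (`NA` = no wedge). 33 degrees corresponds to a +/-57 degree tilt
#'   range.
#' @slot seed RNG seed; the generated volume is a pure function of the spec.
#' @export
setClass("MotorPhantomSpec",
  representation(components = "list", boxSize = "integer", voxelSize = "numeric",
                 noiseSd = "numeric", snr = "numeric", wedgeHalfAngle = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@boxSize %% 2L != 0L) return("boxSize must be even")
    if (object@voxelSize <= 0) return("voxelSize must be > 0")
    if (is.finite(object@noiseSd) && object@noiseSd < 0)
      return("noiseSd must be >= 0")
    if (!all(vapply(object@components, is, logical(1), "PhantomComponent")))
      return("components must be RingComponent, DiskComponent or TubeSpec")
    TRUE
  }
)

#' @param components,boxSize,voxelSize,noiseSd,snr,wedgeHalfAngle,seed see
#'   slot documentation.
#' @rdname MotorPhantomSpec-class
#' @export
MotorPhantomSpec <- function(components, boxSize = 192L, voxelSize = 2,
                             noiseSd = 0, snr = NA_real_,
                             wedgeHalfAngle = NA_real_, seed = 20231009L) {
  new("MotorPhantomSpec", components = components, boxSize = as.integer(boxSize),
      voxelSize = voxelSize, noiseSd = noiseSd, snr = as.numeric(snr),
      wedgeHalfAngle = as.numeric(wedgeHalfAngle), seed = as.integer(seed))
}

setMethod("show", "MotorPhantomSpec", function(object) {
  cat(sprintf("MotorPhantomSpec: %d components, %d^3 voxels at %.3g Å\n",
              length(object@components), object@boxSize, object@voxelSize))
  if (is.finite(object@snr)) cat(sprintf("  noise: SNR %.3g (seed %d)\n",
                                         object@snr, object@seed))
  else cat(sprintf("  noise sd: %.3g (seed %d)\n", object@noiseSd, object@seed))
})

## ---- lattice transform & registration --------------------------------------

#' Linear oligomer lattice transform
#'
#' Rise is the lateral translation per protomer along the oligomer direction;
#' twist is the relative rotation between successive protomers about that
#' direction. Derived from the laterally associating protomer oligomers whose
#' arc is bent into closed rings.
#'
#' @slot rise lateral translation per protomer, ångström (> 0).
#' @slot twist relative rotation between successive protomers, radians.
#' @export
setClass("LatticeTransform",
  representation(rise = "numeric", twist = "numeric"),
  validity = function(object) {
    if (object@rise <= 0) return("rise must be > 0")
    TRUE
  }
)

#' @param rise,twist see slot documentation.
#' @rdname LatticeTransform-class
#' @export
LatticeTransform <- function(rise, twist = 0) {
  new("LatticeTransform", rise = rise, twist = twist)
}

#' Symmetry-mismatch registration result
#'
#' For a ring of `nRing` protomers registered against `nScaffold` scaffold
#' units: `period` is the number of ring protomers per repeating contact
#' (e.g. every third protomer), `contacts` the number of ring protomers
#' contacted per turn, and `offsetAngle` the angular mismatch of the nearest
#' contact. Pairs with gcd 1 are flagged incommensurate.
#'
#' @slot nRing,nScaffold the two cyclic orders.
#' @slot period ring protomers per contact repeat.
#' @slot contacts number of contacted ring protomers.
#' @slot offsetAngle radians.
#' @slot commensurate FALSE when gcd(nRing, nScaffold) = 1.
#' @export
setClass("RegistrationResult",
  representation(nRing = "integer", nScaffold = "integer", period = "integer",
                 contacts = "integer", offsetAngle = "numeric",
                 commensurate = "logical"))

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: C%d ring vs C%d scaffold\n",
              object@nRing, object@nScaffold))
  if (object@commensurate)
    cat(sprintf("  commensurate: one contact per %d ring protomers (%d contacts)\n",
                object@period, object@contacts))
  else
    cat("  incommensurate (gcd = 1): no repeating register\n")
})

## ---- bead assay types -------------------------------------------------------

#' Specification of a stepping-bead trajectory simulation
#'
#' The motor angle is a continuous-time jump process over `nDwells` equally
#' spaced dwell angles with exponential dwell times and unidirectional
#' (counter-clockwise) steps of `2*pi/nDwells`; switching is absent, matching
#' a switch-deleted strain. De-energization (CCCP) is modelled purely as a
#' dwell-rate multiplier: mean dwell time = `meanDwellTime / deenergization`.
#'
#' @slot nDwells number of dwell angles N (>= 2).
#' @slot meanDwellTime mean dwell time at full energization, seconds.
#' @slot linkageSd elastic-linkage angular noise sd, radians.
#' @slot localizationSd localization noise sd on x and y, length units.
#' @slot ellipse named numeric `(a, b, cx, cy, theta)`: semi-major/minor axes,
#'   centre, and orientation of the projected bead orbit.
#' @slot sampleRate camera sampling rate, Hz.
#' @slot duration trace duration, seconds.
#' @slot deenergization rate multiplier in (0, 1].
#' @slot phase azimuthal phase of dwell position 0, radians.
#' @slot seed RNG seed.
#' @export
setClass("BeadSimSpec",
  representation(nDwells = "integer", meanDwellTime = "numeric",
                 linkageSd = "numeric", localizationSd = "numeric",
                 ellipse = "numeric", sampleRate = "numeric",
                 duration = "numeric", deenergization = "numeric",
                 phase = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nDwells < 2L) return("nDwells must be >= 2")
    for (f in c("meanDwellTime", "sampleRate", "duration"))
      if (slot(object, f) <= 0) return(paste(f, "must be > 0"))
    if (object@linkageSd < 0 || object@localizationSd < 0)
      return("noise sds must be >= 0")
    if (object@deenergization <= 0 || object@deenergization > 1)
      return("deenergization must lie in (0, 1]")
    need <- c("a", "b", "cx", "cy", "theta")
    if (!all(need %in% names(object@ellipse)))
      return("ellipse needs named entries a, b, cx, cy, theta")
    if (object@ellipse[["a"]] <= 0 || object@ellipse[["b"]] <= 0)
      return("ellipse semi-axes must be > 0")
    if (object@ellipse[["a"]] < object@ellipse[["b"]])
      return("ellipse semi-major axis a must be >= b")
    TRUE
  }
)

#' @param nDwells,meanDwellTime,linkageSd,localizationSd,ellipse,sampleRate,duration,deenergization,phase,seed
#'   see slot documentation. Defaults simulate a 26-dwell motor observed for
#'   30 s at 250 Hz (about 57 revolutions at full energization).
#' @rdname BeadSimSpec-class
#' @export
BeadSimSpec <- function(nDwells = 26L, meanDwellTime = 0.02, linkageSd = 0.05,
                        localizationSd = 0.01,
                        ellipse = c(a = 0.25, b = 0.20, cx = 0.5, cy = -0.3,
                                    theta = 0.6),
                        sampleRate = 250, duration = 30, deenergization = 1,
                        phase = 0, seed = 20231009L) {
  new("BeadSimSpec", nDwells = as.integer(nDwells), meanDwellTime = meanDwellTime,
      linkageSd = linkageSd, localizationSd = localizationSd, ellipse = ellipse,
      sampleRate = sampleRate, duration = duration,
      deenergization = deenergization, phase = .wrap2pi(phase),
      seed = as.integer(seed))
}

setMethod("show", "BeadSimSpec", function(object) {
  revs <- object@duration * object@deenergization /
    (object@nDwells * object@meanDwellTime)
  cat(sprintf("BeadSimSpec: N = %d dwells, %.0f Hz x %.3g s (~%.0f revolutions)\n",
              object@nDwells, object@sampleRate, object@duration, revs))
})

#' Tethered-bead trajectory
#'
#' Time-stamped x,y positions of a bead attached to a rotating flagellar stub,
#' with a condition label (e.g. CCCP concentration). Simulated trajectories
#' additionally carry the ground truth used to generate them.
#'
#' @slot time strictly increasing, uniformly spaced timestamps, seconds.
#' @slot x,y bead positions, camera length units.
#' @slot condition free-text condition label.
#' @slot truth list of simulation ground truth (empty for real data).
#' @export
setClass("BeadTrajectory",
  representation(time = "numeric", x = "numeric", y = "numeric",
                 condition = "character", truth = "list"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@x) != n || length(object@y) != n)
      return("time, x, y must have equal length")
    if (n >= 2L) {
      dt <- diff(object@time)
      if (any(dt <= 0)) return("time must be strictly increasing")
      if (diff(range(dt)) > 1e-6 * stats::median(dt))
        return("samples must be uniformly spaced with no gaps")
    }
    TRUE
  }
)

#' @param time,x,y,condition,truth see slot documentation.
#' @rdname BeadTrajectory-class
#' @export
BeadTrajectory <- function(time, x, y, condition = "unlabelled", truth = list()) {
  new("BeadTrajectory", time = time, x = x, y = y, condition = condition,
      truth = truth)
}

setMethod("show", "BeadTrajectory", function(object) {
  cat(sprintf("BeadTrajectory: %d samples over %.3g s (%s)\n",
              length(object@time), diff(range(object@time)), object@condition))
})

#' @export
setMethod("as.data.frame", "BeadTrajectory", function(x, ...) {
  data.frame(time_s = x@time, x = x@x, y = x@y)
})

#' Unwrapped angular trace of a rotating bead
#'
#' @slot time timestamps, seconds.
#' @slot angle unwrapped angle, radians (monotone up to noise for a
#'   unidirectional motor).
#' @slot revolutions signed revolution count of the trace.
#' @export
setClass("AngularTrace",
  representation(time = "numeric", angle = "numeric", revolutions = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@angle))
      return("time and angle must have equal length")
    TRUE
  }
)

setMethod("show", "AngularTrace", function(object) {
  cat(sprintf("AngularTrace: %d samples, %.1f revolutions\n",
              length(object@time), object@revolutions))
})

#' @export
setMethod("as.data.frame", "AngularTrace", function(x, ...) {
  data.frame(time_s = x@time, angle = x@angle)
})

#' Circular probability density of dwell angle
#'
#' Von Mises kernel density over wrapped bead angles, occupancy-weighted and
#' normalized so that the density integrates to one over the circle.
#'
#' @slot theta regular angle grid over [0, 2*pi).
#' @slot density nonnegative density values.
#' @slot kappa von Mises kernel concentration used.
#' @export
setClass("DwellDensity",
  representation(theta = "numeric", density = "numeric", kappa = "numeric"),
  validity = function(object) {
    if (length(object@theta) != length(object@density))
      return("theta and density must have equal length")
    if (any(object@density < 0)) return("density must be nonnegative")
    dtheta <- 2 * pi / length(object@theta)
    tot <- sum(object@density) * dtheta
    if (abs(tot - 1) > 1e-6) return("density must integrate to 1 within 1e-6")
    TRUE
  }
)

setMethod("show", "DwellDensity", function(object) {
  cat(sprintf("DwellDensity: %d grid points, kappa = %.4g\n",
              length(object@theta), object@kappa))
})

#' @export
setMethod("as.data.frame", "DwellDensity", function(x, ...) {
  data.frame(theta = x@theta, density = x@density)
})

#' Dwell-count power spectrum
#'
#' Power of the occupancy-weighted angular density at integer harmonics,
#' combined across traces with weights proportional to revolution count.
#'
#' @slot harmonics integer harmonic orders m >= 1.
#' @slot power nonnegative combined power per harmonic.
#' @slot weights per-trace weights used (sum to 1).
#' @export
setClass("StepSpectrum",
  representation(harmonics = "integer", power = "numeric", weights = "numeric"),
  validity = function(object) {
    if (length(object@harmonics) != length(object@power))
      return("harmonics and power lengths differ")
    if (!all(is.finite(object@power)) || any(object@power < 0))
      return("power must be finite and nonnegative")
    if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-9)
      return("trace weights must sum to 1")
    TRUE
  }
)

setMethod("show", "StepSpectrum", function(object) {
  cat(sprintf("StepSpectrum: m = %d..%d from %d trace(s); strongest m = %d\n",
              min(object@harmonics), max(object@harmonics),
              length(object@weights),
              object@harmonics[which.max(object@power)]))
})

#' @export
setMethod("as.data.frame", "StepSpectrum", function(x, ...) {
  data.frame(harmonic = x@harmonics, power = x@power)
})
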