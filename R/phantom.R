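## Synthetic-data generators: concentric-disk specs, ring pseudo-atom models,
## Gaussian-blob rasterization, and multi-symmetry motor phantom volumes.

#' Build a concentric-disk specification from first-ring stoichiometry
#'
#' Implements the circumference-ratio model of the basal disk: the first ring
#' of `n1` protomers at radius `r1` fixes the protomer arc width
#' `w = 2*pi*r1/n1`; ring k (1-based) sits at radius `r1 + (k-1)*ringSpacing`
#' and carries `round(2*pi*r_k / w)` protomers (round half away from zero).
#' Choosing `ringSpacing = 11*w/(2*pi)` makes every ring gain exactly 11
#' protomers over its predecessor.
#'
#' @param n1 protomer count of the innermost ring (>= 1).
#' @param r1 innermost ring radius, ångström (> 0).
#' @param nRings number of concentric rings (>= 1).
#' @param ringSpacing radial spacing between rings, ångström (> 0).
#' @param zCenter axial position of the disk plane, ångström.
#' @return A [DiskSpec-class].
#' @export
buildDiskSpec <- function(n1, r1, nRings, ringSpacing, zCenter = 0) {
  if (!.isScalarNum(n1) || n1 < 1) stop("n1 must be a positive integer")
  if (!.isScalarNum(r1) || r1 <= 0) stop("r1 must be > 0")
  if (!.isScalarNum(nRings) || nRings < 1) stop("nRings must be >= 1")
  if (!.isScalarNum(ringSpacing) || ringSpacing <= 0)
    stop("ringSpacing must be > 0")
  w <- 2 * pi * r1 / n1
  radii <- r1 + (seq_len(nRings) - 1) * ringSpacing
  counts <- .roundHalfAway(2 * pi * radii / w)
  rings <- mapply(function(nk, rk) RingLatticeSpec(nk, rk, zCenter = zCenter),
                  counts, radii, SIMPLIFY = FALSE)
  new("DiskSpec", rings = rings, arcWidth = w, ringSpacing = ringSpacing)
}

#' Place a protomer shape on a ring lattice
#'
#' Protomer k (k = 0..n-1) is the protomer frame rigidly rotated to azimuth
#' `phase + 2*pi*k/n` and translated to the ring radius; local x maps to the
#' tangential direction, local y to the outward radial direction, local z to
#' the axis. A nonzero tilt rotates the protomer frame about the local
#' tangent before placement.
#'
#' @param shape a [ProtomerShape-class].
#' @param ring a [RingLatticeSpec-class].
#' @return A [PseudoAtomModel-class] with one chain label per protomer.
#' @export
makeRingModel <- function(shape, ring) {
  b <- shape@blobs
  ct <- cos(ring@tilt); st <- sin(ring@tilt)
  dy <- b$dy * ct - b$dz * st
  dz <- b$dy * st + b$dz * ct
  n <- ring@nProtomers
  k <- rep(seq_len(n) - 1L, each = nrow(b))
  phi <- ring@phase + 2 * pi * k / n
  dxr <- rep(b$dx, n); dyr <- rep(dy, n); dzr <- rep(dz, n)
  atoms <- data.frame(
    x = ring@radius * cos(phi) - dxr * sin(phi) + dyr * cos(phi),
    y = ring@radius * sin(phi) + dxr * cos(phi) + dyr * sin(phi),
    z = ring@zCenter + dzr,
    amplitude = rep(b$amplitude, n),
    sigma = rep(b$sigma, n),
    label = sprintf("p%d", k + 1L)
  )
  PseudoAtomModel(atoms)
}

#' Place a protomer shape on every ring of a concentric disk
#'
#' @param shape a [ProtomerShape-class].
#' @param disk a [DiskSpec-class].
#' @return A [PseudoAtomModel-class]; chain labels are `r<k>p<j>`.
#' @export
makeDiskModel <- function(shape, disk) {
  parts <- lapply(seq_along(disk@rings), function(i) {
    m <- makeRingModel(shape, disk@rings[[i]])@atoms
    m$label <- sprintf("r%d%s", i, m$label)
    m
  })
  PseudoAtomModel(do.call(rbind, parts))
}

## Core Gaussian splatting. policy = "warn" truncates out-of-box blobs with a
## warning (rasterize contract); "error" aborts naming the component.
.splatGaussians <- function(grid, atoms, voxelSize, policy = c("warn", "error"),
                            componentName = "model") {
  policy <- match.arg(policy)
  n <- dim(grid)[1]
  coords <- .axisCoords(n, voxelSize)
  lo <- coords[1]; hi <- coords[n]
  truncated <- 0L
  for (i in seq_len(nrow(atoms))) {
    cx <- atoms$x[i]; cy <- atoms$y[i]; cz <- atoms$z[i]
    s <- atoms$sigma[i]; A <- atoms$amplitude[i]
    if (any(c(cx, cy, cz) - 3 * s < lo) || any(c(cx, cy, cz) + 3 * s > hi)) {
      if (policy == "error")
        stop("component '", componentName,
             "' overlaps the box edge (blob ", i, " at r = ",
             sprintf("%.1f", sqrt(cx^2 + cy^2)), " Å, z = ",
             sprintf("%.1f", cz), " Å)")
      truncated <- truncated + 1L
    }
    ext <- 4 * s
    rng <- function(cc) {
      a <- max(1L, floor((cc - ext - lo) / voxelSize) + 1L)
      b <- min(n, ceiling((cc + ext - lo) / voxelSize) + 1L)
      if (a > b) integer(0) else a:b
    }
    ix <- rng(cx); iy <- rng(cy); iz <- rng(cz)
    if (!length(ix) || !length(iy) || !length(iz)) next  # fully outside

    gx <- exp(-(coords[ix] - cx)^2 / (2 * s^2))
    gy <- exp(-(coords[iy] - cy)^2 / (2 * s^2))
    gz <- exp(-(coords[iz] - cz)^2 / (2 * s^2))
    grid[ix, iy, iz] <- grid[ix, iy, iz] + A * outer(outer(gx, gy), gz)
  }
  attr(grid, "truncated") <- truncated
  grid
}

#' Rasterize a pseudo-atomic model onto a density grid
#'
#' Each blob contributes an isotropic Gaussian evaluated at voxel centres;
#' the density is the sum over blobs, so total integrated density equals
#' `sum(amplitude * (2*pi)^(3/2) * sigma^3) / voxelVolume` up to grid
#' quadrature error. Blobs extending past the box edge are truncated with a
#' warning reporting the count.
#'
#' @param model a [PseudoAtomModel-class].
#' @param boxSize box edge in voxels (even).
#' @param voxelSize voxel size, ångström.
#' @return A [DensityVolume-class].
#' @export
rasterize <- function(model, boxSize, voxelSize) {
  stopifnot(is(model, "PseudoAtomModel"), nrow(model@atoms) >= 1L)
  grid <- array(0, dim = rep(as.integer(boxSize), 3L))
  grid <- .splatGaussians(grid, model@atoms, voxelSize, policy = "warn")
  if (attr(grid, "truncated") > 0L)
    warning(attr(grid, "truncated"), " blob(s) truncated at the box edge")
  attr(grid, "truncated") <- NULL
  DensityVolume(grid, voxelSize)
}

## Analytic tube density on the grid: Gaussian radial wall, smoothly tapered
## axial envelope (half-Gaussian shoulders of width 2 voxels).
.tubeDensity <- function(n, voxelSize, tube) {
  coords <- .axisCoords(n, voxelSize)
  R <- sqrt(outer(coords^2, coords^2, "+"))
  wall <- tube@amplitude * exp(-(R - tube@radius)^2 / (2 * tube@wallSigma^2))
  over <- pmax(abs(coords - tube@zCenter) - tube@zHalfWidth, 0)
  env <- exp(-over^2 / (2 * (2 * voxelSize)^2))
  grid <- array(0, dim = rep(n, 3L))
  for (k in seq_len(n)) if (env[k] > 1e-12) grid[, , k] <- wall * env[k]
  grid
}

## Missing-wedge mask in Fourier space: tilt axis = y, so the unsampled double
## wedge lies within `halfAngleDeg` of the kz axis in the kx-kz plane.
.applyMissingWedge <- function(grid, halfAngleDeg) {
  n <- dim(grid)[1]
  k1 <- c(0:(n / 2), -(n / 2 - 1):-1)   # index-space frequencies
  tanw <- tan(halfAngleDeg * pi / 180)
  kx <- abs(k1)
  kz <- abs(k1)
  ## wedge: |kx| < |kz| * tan(halfAngle), independent of ky
  wedge2d <- outer(kx, kz, function(a, c) a < c * tanw)  # [kx, kz]
  F <- stats::fft(grid)
  for (k in seq_len(n)) {
    w <- wedge2d[, k]
    if (any(w)) F[w, , k] <- 0
  }
  Re(stats::fft(F, inverse = TRUE)) / length(grid)
}

#' Generate a multi-symmetry motor-like phantom volume
#'
#' Builds the deterministic noise-free density from the spec's components
#' (protomer rings, concentric disks, featureless tubes), then adds seeded
#' Gaussian noise and, if requested, zeroes the Fourier coefficients inside
#' the missing double wedge about the tilt axis before inverse transforming.
#' The result is a pure function of the spec, including its seed.
#'
#' When `spec@snr` is finite it is interpreted as the signal-to-noise power
#' ratio over the box: the noise sd is `sqrt(mean(signal^2) / snr)`.
#' Otherwise `spec@noiseSd` is used directly. Components overlapping the box
#' edge raise an error naming the offending component.
#'
#' @param spec a [MotorPhantomSpec-class].
#' @return A [DensityVolume-class].
#' @export
makeMotorPhantom <- function(spec) {
  stopifnot(is(spec, "MotorPhantomSpec"))
  n <- spec@boxSize
  v <- spec@voxelSize
  grid <- array(0, dim = rep(n, 3L))
  for (i in seq_along(spec@components)) {
    comp <- spec@components[[i]]
    if (is(comp, "TubeSpec")) {
      lim <- (n / 2 - 1) * v
      if (comp@radius + 3 * comp@wallSigma > lim)
        stop("component '", comp@label, "' overlaps the box edge")
      grid <- grid + .tubeDensity(n, v, comp)
    } else if (is(comp, "RingComponent")) {
      m <- makeRingModel(comp@shape, comp@ring)
      grid <- .splatGaussians(grid, m@atoms, v, policy = "error",
                              componentName = sprintf("C%d ring at r=%.0f",
                                                      comp@ring@nProtomers,
                                                      comp@ring@radius))
    } else {
      m <- makeDiskModel(comp@shape, comp@disk)
      grid <- .splatGaussians(grid, m@atoms, v, policy = "error",
                              componentName = "disk")
    }
    attr(grid, "truncated") <- NULL
  }
  sdNoise <- spec@noiseSd
  if (is.finite(spec@snr)) {
    ## SNR as a power ratio: mean squared signal over the box / noise variance
    sdNoise <- sqrt(mean(grid^2) / spec@snr)
  }
  if (sdNoise > 0)
    grid <- grid + withr::with_seed(spec@seed,
                                    array(stats::rnorm(n^3, sd = sdNoise),
                                          dim = rep(n, 3L)))
  if (is.finite(spec@wedgeHalfAngle))
    grid <- .applyMissingWedge(grid, spec@wedgeHalfAngle)
  DensityVolume(grid, v)
}

#' The standard motor phantom specification
#'
#' The bundled study conditions for all symmetry-detection work: a coaxial
#' composition mimicking the symmetry-mismatched motor, with a C17 protomer
#' ring at the periplasmic-scaffold radius, a C38 ring at the (wider, lower)
#' C-ring radius, a C26 ring at the LP-ring radius, and an azimuthally
#' featureless rod tube, plus seeded Gaussian noise.
#'
#' @param boxSize box edge in voxels (default 192).
#' @param voxelSize voxel size, ångström (default 2).
#' @param snr signal-to-noise ratio of the added Gaussian noise (default 0.5).
#' @param seed RNG seed (default 20231009).
#' @param wedgeHalfAngle optional missing-wedge half-angle, degrees.
#' @return A [MotorPhantomSpec-class].
#' @export
standardPhantomSpec <- function(boxSize = 192L, voxelSize = 2, snr = 0.5,
                                seed = 20231009L, wedgeHalfAngle = NA_real_) {
  p <- defaultProtomer()
  comps <- list(
    TubeSpec(radius = 25, wallSigma = 5, zCenter = 0, zHalfWidth = 80,
             amplitude = 0.6, label = "rod"),
    RingComponent(p, RingLatticeSpec(26L, radius = 60, zCenter = 50, phase = 0.30)),
    RingComponent(p, RingLatticeSpec(17L, radius = 110, zCenter = 0, phase = 0.10)),
    RingComponent(p, RingLatticeSpec(38L, radius = 140, zCenter = -60, phase = 0.50))
  )
  MotorPhantomSpec(comps, boxSize = boxSize, voxelSize = voxelSize,
                   noiseSd = 0, snr = snr, wedgeHalfAngle = wedgeHalfAngle,
                   seed = seed)
}

#' Annular analysis windows of the standard phantom
#'
#' @return Named list of `(rMin, rMax, zMin, zMax)` windows (ångström) for the
#'   scaffold, C-ring, LP-ring and rod regions of [standardPhantomSpec()].
#' @export
standardAnnuli <- function() {
  list(scaffold = c(rMin = 98, rMax = 124, zMin = -14, zMax = 14),
       cring    = c(rMin = 128, rMax = 154, zMin = -74, zMax = -46),
       lpring   = c(rMin = 50, rMax = 75, zMin = 36, zMax = 64),
       rod      = c(rMin = 10, rMax = 40, zMin = -40, zMax = 40))
}

#' Single protomer-ring phantom specification
#'
#' One Cn protomer ring in an otherwise empty box; the fixture used for
#' exhaustive symmetry-detector sweeps.
#'
#' @param n cyclic order of the ring.
#' @param radius ring radius, ångström.
#' @param boxSize,voxelSize grid geometry.
#' @param snr signal-to-noise ratio (`Inf` for noise-free).
#' @param seed RNG seed.
#' @param protomerSize scale passed to [defaultProtomer()]; smaller protomers
#'   keep high-n rings resolvable.
#' @return A [MotorPhantomSpec-class].
#' @export
singleRingPhantomSpec <- function(n, radius = 70, boxSize = 96L, voxelSize = 2,
                                  snr = Inf, seed = 20231009L,
                                  protomerSize = 0.6) {
  noiseSd <- 0
  snrSlot <- if (is.finite(snr)) snr else NA_real_
  RingComponentList <- list(
    RingComponent(defaultProtomer(protomerSize),
                  RingLatticeSpec(as.integer(n), radius = radius, zCenter = 0,
                                  phase = 0.1)))
  MotorPhantomSpec(RingComponentList, boxSize = boxSize, voxelSize = voxelSize,
                   noiseSd = noiseSd, snr = snrSlot, seed = seed)
}

#' Featureless tube phantom specification
#'
#' A single cylindrical wall at a stated radius, used for radial-profile
#' feature recovery (beta-collar-like fixtures).
#'
#' @param radius wall-centre radius, ångström.
#' @param wallSigma Gaussian wall half-width, ångström.
#' @param boxSize,voxelSize grid geometry.
#' @param snr signal-to-noise ratio (`Inf` for noise-free).
#' @param seed RNG seed.
#' @return A [MotorPhantomSpec-class].
#' @export
tubePhantomSpec <- function(radius, wallSigma = 4, boxSize = 192L,
                            voxelSize = 2, snr = 1, seed = 20231009L) {
  MotorPhantomSpec(list(TubeSpec(radius = radius, wallSigma = wallSigma,
                                 zCenter = 0, zHalfWidth = 30, amplitude = 1,
                                 label = "collar")),
                   boxSize = boxSize, voxelSize = voxelSize, noiseSd = 0,
                   snr = if (is.finite(snr)) snr else NA_real_, seed = seed)
}
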