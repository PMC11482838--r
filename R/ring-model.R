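## Closed-ring geometry: arc bending, circumference-ratio stoichiometry,
## symmetry-mismatch registration, and map-model fit scoring.

#' Bend a linear oligomer repeat onto a closed ring
#'
#' Protomer k (k = 0..n-1) is the input protomer rigidly rotated by
#' `2*pi*k/n` about the ring axis and placed at radius `r = n*rise/(2*pi)`,
#' so that the ring circumference equals n times the lateral rise of the
#' linear oligomer. Protomers stay rigid; all bending distortion is absorbed
#' by the interfaces. The nearest-neighbour centre distance is the chord
#' `2*r*sin(pi/n)`, which tends to the rise as n grows.
#'
#' The protomer model is expressed in the oligomer frame: x along the
#' oligomerisation (tangential) direction, y normal to it (radially outward
#' once bent), z axial. A nonzero lattice twist additionally rotates protomer
#' k by `k*twist` about its local tangent.
#'
#' @param protomer a [PseudoAtomModel-class] in the oligomer frame; its local
#'   origin becomes the protomer centre placed at radius r.
#' @param transform a [LatticeTransform-class].
#' @param n number of protomers in the closed ring (>= 3).
#' @param zCenter axial position of the ring plane, ångström.
#' @return A [PseudoAtomModel-class] with one chain per protomer and
#'   attribute `radius` (ångström).
#' @export
bendToArc <- function(protomer, transform, n, zCenter = 0) {
  stopifnot(is(protomer, "PseudoAtomModel"), is(transform, "LatticeTransform"))
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("n must be >= 3: no closed arc below a triangle")
  r <- n * transform@rise / (2 * pi)
  b <- protomer@atoms
  parts <- vector("list", n)
  for (k in seq_len(n) - 1L) {
    tau <- k * transform@twist
    dy <- b$y * cos(tau) - b$z * sin(tau)
    dz <- b$y * sin(tau) + b$z * cos(tau)
    phi <- 2 * pi * k / n
    parts[[k + 1L]] <- data.frame(
      x = r * cos(phi) - b$x * sin(phi) + dy * cos(phi),
      y = r * sin(phi) + b$x * cos(phi) + dy * sin(phi),
      z = zCenter + dz,
      amplitude = b$amplitude,
      sigma = b$sigma,
      label = sprintf("p%d", k + 1L)
    )
  }
  out <- PseudoAtomModel(do.call(rbind, parts))
  attr(out, "radius") <- r
  out
}

#' Predict concentric-ring protomer counts from circumference ratios
#'
#' The first ring of `n1` protomers at radius `r1` fixes the protomer arc
#' width `w = 2*pi*r1/n1`; each ring's count is its circumference divided by
#' w, rounded half away from zero. When the radial spacing satisfies
#' `2*pi*spacing/w = 11` each successive ring gains exactly 11 protomers.
#' Counts whose fractional part lies within `tieTol` of one half are flagged
#' `nearHalf` so rounding-model ties stay visible.
#'
#' @param n1 protomer count of the first ring.
#' @param r1 radius of the first ring, ångström.
#' @param radii increasing ring radii with `radii[1] == r1`.
#' @param tieTol near-half flag tolerance on the fractional count.
#' @return data.frame with columns `radius`, `count`, `increment` (`NA` for
#'   the first ring) and `nearHalf`.
#' @export
predictRingCounts <- function(n1, r1, radii, tieTol = 0.05) {
  if (!.isScalarNum(n1) || n1 < 1) stop("n1 must be a positive integer")
  if (!.isScalarNum(r1) || r1 <= 0) stop("r1 must be > 0")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (!isTRUE(all.equal(radii[1], r1)))
    stop("radii[1] must equal r1")
  w <- 2 * pi * r1 / n1
  exact <- 2 * pi * radii / w
  counts <- .roundHalfAway(exact)
  frac <- abs(exact - floor(exact) - 0.5)
  data.frame(radius = radii, count = as.integer(counts),
             increment = c(NA_integer_, as.integer(diff(counts))),
             nearHalf = frac < tieTol)
}

#' Ring stoichiometry from asymmetric units
#'
#' The protomer count of a ring assembled from `units` asymmetric units of
#' `protomersPerUnit` protomers each (e.g. 17 trimeric repeats give a
#' 51-protomer ring).
#'
#' @param units number of asymmetric units (>= 1).
#' @param protomersPerUnit protomers per unit (>= 1).
#' @return integer protomer count.
#' @export
ringFromAsymmetricUnit <- function(units, protomersPerUnit) {
  if (units < 1 || protomersPerUnit < 1)
    stop("units and protomersPerUnit must both be >= 1")
  as.integer(units) * as.integer(protomersPerUnit)
}

#' Register a protomer ring against a coaxial scaffold symmetry
#'
#' Pure symmetry-mismatch arithmetic: with `g = gcd(nRing, nScaffold)` a
#' commensurate pair repeats every `nRing/g` ring protomers and contacts `g`
#' of them per turn (a 51-protomer ring against a C17 scaffold puts a contact
#' on every third protomer, 17 contacts). Pairs with g = 1 share no
#' repeating register and are flagged incommensurate.
#'
#' @param nRing ring protomer count (>= 1).
#' @param nScaffold scaffold unit count (>= 1).
#' @param ringPhase,scaffoldPhase azimuthal phases of the two lattices,
#'   radians; they set the reported `offsetAngle` (the angular mismatch of
#'   the closest lattice-point pair).
#' @return A [RegistrationResult-class].
#' @export
registerSymmetry <- function(nRing, nScaffold, ringPhase = 0, scaffoldPhase = 0) {
  nRing <- as.integer(nRing); nScaffold <- as.integer(nScaffold)
  if (nRing < 1L || nScaffold < 1L) stop("both counts must be >= 1")
  g <- .gcd(nRing, nScaffold)
  step <- 2 * pi * g / (nRing * nScaffold)   # 2*pi / lcm
  d <- (scaffoldPhase - ringPhase) %% step
  offset <- min(d, step - d)
  new("RegistrationResult", nRing = nRing, nScaffold = nScaffold,
      period = as.integer(nRing / g), contacts = as.integer(g),
      offsetAngle = offset, commensurate = g > 1L)
}

#' Score a ring model against a target map
#'
#' Rasterizes the model on the target grid, applies a soft spherical mask
#' around the model to both maps, and reports the map-model FSC resolution at
#' the 0.5 threshold. Smaller is better; a wrong-count ring scores strictly
#' worse than the true count on matched phantoms.
#'
#' @param model a [PseudoAtomModel-class].
#' @param target a [DensityVolume-class].
#' @param threshold FSC threshold (default [FSC_MAPMODEL]).
#' @param soft mask rolloff width, ångström.
#' @return resolution in ångström (attribute `crossed` as in
#'   [resolutionAt()]).
#' @export
scoreRingFit <- function(model, target, threshold = FSC_MAPMODEL, soft = 12) {
  stopifnot(is(model, "PseudoAtomModel"), is(target, "DensityVolume"))
  raster <- suppressWarnings(rasterize(model, boxSize(target), voxelSize(target)))
  if (max(abs(raster@grid)) == 0)
    stop("model does not overlap the target box")
  at <- model@atoms
  wts <- abs(at$amplitude)
  ctr <- c(sum(at$x * wts), sum(at$y * wts), sum(at$z * wts)) / sum(wts)
  dmax <- max(sqrt((at$x - ctr[1])^2 + (at$y - ctr[2])^2 + (at$z - ctr[3])^2)
              + 3 * at$sigma)
  mask <- softSphericalMask(target, center = ctr,
                            radius = dmax + 2 * voxelSize(target), soft = soft)
  resolutionAt(fscCurve(applyMask(raster, mask), applyMask(target, mask)),
               threshold)
}

#' Export a ring pseudo-atom model as a PDB file
#'
#' Each Gaussian blob becomes a CA pseudo-atom; protomers map to chains
#' (chain identifiers recycle through A-Z, a-z, 0-9 for rings larger than 62
#' protomers, with the protomer index kept in the residue number).
#'
#' @param model a [PseudoAtomModel-class].
#' @param path output PDB path.
#' @return `path`, invisibly. Requires the bio3d package.
#' @export
exportRingPDB <- function(model, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("exportRingPDB requires the bio3d package")
  at <- model@atoms
  chains <- c(LETTERS, letters, as.character(0:9))
  labelIdx <- as.integer(factor(at$label, levels = unique(at$label)))
  nAt <- nrow(at)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = labelIdx,
    chain = chains[(labelIdx - 1L) %% length(chains) + 1L],
    resid = rep("GLY", nAt),
    elety = rep("CA", nAt),
    o = rep(1, nAt),
    b = at$sigma
  )
  invisible(path)
}
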