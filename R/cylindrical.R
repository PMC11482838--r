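## Cylindrical-coordinate operations about the box-centre z axis.

## Precompute bilinear interpolation stencil for a set of (x, y) points on an
## n x n slice; returns linear indices + weights, with a validity mask.
.bilinearStencil <- function(x, y, n, voxelSize) {
  fx <- x / voxelSize + n / 2 + 1
  fy <- y / voxelSize + n / 2 + 1
  valid <- fx >= 1 & fx <= n & fy >= 1 & fy <= n
  i0 <- pmin(pmax(floor(fx), 1), n - 1)
  j0 <- pmin(pmax(floor(fy), 1), n - 1)
  wx <- fx - i0
  wy <- fy - j0
  lin00 <- i0 + (j0 - 1) * n
  list(lin00 = lin00, lin10 = lin00 + 1, lin01 = lin00 + n,
       lin11 = lin00 + n + 1,
       w00 = (1 - wx) * (1 - wy), w10 = wx * (1 - wy),
       w01 = (1 - wx) * wy, w11 = wx * wy, valid = valid)
}

.applyStencilSlice <- function(slice, st, fill = NA_real_) {
  out <- st$w00 * slice[st$lin00] + st$w10 * slice[st$lin10] +
         st$w01 * slice[st$lin01] + st$w11 * slice[st$lin11]
  out[!st$valid] <- fill
  out
}

#' Resample a density volume onto a cylindrical grid
#'
#' Trilinear interpolation of the volume onto a regular (r, theta, z) grid
#' about the box-centre z axis. Because the z samples coincide with the voxel
#' planes, the interpolation reduces to bilinear interpolation within each
#' slice. Samples whose Cartesian pre-image falls outside the box are `NA`
#' (flagged absent, never zero-filled); with the default `rMax` every sample
#' is inside the box.
#'
#' @param v a [DensityVolume-class].
#' @param nTheta number of azimuthal samples, a power of two >= 256.
#' @param rMax largest sampled radius, ångström; default `(n/2 - 1) *
#'   voxelSize` keeps all samples inside the box.
#' @return A [CylindricalMap-class].
#' @export
resampleCylindrical <- function(v, nTheta = 256L, rMax = NULL) {
  stopifnot(is(v, "DensityVolume"))
  nTheta <- as.integer(nTheta)
  if (!.isPow2(nTheta) || nTheta < 256L)
    stop("nTheta must be a power of two >= 256")
  n <- boxSize(v)
  vox <- voxelSize(v)
  if (is.null(rMax)) rMax <- (n / 2 - 1) * vox
  r <- seq(0, rMax, by = vox)
  theta <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
  x <- outer(r, cos(theta))
  y <- outer(r, sin(theta))
  st <- .bilinearStencil(x, y, n, vox)
  vals <- array(NA_real_, dim = c(length(r), nTheta, n))
  for (k in seq_len(n))
    vals[, , k] <- .applyStencilSlice(v@grid[, , k], st)
  new("CylindricalMap", values = vals, r = r, theta = theta,
      z = .axisCoords(n, vox), voxelSize = vox)
}

#' Rotate a volume about the symmetry axis
#'
#' Bilinear in-plane interpolation at the back-rotated coordinates, slice by
#' slice. Samples rotated in from outside the box are filled with `fill`.
#'
#' @param v a [DensityVolume-class].
#' @param angle rotation angle, radians, counter-clockwise viewed from +z.
#' @param fill value for samples from outside the box (default 0).
#' @return A [DensityVolume-class].
#' @export
rotateVolume <- function(v, angle, fill = 0) {
  stopifnot(is(v, "DensityVolume"))
  n <- boxSize(v)
  vox <- voxelSize(v)
  coords <- .axisCoords(n, vox)
  X <- matrix(coords, n, n)
  Y <- matrix(coords, n, n, byrow = TRUE)
  ## output voxel (X, Y) samples the input at R(-angle) (X, Y)
  ca <- cos(angle); sa <- sin(angle)
  st <- .bilinearStencil(ca * X + sa * Y, -sa * X + ca * Y, n, vox)
  out <- array(0, dim = dim(v@grid))
  for (k in seq_len(n))
    out[, , k] <- .applyStencilSlice(v@grid[, , k], st, fill = fill)
  DensityVolume(out, vox, origin = v@origin)
}

#' Impose cyclic symmetry on a volume
#'
#' Cn symmetrization: the average of the n copies of the volume rotated by
#' multiples of `2*pi/n` about the box-centre z axis. The output is invariant
#' under a `2*pi/n` rotation up to interpolation error; `n = 1` returns the
#' input unchanged.
#'
#' @param v a [DensityVolume-class].
#' @param n cyclic order (>= 1).
#' @return A [DensityVolume-class].
#' @export
symmetrizeVolume <- function(v, n) {
  stopifnot(is(v, "DensityVolume"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("symmetry order n must be >= 1")
  if (n == 1L) return(v)
  acc <- v@grid
  for (k in seq_len(n - 1L))
    acc <- acc + rotateVolume(v, 2 * pi * k / n)@grid
  DensityVolume(acc / n, voxelSize(v), origin = v@origin)
}

## Radial hat-basis stencil shared by the azimuthal average (scatter) and its
## Cartesian back-interpolation (gather). Every voxel contributes at its
## exact radius, so the azimuthal mean itself has no interpolation error.
.radialStencil <- function(n, voxelSize) {
  coords <- .axisCoords(n, voxelSize)
  rr <- sqrt(outer(coords^2, coords^2, "+"))
  nR <- floor(max(rr) / voxelSize) + 2L
  idx <- pmin(floor(rr / voxelSize) + 1L, nR - 1L)
  wr <- rr / voxelSize - (idx - 1L)
  grp <- c(idx, idx + 1L)
  den <- as.vector(rowsum(c(1 - wr, wr), grp))
  bins <- sort(unique(grp))
  denFull <- numeric(nR)
  denFull[bins] <- den
  list(nR = nR, r = (seq_len(nR) - 1) * voxelSize, idx = idx, wr = wr,
       grp = grp, den = denFull, bins = bins)
}

## per-slice radial profile: hat-weighted average over all voxels of a slice
.sliceProfile <- function(slice, st) {
  num <- numeric(st$nR)
  num[st$bins] <- rowsum(c((1 - st$wr) * slice, st$wr * slice), st$grp)
  ifelse(st$den > 0, num / st$den, 0)
}

#' Lathe a volume (cylindrical averaging)
#'
#' Replaces the volume by its azimuthal average mapped back to Cartesian
#' coordinates, producing a map with axial and radial features but no
#' azimuthal features — the C-infinity limit of Cn symmetrization. The
#' azimuthal mean is taken over every voxel at its exact radius (hat-basis
#' radial binning at the voxel pitch), then interpolated back with the same
#' basis, so the operation is idempotent up to the radial hat-basis
#' smoothing.
#'
#' @param v a [DensityVolume-class].
#' @return A [DensityVolume-class], azimuthally invariant up to interpolation
#'   error.
#' @export
latheVolume <- function(v) {
  stopifnot(is(v, "DensityVolume"))
  n <- boxSize(v)
  vox <- voxelSize(v)
  st <- .radialStencil(n, vox)
  out <- array(0, dim = dim(v@grid))
  for (k in seq_len(n)) {
    pk <- .sliceProfile(as.vector(v@grid[, , k]), st)
    out[, , k] <- pk[st$idx] * (1 - st$wr) + pk[st$idx + 1L] * st$wr
  }
  DensityVolume(out, vox, origin = v@origin)
}
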