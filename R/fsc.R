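## Fourier shell correlation and threshold-crossing resolution.

#' Conventional FSC thresholds
#'
#' `FSC_MAPMODEL` (0.5) is the map-model convention; `FSC_HALFMAP` (0.143)
#' the independent-half-map convention.
#'
#' @name fsc-thresholds
#' @export
FSC_MAPMODEL <- 0.5

#' @rdname fsc-thresholds
#' @export
FSC_HALFMAP <- 0.143

## shell index (0..n/2) per Fourier voxel, in index units
.shellIndex <- function(n) {
  k1 <- c(0:(n / 2), -(n / 2 - 1):-1)
  k2 <- k1^2
  round(sqrt(outer(outer(k2, k2, "+"), k2, "+")))
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of the Fourier coefficients:
#' `FSC(s) = Re(sum F_a conj(F_b)) / sqrt(sum |F_a|^2 sum |F_b|^2)` over
#' shells one Fourier voxel wide, exhaustive to Nyquist. Symmetric in its
#' arguments and invariant to a global scale of either input.
#'
#' @param a,b [DensityVolume-class] objects on the same grid with the same
#'   voxel size.
#' @return An [FSCCurve-class].
#' @export
fscCurve <- function(a, b) {
  stopifnot(is(a, "DensityVolume"), is(b, "DensityVolume"))
  if (!identical(dim(a@grid), dim(b@grid)) ||
      !isTRUE(all.equal(voxelSize(a), voxelSize(b))))
    stop("volumes must share the same grid and voxel size")
  n <- boxSize(a)
  Fa <- stats::fft(a@grid)
  Fb <- stats::fft(b@grid)
  shell <- as.vector(.shellIndex(n))
  keep <- shell <= n / 2
  grp <- shell[keep] + 1L
  cross <- Re(Fa * Conj(Fb))[keep]
  pa <- (Mod(Fa)^2)[keep]
  pb <- (Mod(Fb)^2)[keep]
  sums <- rowsum(cbind(cross, pa, pb), grp)
  den <- sqrt(sums[, 2] * sums[, 3])
  corr <- ifelse(den > 0, sums[, 1] / den, NA_real_)
  corr <- pmin(pmax(corr, -1), 1)
  shellWidth <- 1 / (n * voxelSize(a))
  new("FSCCurve", frequency = (seq_len(nrow(sums)) - 1) * shellWidth,
      correlation = as.numeric(corr), shellWidth = shellWidth,
      voxelSize = voxelSize(a))
}

#' Resolution at an FSC threshold crossing
#'
#' Returns `1/frequency` at the first downward crossing of the threshold,
#' with linear interpolation between shells. A curve that never drops below
#' the threshold is reported at the Nyquist resolution `2*voxelSize` with
#' attribute `crossed = FALSE` ("beyond Nyquist").
#'
#' @param curve an [FSCCurve-class].
#' @param threshold FSC threshold, e.g. [FSC_MAPMODEL] or [FSC_HALFMAP].
#' @return resolution in ångström (numeric scalar; attribute `crossed`).
#' @export
resolutionAt <- function(curve, threshold = FSC_MAPMODEL) {
  stopifnot(is(curve, "FSCCurve"))
  f <- curve@frequency
  c0 <- curve@correlation
  ok <- is.finite(c0)
  f <- f[ok]; c0 <- c0[ok]
  for (i in seq.int(2L, length(c0))) {
    if (c0[i] < threshold && c0[i - 1] >= threshold) {
      fc <- f[i - 1] + (c0[i - 1] - threshold) / (c0[i - 1] - c0[i]) *
        (f[i] - f[i - 1])
      res <- 1 / fc
      attr(res, "crossed") <- TRUE
      return(res)
    }
  }
  res <- 2 * curve@voxelSize
  attr(res, "crossed") <- FALSE
  res
}

#' Soft spherical mask
#'
#' Value 1 inside `radius`, raised-cosine rolloff to 0 over `soft` ångström.
#' Used to isolate a model region before map-model FSC scoring.
#'
#' @param v a [DensityVolume-class] supplying the grid geometry.
#' @param center mask centre, ångström (centred frame).
#' @param radius hard radius, ångström.
#' @param soft rolloff width, ångström.
#' @return A [DensityVolume-class] holding the mask.
#' @export
softSphericalMask <- function(v, center = c(0, 0, 0), radius, soft = 12) {
  stopifnot(is(v, "DensityVolume"))
  n <- boxSize(v)
  coords <- .axisCoords(n, voxelSize(v))
  dx2 <- (coords - center[1])^2
  dy2 <- (coords - center[2])^2
  dz2 <- (coords - center[3])^2
  d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  m <- 0.5 * (1 + cos(pi * (d - radius) / soft))
  m[d <= radius] <- 1
  m[d >= radius + soft] <- 0
  DensityVolume(m, voxelSize(v), origin = v@origin)
}

#' Multiply a volume by a mask
#'
#' @param v,mask [DensityVolume-class] objects on the same grid.
#' @return A [DensityVolume-class].
#' @export
applyMask <- function(v, mask) {
  stopifnot(identical(dim(v@grid), dim(mask@grid)))
  DensityVolume(v@grid * mask@grid, voxelSize(v), origin = v@origin)
}
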