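## Radial density profiles and sub-voxel feature-radius estimation.

#' Radial density profile of a volume
#'
#' Mean density versus radius over a z slab, computed on the lathed
#' (azimuthally averaged) representation: every voxel of the slab contributes
#' at its exact radius through hat-basis radial binning at the voxel pitch.
#'
#' @param v a [DensityVolume-class].
#' @param zRange numeric `(zMin, zMax)` slab in ångström, within the box.
#' @return data.frame with columns `r` (ångström) and `density`.
#' @export
radialProfile <- function(v, zRange = NULL) {
  stopifnot(is(v, "DensityVolume"))
  n <- boxSize(v)
  vox <- voxelSize(v)
  zAll <- .axisCoords(n, vox)
  if (is.null(zRange)) zRange <- range(zAll)
  zIdx <- which(zAll >= zRange[1] & zAll <= zRange[2])
  if (!length(zIdx)) stop("empty z range")
  st <- .radialStencil(n, vox)
  slab <- rowSums(matrix(v@grid[, , zIdx], ncol = length(zIdx))) /
    length(zIdx)
  data.frame(r = st$r, density = .sliceProfile(slab, st))
}

#' Estimate a feature radius with sub-voxel refinement
#'
#' Finds the highest local maximum of the profile inside the search window
#' and refines its location with a 3-point parabola. A window containing no
#' local maximum returns a "not found" result instead of an error.
#'
#' @param profile data.frame with columns `r` and `density` (as returned by
#'   [radialProfile()]).
#' @param searchWindow numeric `(rMin, rMax)` in ångström; defaults to the
#'   full profile support.
#' @return list with `radius` (ångström, `NA` if not found), `value` (peak
#'   density) and `found` (logical).
#' @export
estimateFeatureRadius <- function(profile, searchWindow = NULL) {
  r <- profile$r
  d <- profile$density
  if (is.null(searchWindow)) searchWindow <- range(r)
  if (searchWindow[1] < min(r) || searchWindow[2] > max(r))
    stop("search window must lie inside the profile support")
  nR <- length(r)
  interior <- 2:(nR - 1)
  isMax <- d[interior] > d[interior - 1] & d[interior] >= d[interior + 1]
  cand <- interior[isMax]
  cand <- cand[r[cand] >= searchWindow[1] & r[cand] <= searchWindow[2]]
  if (!length(cand))
    return(list(radius = NA_real_, value = NA_real_, found = FALSE))
  i <- cand[which.max(d[cand])]
  denom <- d[i - 1] - 2 * d[i] + d[i + 1]
  delta <- if (denom < 0) 0.5 * (d[i - 1] - d[i + 1]) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  dr <- r[2] - r[1]
  list(radius = r[i] + delta * dr, value = d[i], found = TRUE)
}
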