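## Azimuthal symmetry spectra and cyclic-order detection.

.annulusVec <- function(annulus) {
  a <- as.numeric(annulus)
  if (length(a) != 4L) stop("annulus must be (rMin, rMax, zMin, zMax)")
  names(a) <- c("rMin", "rMax", "zMin", "zMax")
  a
}

#' Azimuthal power spectrum of an annular region
#'
#' For each (r, z) sample in the annulus the discrete Fourier transform over
#' theta is taken; the spectrum is `power[m] = sum_{r,z} |F_m|^2 * r`, each
#' azimuthal ring weighted by its radius (area weighting). Power over
#' harmonics m >= 1 is normalized to sum to one whenever any is nonzero; the
#' m = 0 term is retained unnormalized and excluded from peak searches.
#'
#' @param cmap a [CylindricalMap-class].
#' @param annulus numeric `(rMin, rMax, zMin, zMax)` in ångström; must lie
#'   within the sampled region.
#' @return A [SymmetrySpectrum-class] with harmonics 0..nTheta/2.
#' @export
azimuthalPowerSpectrum <- function(cmap, annulus) {
  stopifnot(is(cmap, "CylindricalMap"))
  a <- .annulusVec(annulus)
  rIdx <- which(cmap@r >= a[1] & cmap@r <= a[2])
  zIdx <- which(cmap@z >= a[3] & cmap@z <= a[4])
  if (!length(rIdx) || !length(zIdx)) stop("empty annulus")
  vals <- cmap@values[rIdx, , zIdx, drop = FALSE]
  if (anyNA(vals)) stop("annulus extends beyond the sampled region")
  nTheta <- length(cmap@theta)
  m <- aperm(vals, c(2, 1, 3))
  dim(m) <- c(nTheta, length(rIdx) * length(zIdx))
  F <- stats::mvfft(m)
  w <- rep(cmap@r[rIdx], times = length(zIdx))
  P <- as.vector(Mod(F)^2 %*% w)
  half <- nTheta / 2
  power <- P[seq_len(half + 1)]
  s <- sum(power[-1])
  if (s > 0) power[-1] <- power[-1] / s
  new("SymmetrySpectrum", harmonics = 0:half, power = power,
      annulus = a, totalPower = s)
}

#' Detect the cyclic symmetry order from an azimuthal spectrum
#'
#' The detected order is the argmax of power over harmonics in
#' `[mMin, mMax]`, with ties broken toward the smallest order. The confidence
#' is the ratio of the top power to the median power over the search window,
#' so callers can reject flat spectra; an all-zero window yields a
#' "no symmetry detectable" result rather than an error.
#'
#' The default window 10..50 brackets every cyclic order relevant to
#' flagellar motor components (17, 26, 38, 51) while excluding low-order
#' shape and missing-wedge artifacts.
#'
#' @param spectrum a [SymmetrySpectrum-class].
#' @param mMin,mMax search window (mMin >= 2, mMax <= nTheta/2).
#' @param confidenceThreshold minimum top/median power ratio for a call.
#' @return A list with elements `n` (integer, `NA` if no call), `confidence`,
#'   `called` (logical), and the window used.
#' @export
detectSymmetry <- function(spectrum, mMin = 10L, mMax = 50L,
                           confidenceThreshold = 1.5) {
  stopifnot(is(spectrum, "SymmetrySpectrum"))
  mMin <- as.integer(mMin); mMax <- as.integer(mMax)
  if (mMin < 2L) stop("mMin must be >= 2")
  if (mMax > max(spectrum@harmonics))
    stop("mMax exceeds the sampled harmonic range")
  if (mMax < mMin) stop("mMax must be >= mMin")
  sel <- spectrum@harmonics >= mMin & spectrum@harmonics <= mMax
  p <- spectrum@power[sel]
  m <- spectrum@harmonics[sel]
  if (all(p == 0))
    return(list(n = NA_integer_, confidence = 0, called = FALSE,
                mMin = mMin, mMax = mMax))
  i <- which.max(p)            # first maximum = smallest order on ties
  med <- stats::median(p)
  confidence <- if (med > 0) p[i] / med else Inf
  called <- confidence >= confidenceThreshold
  list(n = if (called) m[i] else NA_integer_, confidence = confidence,
       called = called, peak = m[i], mMin = mMin, mMax = mMax)
}
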