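## Fourier low-pass filtering.

## squared spatial frequency (1/Å)^2 on the FFT grid, as a 3-D array
.freqSq3d <- function(n, voxelSize) {
  f1 <- c(0:(n / 2), -(n / 2 - 1):-1) / (n * voxelSize)
  f2 <- f1^2
  outer(outer(f2, f2, "+"), f2, "+")
}

#' Low-pass filter a volume to a target resolution
#'
#' Applies a raised-cosine rolloff of one Fourier-shell width centred at
#' `1/resolution`. The zero-frequency term is always passed, so the mean
#' density is preserved.
#'
#' @param v a [DensityVolume-class].
#' @param resolution target resolution in ångström; must exceed the Nyquist
#'   resolution `2*voxelSize`.
#' @return A [DensityVolume-class].
#' @export
lowpassVolume <- function(v, resolution) {
  stopifnot(is(v, "DensityVolume"))
  vox <- voxelSize(v)
  if (!.isScalarNum(resolution) || resolution <= 2 * vox)
    stop("resolution must exceed the Nyquist limit 2*voxelSize = ",
         2 * vox, " Å")
  n <- boxSize(v)
  fc <- 1 / resolution
  w <- 1 / (n * vox)                       # one shell width
  fr <- sqrt(.freqSq3d(n, vox))
  H <- 0.5 * (1 + cos(pi * (fr - (fc - w / 2)) / w))
  H[fr <= fc - w / 2] <- 1
  H[fr >= fc + w / 2] <- 0
  F <- stats::fft(v@grid) * H
  DensityVolume(Re(stats::fft(F, inverse = TRUE)) / n^3, vox,
                origin = v@origin)
}
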