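## Minimal MRC2014 / CCP4 map I/O, mode 2 (32-bit float) only.
## Little-endian, no extended header, cell = box, axis order x,y,z.

#' Write a density volume as an MRC/CCP4 mode-2 map
#'
#' Writes the MRC2014 subset this package uses: 32-bit float data, voxel size
#' in the cell parameters, map origin (box corner, ångström) in the ORIGIN
#' header words, axes in x,y,z order, no extended header.
#'
#' @param v a [DensityVolume-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(v, path) {
  stopifnot(is(v, "DensityVolume"))
  g <- densityGrid(v)
  n <- dim(g)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wInt(n)                        # NX NY NZ
  wInt(2L)                       # MODE 2: float32
  wInt(c(0L, 0L, 0L))            # NXSTART..
  wInt(n)                        # MX MY MZ
  wFlt(n * voxelSize(v))         # CELLA
  wFlt(c(90, 90, 90))            # CELLB
  wInt(c(1L, 2L, 3L))            # MAPC MAPR MAPS
  wFlt(c(min(g), max(g), mean(g)))  # DMIN DMAX DMEAN
  wInt(c(1L, 0L))                # ISPG, NSYMBT
  wInt(rep(0L, 25L))             # EXTRA (incl. EXTTYP/NVERSION left 0)
  wFlt(v@origin)                 # ORIGIN x y z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wFlt(stats::sd(as.vector(g)))  # RMS
  wInt(1L)                       # NLABL
  lab <- sprintf("ringstoich %s", as.character(utils::packageVersion("ringstoich")))
  lab <- substr(paste0(lab, strrep(" ", 80)), 1, 80)
  writeBin(charToRaw(paste0(lab, strrep(" ", 720))), con)
  writeBin(as.numeric(g), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC/CCP4 mode-2 map as a density volume
#'
#' @param path path to a little-endian mode-2 MRC file with x,y,z axis order.
#' @return A [DensityVolume-class]; the voxel size is taken from the cell
#'   parameters and the origin from the ORIGIN header words.
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(k) readBin(con, "integer", n = k, size = 4L, endian = "little")
  rFlt <- function(k) readBin(con, "numeric", n = k, size = 4L, endian = "little")
  n <- rInt(3L)
  mode <- rInt(1L)
  if (mode != 2L) stop("only MRC mode 2 (float32) is supported, got mode ", mode)
  rInt(3L)                       # NXSTART
  mxyz <- rInt(3L)
  cella <- rFlt(3L)
  rFlt(3L)                       # CELLB
  mapcrs <- rInt(3L)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("only x,y,z axis order (MAPC,MAPR,MAPS = 1,2,3) is supported")
  rFlt(3L)                       # DMIN DMAX DMEAN
  rInt(1L)                       # ISPG
  nsymbt <- rInt(1L)
  rInt(25L)                      # EXTRA
  origin <- rFlt(3L)
  readBin(con, "raw", n = 4L)    # MAP
  readBin(con, "raw", n = 4L)    # MACHST
  rFlt(1L)                       # RMS
  rInt(1L)                       # NLABL
  readBin(con, "raw", n = 800L)  # labels
  if (nsymbt > 0L) readBin(con, "raw", n = nsymbt)
  vox <- cella[1] / mxyz[1]
  dat <- readBin(con, "numeric", n = prod(n), size = 4L, endian = "little")
  DensityVolume(array(dat, dim = n), voxelSize = vox, origin = origin)
}
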