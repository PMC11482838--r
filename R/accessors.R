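#' Accessors for ringstoich containers
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x a ringstoich S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("densityGrid", function(x) standardGeneric("densityGrid"))

#' @rdname accessors
#' @export
setMethod("densityGrid", "DensityVolume", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setMethod("voxelSize", "DensityVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "CylindricalMap", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("boxSize", function(x) standardGeneric("boxSize"))

#' @rdname accessors
#' @export
setMethod("boxSize", "DensityVolume", function(x) dim(x@grid)[1])

#' @rdname accessors
#' @export
setGeneric("harmonics", function(x) standardGeneric("harmonics"))

#' @rdname accessors
#' @export
setMethod("harmonics", "SymmetrySpectrum", function(x) x@harmonics)

#' @rdname accessors
#' @export
setMethod("harmonics", "StepSpectrum", function(x) x@harmonics)

#' @rdname accessors
#' @export
setGeneric("harmonicPower", function(x) standardGeneric("harmonicPower"))

#' @rdname accessors
#' @export
setMethod("harmonicPower", "SymmetrySpectrum", function(x) x@power)

#' @rdname accessors
#' @export
setMethod("harmonicPower", "StepSpectrum", function(x) x@power)

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setMethod("atoms", "PseudoAtomModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("revolutions", function(x) standardGeneric("revolutions"))

#' @rdname accessors
#' @export
setMethod("revolutions", "AngularTrace", function(x) x@revolutions)

#' Physical voxel-centre coordinates of a volume axis
#'
#' Coordinates in the centred frame: the assumed symmetry axis passes through
#' coordinate 0 on x and y (grid index `n/2 + 1`).
#'
#' @param v a [DensityVolume-class].
#' @return numeric vector of length `boxSize(v)`, in ångström.
#' @export
axisCoords <- function(v) .axisCoords(boxSize(v), voxelSize(v))
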