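#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Accessors for the core S4 containers: `voxels()` returns the raw 0/1 voxel
#' array of a [BinaryVolume-class], `voxelSize()` its physical voxel edge
#' length in micrometres, and `dims()` the grid dimensions.
#'
#' @param x an object.
#' @return `voxels()`: a 3D integer array; `voxelSize()`: numeric scalar (um);
#'   `dims()`: integer vector of length 3.
#' @name accessors
#' @aliases voxels voxelSize dims
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("dims", function(x) standardGeneric("dims"))

#' Porosity (void volume fraction) of a binary volume
#'
#' Computes the porosity n = V_V / V_TOT of a binary pore/solid volume as the
#' exact ratio of pore voxels (value 1) to total voxels. No estimation is
#' involved: the result is a deterministic voxel count.
#'
#' @param x a [BinaryVolume-class].
#' @return a [PorosityResult-class] with slots `n`, `poreVoxels`,
#'   `totalVoxels`.
#' @examples
#' v <- bernoulliVolume(c(16, 16, 16), p = 0.7, seed = 1)
#' porosity(v)
#' @export
setGeneric("porosity", function(x) standardGeneric("porosity"))
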