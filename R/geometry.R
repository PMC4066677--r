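#' @include AllClasses.R utils.R
NULL

#' Assemble binary slices into a 3D volume
#'
#' Stacks binary 2D slices in acquisition order as constant-k planes of a
#' [BinaryVolume-class]. Voxel count is conserved: the sum over slices equals
#' the pore-voxel count of the volume.
#'
#' @param slices nonempty list of 0/1 matrices, all of identical dimensions.
#' @param voxelSize voxel edge length in micrometres.
#' @return a [BinaryVolume-class] with dims `(nrow, ncol, length(slices))`.
#' @export
stackToVolume <- function(slices, voxelSize = 1) {
  if (length(slices) < 1L) stop("at least one slice is required")
  d0 <- dim(slices[[1]])
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]), d0))
      stop("slice ", i, " has dimensions ",
           paste(dim(slices[[i]]), collapse = "x"), ", expected ",
           paste(d0, collapse = "x"))
  }
  vox <- array(0L, dim = c(d0, length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- as.integer(slices[[i]])
  BinaryVolume(vox, voxelSize)
}

#' Slice a volume along the stacking axis
#'
#' Inverse of [stackToVolume()]: returns the constant-k planes as a list of
#' 0/1 matrices.
#'
#' @param volume a [BinaryVolume-class].
#' @return list of 2D integer matrices.
#' @export
sliceVolume <- function(volume) {
  vox <- voxels(volume)
  lapply(seq_len(dim(vox)[3]), function(k) vox[, , k])
}

#' Extract a rectangular region of interest
#'
#' Copies the sub-block starting at 1-based `origin` with the given `size`;
#' voxel size and provenance are preserved.
#'
#' @param volume a [BinaryVolume-class].
#' @param origin integer triple of 1-based start indices.
#' @param size integer triple of extents; `origin + size - 1` must fit.
#' @return a [BinaryVolume-class] of dimensions `size`.
#' @export
extractROI <- function(volume, origin, size) {
  origin <- as.integer(origin); size <- as.integer(size)
  d <- dims(volume)
  bad <- which(origin < 1L | size < 1L | origin + size - 1L > d)
  if (length(bad))
    stop("ROI out of bounds along axis ",
         paste(c("x", "y", "z")[bad], collapse = ", "))
  vox <- voxels(volume)[origin[1]:(origin[1] + size[1] - 1L),
                        origin[2]:(origin[2] + size[2] - 1L),
                        origin[3]:(origin[3] + size[3] - 1L), drop = FALSE]
  BinaryVolume(vox, voxelSize(volume),
               provenance = c(volume@provenance,
                              list(roiOrigin = origin, roiSize = size)))
}

#' @rdname porosity
#' @export
setMethod("porosity", "BinaryVolume", function(x) {
  vox <- voxels(x)
  pv <- sum(as.numeric(vox))
  tv <- prod(as.numeric(dim(vox)))
  new("PorosityResult", n = pv / tv, poreVoxels = pv, totalVoxels = tv)
})

#' Extract parallel subvolume slabs
#'
#' Cuts the slabs described by a [SubvolumeSpec-class] perpendicular to its
#' axis, in offset order. A thickness in micrometres is converted to voxels
#' by rounding `thickness / voxelSize` to the nearest integer (minimum 1);
#' e.g. 520 um at 8.7 um/voxel gives a 60-voxel slab. Overlapping slabs are
#' allowed with a warning; out-of-bounds slabs are rejected.
#'
#' @param volume a [BinaryVolume-class].
#' @param spec a [SubvolumeSpec-class].
#' @return list of [BinaryVolume-class] slabs; each carries its offset and
#'   realized physical thickness in provenance.
#' @examples
#' v <- bernoulliVolume(c(16, 16, 64), 0.7, seed = 1, voxelSize = 8.7)
#' slabs <- extractSubvolumes(v, subvolumeSpec("z", c(1, 23, 45), 20))
#' sapply(slabs, function(s) porosity(s)@n)
#' @export
extractSubvolumes <- function(volume, spec) {
  stopifnot(is(volume, "BinaryVolume"), is(spec, "SubvolumeSpec"))
  margin <- axisMargin(spec@axis)
  d <- dims(volume)
  thick <- if (spec@units == "um")
    max(1L, as.integer(round(spec@thickness / voxelSize(volume))))
  else as.integer(spec@thickness)
  ends <- spec@offsets + thick - 1L
  if (any(ends > d[margin]) || any(spec@offsets < 1L))
    stop("subvolume slab out of bounds along axis ", spec@axis,
         " (extent ", d[margin], ", thickness ", thick, " voxels)")
  off <- sort(spec@offsets)
  if (length(off) > 1L && any(off[-1] <= (off[-length(off)] + thick - 1L)))
    warning("subvolume slabs overlap")
  lapply(spec@offsets, function(o) {
    origin <- c(1L, 1L, 1L); origin[margin] <- o
    size <- d; size[margin] <- thick
    slab <- extractROI(volume, origin, size)
    slab@provenance <- c(slab@provenance,
                         list(slabAxis = spec@axis, slabOffset = o,
                              slabThicknessVoxels = thick,
                              slabThicknessUm = thick * voxelSize(volume)))
    slab
  })
}

#' Equispaced slab offsets
#'
#' Convenience default for subvolume analysis: `n` slabs of the given
#' thickness spread evenly (first at index 1, last flush with the far face).
#'
#' @param volume a [BinaryVolume-class].
#' @param axis slab normal axis.
#' @param thickness slab thickness in voxels.
#' @param n number of slabs.
#' @return a [SubvolumeSpec-class].
#' @export
equispacedSlabs <- function(volume, axis = "z", thickness, n = 3) {
  d <- dims(volume)[axisMargin(axis)]
  thickness <- as.integer(thickness)
  if (thickness > d) stop("thickness exceeds volume extent along ", axis)
  if (n == 1L) return(subvolumeSpec(axis, 1L, thickness))
  off <- round(seq(1L, d - thickness + 1L, length.out = n))
  subvolumeSpec(axis, as.integer(off), thickness)
}
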