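#' @include AllGenerics.R
NULL

#' BinaryVolume: a 3D pore/solid voxel grid
#'
#' The substrate of all texture statistics in this package. Voxels are coded
#' 1 = pore (void, "white") and 0 = solid ("black"). The array uses R-native
#' 1-based `[i, j, k]` indexing with the first index fastest in memory; slices
#' of an acquisition stack occupy constant-`k` planes.
#'
#' @slot voxels 3D integer array over {0, 1}; 1 = pore.
#' @slot voxelSize physical voxel edge length in micrometres (> 0).
#' @slot provenance free-form list of metadata (generator parameters,
#'   realized porosity, segmentation settings, ...).
#' @seealso [porosity()], [lacunarityCurve()], [stackToVolume()]
#' @export
setClass("BinaryVolume",
  slots = c(voxels = "array", voxelSize = "numeric", provenance = "list"))

setValidity("BinaryVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L)
    return("voxels must be a 3D array")
  if (any(dim(v) < 1L))
    return("all dimensions must be >= 1")
  rng <- range(v)
  if (!(rng[1] %in% c(0, 1)) || !(rng[2] %in% c(0, 1)))
    return("voxels must contain only 0 (solid) and 1 (pore)")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive number (micrometres)")
  TRUE
})

#' Construct a BinaryVolume
#'
#' @param voxels 3D array of 0/1 values (1 = pore).
#' @param voxelSize voxel edge length in micrometres; default 1.
#' @param provenance optional metadata list.
#' @return a [BinaryVolume-class].
#' @examples
#' v <- BinaryVolume(array(c(0L, 1L), dim = c(2, 2, 2)))
#' porosity(v)
#' @export
BinaryVolume <- function(voxels, voxelSize = 1, provenance = list()) {
  storage.mode(voxels) <- "integer"
  new("BinaryVolume", voxels = voxels, voxelSize = as.numeric(voxelSize),
      provenance = provenance)
}

#' @rdname accessors
#' @export
setMethod("voxels", "BinaryVolume", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("voxelSize", "BinaryVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("dims", "BinaryVolume", function(x) dim(x@voxels))

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@voxels)
  p <- sum(object@voxels) / prod(d)
  cat(sprintf("BinaryVolume %d x %d x %d voxels (%.4g um/voxel), porosity %.4f\n",
              d[1], d[2], d[3], object@voxelSize, p))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

#' PorosityResult: exact void-fraction bookkeeping
#'
#' @slot n porosity, pore voxels over total voxels, in [0, 1].
#' @slot poreVoxels pore (void) voxel count, V_V in voxel units.
#' @slot totalVoxels total voxel count, V_TOT in voxel units.
#' @export
setClass("PorosityResult",
  slots = c(n = "numeric", poreVoxels = "numeric", totalVoxels = "numeric"))

setValidity("PorosityResult", function(object) {
  if (object@totalVoxels < 1) return("totalVoxels must be positive")
  if (abs(object@n - object@poreVoxels / object@totalVoxels) > 0)
    return("n must equal poreVoxels/totalVoxels exactly")
  if (object@n < 0 || object@n > 1) return("n must lie in [0, 1]")
  TRUE
})

setMethod("show", "PorosityResult", function(object) {
  cat(sprintf("Porosity n = %.6f (%g pore / %g total voxels)\n",
              object@n, object@poreVoxels, object@totalVoxels))
})

#' SyntheticSpec: parameters of a generated test volume
#'
#' Describes a synthetic binary volume: dimensions, target porosity, the
#' generator family, pore-radius distribution (for foams), the relative pore
#' occlusion fraction, and the RNG seed. Identical spec + seed yields a
#' bit-identical volume.
#'
#' @slot dims integer triple, all >= 2.
#' @slot targetPorosity fraction strictly inside (0, 1).
#' @slot generator one of `"regular"`, `"bernoulli"`, `"foam"`,
#'   `"occluded_foam"`.
#' @slot poreRadiusMean mean pore radius in voxels (foam generators).
#' @slot poreRadiusSd sd of the truncated-normal pore radius (voxels).
#' @slot occlusionFraction relative pore-volume reduction in [0, 1]
#'   (occluded_foam).
#' @slot seed non-negative integer RNG seed.
#' @export
setClass("SyntheticSpec",
  slots = c(dims = "integer", targetPorosity = "numeric",
            generator = "character", poreRadiusMean = "numeric",
            poreRadiusSd = "numeric", occlusionFraction = "numeric",
            seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 2L))
    return("dims must be a triple of integers >= 2")
  if (object@targetPorosity <= 0 || object@targetPorosity >= 1)
    return("targetPorosity must lie strictly inside (0, 1)")
  if (!object@generator %in% c("regular", "bernoulli", "foam", "occluded_foam"))
    return("unknown generator")
  if (object@occlusionFraction < 0 || object@occlusionFraction > 1)
    return("occlusionFraction must lie in [0, 1]")
  if (object@seed < 0L) return("seed must be non-negative")
  TRUE
})

#' Construct a SyntheticSpec
#'
#' @param dims integer triple of voxel dimensions.
#' @param targetPorosity target void fraction in (0, 1).
#' @param generator generator family (see [SyntheticSpec-class]).
#' @param poreRadiusMean,poreRadiusSd truncated-normal pore radius (voxels).
#' @param occlusionFraction relative pore-volume reduction in [0, 1].
#' @param seed non-negative integer seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(dims, targetPorosity = 0.81, generator = "foam",
                          poreRadiusMean = 7.5, poreRadiusSd = 1.5,
                          occlusionFraction = 0, seed = 0L) {
  new("SyntheticSpec", dims = as.integer(dims),
      targetPorosity = targetPorosity, generator = generator,
      poreRadiusMean = poreRadiusMean, poreRadiusSd = poreRadiusSd,
      occlusionFraction = occlusionFraction, seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec [%s] %s, target n = %.2f, seed %d\n",
              object@generator, paste(object@dims, collapse = "x"),
              object@targetPorosity, object@seed))
})

#' SegmentationResult: a binarized image with its selection score
#'
#' @slot binary 2D integer matrix over {0, 1}, 1 = pore; same dimensions as
#'   the source image.
#' @slot method one of `"niblack"`, `"sauvola"`, `"otsu"`, `"mean"`,
#'   `"fixed"`.
#' @slot parameters method-specific named parameter list.
#' @slot phaseNCC Fourier-phase normalized cross-correlation score in
#'   [-1, 1]; `NA` until scored against the grayscale original.
#' @export
setClass("SegmentationResult",
  slots = c(binary = "matrix", method = "character", parameters = "list",
            phaseNCC = "numeric"))

setValidity("SegmentationResult", function(object) {
  if (!object@method %in% c("niblack", "sauvola", "otsu", "mean", "fixed"))
    return("unknown segmentation method")
  rng <- range(object@binary)
  if (!(rng[1] %in% c(0, 1)) || !(rng[2] %in% c(0, 1)))
    return("binary image must contain only 0 and 1")
  s <- object@phaseNCC
  if (length(s) != 1L || (!is.na(s) && (s < -1 - 1e-12 || s > 1 + 1e-12)))
    return("phaseNCC must be a single value in [-1, 1] or NA")
  TRUE
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult [%s] %d x %d, pore fraction %.4f",
              object@method, nrow(object@binary), ncol(object@binary),
              mean(object@binary)))
  if (!is.na(object@phaseNCC))
    cat(sprintf(", phase NCC %.4f", object@phaseNCC))
  cat("\n")
})

#' BoxOccupancyDistribution: P(S, r) of the gliding box
#'
#' The probability distribution of pore-voxel counts per gliding box of side
#' `r`: for each observed occupancy S, `n(S, r)` is the number of box
#' positions containing exactly S pore voxels out of the `N(r)` boxes
#' enumerated at unit stride, and `P(S, r) = n(S, r) / N(r)`.
#'
#' @slot r box side in voxels.
#' @slot counts data.frame with columns `S` (occupancy), `n` (box count) and
#'   `p` (probability); S within [0, r^3].
#' @slot totalBoxes N(r), the number of box positions.
#' @export
setClass("BoxOccupancyDistribution",
  slots = c(r = "integer", counts = "data.frame", totalBoxes = "numeric"))

setValidity("BoxOccupancyDistribution", function(object) {
  cts <- object@counts
  if (!all(c("S", "n", "p") %in% names(cts)))
    return("counts must have columns S, n, p")
  if (any(cts$S < 0) || any(cts$S > as.numeric(object@r)^3))
    return("occupancies S must lie in [0, r^3]")
  if (abs(sum(cts$n) - object@totalBoxes) > 0)
    return("sum of counts must equal totalBoxes")
  if (abs(sum(cts$p) - 1) > 1e-12)
    return("probabilities must sum to 1 within 1e-12")
  TRUE
})

setMethod("show", "BoxOccupancyDistribution", function(object) {
  cat(sprintf("BoxOccupancyDistribution r = %d, N(r) = %g, %d distinct occupancies\n",
              object@r, object@totalBoxes, nrow(object@counts)))
})

#' LacunarityCurve: LAC(r) and RLF(r) across box sizes
#'
#' One record per box size r with the occupancy moments and derived
#' statistics: `N` = N(r) box positions, `meanS`/`varS` = mean and population
#' variance of pore counts per box, `mu1`/`mu2` = first and second moments of
#' P(S, r), `lac` = mu2/mu1^2 = 1 + varS/meanS^2, `lnR`/`lnLac` = natural-log
#' coordinates, and `rlf` = -ln(LAC)/ln(n) using the porosity stored on the
#' curve.
#'
#' @slot records data.frame with columns r, N, meanS, varS, mu1, mu2, lac,
#'   lnR, lnLac, rlf.
#' @slot porosity the porosity n used for RLF (NA when RLF undefined).
#' @slot dims dimensions of the analysed volume.
#' @slot voxelSize voxel edge length in micrometres.
#' @export
setClass("LacunarityCurve",
  slots = c(records = "data.frame", porosity = "numeric", dims = "integer",
            voxelSize = "numeric"))

setValidity("LacunarityCurve", function(object) {
  rec <- object@records
  need <- c("r", "N", "meanS", "varS", "mu1", "mu2", "lac", "lnR", "lnLac", "rlf")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  ok <- is.finite(rec$lac)
  if (any(rec$lac[ok] < 1 - 1e-9))
    return("lac must be >= 1 wherever defined")
  if (any(abs(rec$lac[ok] - (1 + rec$varS[ok] / rec$meanS[ok]^2)) > 1e-9))
    return("lac must equal 1 + varS/meanS^2 within 1e-9")
  if (any(abs(rec$lac[ok] - rec$mu2[ok] / rec$mu1[ok]^2) > 1e-9))
    return("lac must equal mu2/mu1^2 within 1e-9")
  TRUE
})

#' @rdname LacunarityCurve-class
#' @param x a LacunarityCurve.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "LacunarityCurve",
          function(x, ...) x@records)

setMethod("show", "LacunarityCurve", function(object) {
  rec <- object@records
  cat(sprintf("LacunarityCurve over %d box sizes (r = %d..%d), volume %s, n = %.4f\n",
              nrow(rec), min(rec$r), max(rec$r),
              paste(object@dims, collapse = "x"), object@porosity))
  print(utils::head(rec[, c("r", "N", "meanS", "lac", "rlf")], 8))
  if (nrow(rec) > 8) cat("  ...\n")
})

#' SubvolumeSpec: parallel slabs of a parent volume
#'
#' Describes parallel, non-wrapping slabs cut perpendicular to one axis, by
#' 1-based start indices and a common thickness. A thickness given in
#' micrometres is converted to voxels by rounding `thickness / voxelSize` to
#' the nearest integer (minimum 1).
#'
#' @slot axis one of `"x"`, `"y"`, `"z"` (array indices i, j, k).
#' @slot offsets integer vector of 1-based slab start indices.
#' @slot thickness slab thickness (in `units`).
#' @slot units `"voxels"` or `"um"`.
#' @export
setClass("SubvolumeSpec",
  slots = c(axis = "character", offsets = "integer", thickness = "numeric",
            units = "character"))

setValidity("SubvolumeSpec", function(object) {
  if (!object@axis %in% c("x", "y", "z")) return("axis must be x, y or z")
  if (length(object@offsets) < 1L || any(object@offsets < 1L))
    return("offsets must be 1-based start indices")
  if (object@thickness <= 0) return("thickness must be positive")
  if (!object@units %in% c("voxels", "um")) return("units must be voxels or um")
  TRUE
})

#' Construct a SubvolumeSpec
#'
#' @param axis slab normal axis, `"x"`, `"y"` or `"z"`.
#' @param offsets 1-based slab start indices along that axis.
#' @param thickness slab thickness.
#' @param units `"voxels"` (default) or `"um"`.
#' @return a [SubvolumeSpec-class].
#' @examples
#' subvolumeSpec("z", offsets = c(1, 23, 45), thickness = 20)
#' @export
subvolumeSpec <- function(axis, offsets, thickness, units = "voxels") {
  new("SubvolumeSpec", axis = axis, offsets = as.integer(offsets),
      thickness = as.numeric(thickness), units = units)
}

setMethod("show", "SubvolumeSpec", function(object) {
  cat(sprintf("SubvolumeSpec: %d slab(s) along %s, thickness %g %s, offsets %s\n",
              length(object@offsets), object@axis, object@thickness,
              object@units, paste(object@offsets, collapse = ", ")))
})

#' TextureReport: the full output of a pipeline run
#'
#' @slot porosity a [PorosityResult-class] for the analysed volume (post-ROI).
#' @slot curve the whole-volume [LacunarityCurve-class].
#' @slot randomness randomness-scale diagnostics (see [randomnessScale()]).
#' @slot subvolumes per-slab curves and divergence summary, or empty list.
#' @slot segmentation per-slice method/score data.frame, or NULL for
#'   pre-binarized input.
#' @slot config the fully-resolved configuration echo.
#' @export
setClass("TextureReport",
  slots = c(porosity = "PorosityResult", curve = "LacunarityCurve",
            randomness = "list", subvolumes = "list", segmentation = "ANY",
            config = "list"))

setMethod("show", "TextureReport", function(object) {
  cat("TextureReport\n")
  cat("  "); show(object@porosity)
  rec <- object@curve@records
  cat(sprintf("  LAC(r): %d box sizes, LAC(1) = %.4f, LAC(max r) = %.4f\n",
              nrow(rec), rec$lac[1], rec$lac[nrow(rec)]))
  rs <- object@randomness$rStar
  cat(sprintf("  randomness scale r* = %s (epsilon = %g)\n",
              ifelse(is.na(rs), "beyond range", as.character(rs)),
              object@randomness$epsilon))
  if (length(object@subvolumes))
    cat(sprintf("  subvolumes: %d slabs, max RLF divergence %.4f\n",
                length(object@subvolumes$curves),
                object@subvolumes$divergence))
})
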