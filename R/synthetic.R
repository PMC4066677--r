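#' @include AllClasses.R utils.R
NULL

#' Exactly periodic pore lattice
#'
#' Generates a binary volume that is exactly periodic with the given period
#' along all three axes: every period-sized tile holds the same pore pattern
#' (the first `poresPerPeriod` tile cells in linear order). A totally regular
#' structure of this kind has gliding-box lacunarity exactly 1 at every box
#' size that is a multiple of the period, because every such box holds the
#' same pore count.
#'
#' @param dims integer triple; `period` must divide every dimension.
#' @param period tile side in voxels.
#' @param poresPerPeriod pore voxels per tile, at most `period^3`.
#' @param voxelSize voxel edge length in micrometres.
#' @return a [BinaryVolume-class] with porosity `poresPerPeriod / period^3`.
#' @examples
#' v <- regularLattice(c(8, 8, 8), period = 2, poresPerPeriod = 1)
#' porosity(v)  # 1/8
#' glidingBoxLacunarity(v, r = 2)  # exactly 1
#' @export
regularLattice <- function(dims, period, poresPerPeriod, voxelSize = 1) {
  dims <- as.integer(dims); period <- as.integer(period)
  if (any(dims %% period != 0L))
    stop("period must divide every dimension; offending axis: ",
         paste(c("x", "y", "z")[dims %% period != 0L], collapse = ", "))
  if (poresPerPeriod < 0 || poresPerPeriod > period^3)
    stop("poresPerPeriod must lie in [0, period^3]")
  tile <- array(0L, rep(period, 3))
  if (poresPerPeriod > 0) tile[seq_len(poresPerPeriod)] <- 1L
  ix <- function(n) ((seq_len(n) - 1L) %% period) + 1L
  vox <- tile[ix(dims[1]), ix(dims[2]), ix(dims[3]), drop = FALSE]
  dim(vox) <- dims
  BinaryVolume(vox, voxelSize,
               provenance = list(generator = "regular", period = period,
                                 poresPerPeriod = poresPerPeriod))
}

#' Independent Bernoulli voxel field
#'
#' Each voxel is pore with probability `p`, independently. This is the
#' maximally random texture at a given porosity: its lacunarity follows the
#' i.i.d. closed form LAC(r) ~ 1 + (1 - p) / (p r^3) and decays to 1 within a
#' few voxels, making it the baseline against which clustered (foam-like)
#' structures are compared.
#'
#' @param dims integer triple.
#' @param p pore probability in [0, 1].
#' @param seed non-negative integer seed; the draw is bit-reproducible.
#' @param voxelSize voxel edge length in micrometres.
#' @return a [BinaryVolume-class].
#' @export
bernoulliVolume <- function(dims, p, seed = 0L, voxelSize = 1) {
  dims <- as.integer(dims)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  vox <- withSeed(seed, {
    array(as.integer(stats::runif(prod(dims)) < p), dim = dims)
  })
  BinaryVolume(vox, voxelSize,
               provenance = list(generator = "bernoulli", p = p, seed = seed))
}

# Truncated-normal pore radius: lower bound 1 voxel, upper bound below the
# smallest volume extent. sd = 0 degenerates to the (clamped) mean.
drawRadius <- function(mean, sd, upper) {
  if (sd <= 0) return(min(max(mean, 1), upper))
  for (i in 1:1000) {
    r <- stats::rnorm(1, mean, sd)
    if (r >= 1 && r <= upper) return(r)
  }
  min(max(mean, 1), upper)
}

# Stamp a sphere of pore voxels (voxel centre inside the sphere) onto vox,
# clipped at the volume boundary. Returns the updated array.
stampSphere <- function(vox, centre, radius) {
  d <- dim(vox)
  lo <- pmax(ceiling(centre - radius), 1L)
  hi <- pmin(floor(centre + radius), d)
  if (any(lo > hi)) return(vox)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - centre[1])^2
  dy2 <- (ys - centre[2])^2
  dz2 <- (zs - centre[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
  block <- vox[xs, ys, zs, drop = FALSE]
  block[inside] <- 1L
  vox[xs, ys, zs] <- block
  vox
}

#' Overlapping-sphere foam volume
#'
#' Emulates a freeze-dried foam: spherical pores with truncated-normal radii
#' are dropped at uniform random centres and unioned into the pore phase
#' until the realized porosity first reaches the target (overshoot of at most
#' one sphere is allowed). The realized porosity is recorded in the
#' provenance and always equals a direct voxel count.
#'
#' @param spec a [SyntheticSpec-class] with `generator = "foam"` (or
#'   `"occluded_foam"`, in which case [occludePores()] is applied with
#'   `spec@occlusionFraction` afterwards).
#' @param voxelSize voxel edge length in micrometres.
#' @return a [BinaryVolume-class]; `provenance$realizedPorosity` holds the
#'   achieved void fraction.
#' @examples
#' sp <- syntheticSpec(c(32, 32, 32), targetPorosity = 0.8,
#'                     poreRadiusMean = 4, poreRadiusSd = 1, seed = 7)
#' v <- foamVolume(sp)
#' v@provenance$realizedPorosity
#' @export
foamVolume <- function(spec, voxelSize = 1) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (!spec@generator %in% c("foam", "occluded_foam"))
    stop("spec generator must be foam or occluded_foam")
  d <- spec@dims
  if (spec@poreRadiusMean >= min(d))
    stop("unreachable porosity: pore radius >= smallest dimension")
  total <- prod(as.numeric(d))
  target <- spec@targetPorosity
  maxR <- min(d) / 2
  res <- withSeed(spec@seed, {
    v <- array(0L, dim = d)
    nPore <- 0
    spheres <- list()
    while (nPore / total < target) {
      centre <- stats::runif(3, min = 0.5, max = d + 0.5)
      radius <- drawRadius(spec@poreRadiusMean, spec@poreRadiusSd, maxR)
      v <- stampSphere(v, centre, radius)
      nPore <- sum(v)
      spheres[[length(spheres) + 1L]] <- c(centre, radius)
      if (length(spheres) > 1e6)
        stop("unreachable porosity: sphere cap exceeded")
    }
    list(v = v, spheres = do.call(rbind, spheres))
  })
  vox <- res$v
  spheres <- res$spheres
  colnames(spheres) <- c("cx", "cy", "cz", "radius")
  out <- BinaryVolume(vox, voxelSize,
    provenance = list(generator = "foam", spec = spec,
                      realizedPorosity = sum(vox) / total,
                      spheres = spheres))
  if (spec@generator == "occluded_foam" && spec@occlusionFraction > 0)
    out <- occludePores(out, spec@occlusionFraction, seed = spec@seed + 1L)
  out
}

# Pore voxels with at least one 6-neighbour that is solid or outside the
# volume (outside counts as solid, so erosion proceeds from the boundary).
poreBoundary <- function(vox) {
  d <- dim(vox)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vox
  core <- function(di, dj, dk)
    pad[(2:(d[1] + 1L)) + di, (2:(d[2] + 1L)) + dj, (2:(d[3] + 1L)) + dk,
        drop = FALSE]
  nbMin <- pmin(core(-1L, 0L, 0L), core(1L, 0L, 0L),
                core(0L, -1L, 0L), core(0L, 1L, 0L),
                core(0L, 0L, -1L), core(0L, 0L, 1L))
  vox == 1L & nbMin == 0L
}

#' Occlude pores of a binary volume
#'
#' Emulates micropore occlusion by particle deposition, reducing the pore
#' volume by the requested relative fraction. Two mechanisms are available:
#'
#' * `"pores"` — converts randomly selected whole pores to solid. Requires
#'   the sphere list a [foamVolume()] records in its provenance: spheres are
#'   dropped in a seeded random order until the pore-volume reduction first
#'   reaches the target (granularity of one sphere; voxels shared with kept
#'   spheres stay pore). Removing whole pores leaves the surviving pores at
#'   full size, so the structure becomes sparser and more clumped — its
#'   porosity-normalized heterogeneity (RLF) rises, as occlusion does in
#'   real composite foams.
#' * `"erosion"` — morphological erosion of the pore phase, layer by layer
#'   (6-connectivity, the volume boundary acting as solid), removing voxels
#'   of the final partial layer in a seeded random order so the reduction is
#'   met exactly. Works on any binary volume; thickens walls uniformly.
#'
#' The default `"auto"` uses `"pores"` when a sphere list is present and
#' `"erosion"` otherwise. Either way the seeded removal order is a fixed
#' sequence, so the operation is monotone: a larger fraction removes a
#' superset of pore voxels and never yields a larger porosity.
#'
#' @param volume a [BinaryVolume-class].
#' @param occlusionFraction relative pore-volume reduction in [0, 1].
#' @param seed non-negative integer seed for the removal order.
#' @param mode `"auto"`, `"pores"` or `"erosion"`.
#' @return a [BinaryVolume-class] with reduced (never increased) porosity;
#'   `provenance$realizedPorosity` records the achieved void fraction.
#' @examples
#' sp <- syntheticSpec(c(32, 32, 32), targetPorosity = 0.81,
#'                     poreRadiusMean = 4, seed = 1)
#' s1 <- foamVolume(sp)
#' s3 <- occludePores(s1, 1 - 0.68 / 0.81, seed = 2)  # Table-1-like contrast
#' porosity(s3)@n
#' @export
occludePores <- function(volume, occlusionFraction, seed = 0L,
                         mode = c("auto", "pores", "erosion")) {
  stopifnot(is(volume, "BinaryVolume"))
  mode <- match.arg(mode)
  if (occlusionFraction < 0 || occlusionFraction > 1)
    stop("occlusionFraction must lie in [0, 1]")
  spheres <- volume@provenance$spheres
  if (mode == "auto") mode <- if (is.null(spheres)) "erosion" else "pores"
  if (mode == "pores" && is.null(spheres))
    stop("mode 'pores' requires the sphere list recorded by foamVolume()")
  vox <- voxels(volume)
  nPore <- sum(vox)
  toRemove <- round(occlusionFraction * nPore)
  if (toRemove == 0)
    return(BinaryVolume(vox, voxelSize(volume),
                        provenance = c(volume@provenance,
                                       list(occlusionFraction = occlusionFraction))))
  if (mode == "pores") {
    nS <- nrow(spheres)
    ord <- withSeed(seed, sample.int(nS))  # removal order; prefix-nested
                                           # across fractions at fixed seed
    rebuild <- function(nRemoved) {
      v <- array(0L, dim = dim(vox))
      keep <- if (nRemoved < nS) ord[(nRemoved + 1L):nS] else integer(0)
      for (s in keep)
        v <- stampSphere(v, spheres[s, 1:3], spheres[s, 4])
      v
    }
    # first crossing of the target reduction; removed-voxel count is
    # monotone in the number of dropped spheres, so bisect
    lo <- 0L; hi <- nS
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (nPore - sum(rebuild(mid)) >= toRemove) hi <- mid else lo <- mid
    }
    vox <- rebuild(hi)
  } else {
    vox <- withSeed(seed, {
      left <- toRemove
      while (left > 0) {
        idx <- which(poreBoundary(vox))
        if (length(idx) == 0L) break  # isolated pores exhausted
        ord <- sample.int(length(idx))  # drawn every layer: keeps the
                                        # removal sequence identical
                                        # across fractions
        take <- idx[ord[seq_len(min(left, length(idx)))]]
        vox[take] <- 0L
        left <- left - length(take)
      }
      vox
    })
  }
  BinaryVolume(vox, voxelSize(volume),
               provenance = c(volume@provenance[setdiff(names(volume@provenance),
                                                        "spheres")],
                              list(occlusionFraction = occlusionFraction,
                                   occlusionMode = mode,
                                   occlusionSeed = as.integer(seed),
                                   realizedPorosity = sum(vox) / prod(dim(vox)))))
}

#' Render a binary volume as a grayscale slice stack
#'
#' Maps solid voxels to a high intensity and pores to a low intensity
#' (matching the X-ray attenuation of material versus air), adds i.i.d.
#' Gaussian noise, optionally superimposes a linear per-slice illumination
#' gradient across the columns, and clamps to [0, 1]. The generating binary
#' volume is the ground truth for segmentation tests.
#'
#' @param volume a [BinaryVolume-class]; slices are taken along the third
#'   array index.
#' @param noiseSd Gaussian noise standard deviation (intensity units >= 0).
#' @param illuminationGradient total intensity change across the slice width
#'   (0 disables the gradient).
#' @param seed non-negative integer seed for the noise.
#' @param solidIntensity,poreIntensity noise-free intensities of the two
#'   phases.
#' @return a list with elements `slices` (list of 2D matrices in [0, 1]) and
#'   `groundTruth` (the input volume).
#' @export
renderGrayscaleStack <- function(volume, noiseSd = 0, illuminationGradient = 0,
                                 seed = 0L, solidIntensity = 0.8,
                                 poreIntensity = 0.2) {
  stopifnot(is(volume, "BinaryVolume"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  vox <- voxels(volume)
  d <- dim(vox)
  slices <- withSeed(seed, {
    lapply(seq_len(d[3]), function(k) {
      img <- ifelse(vox[, , k] == 1L, poreIntensity, solidIntensity)
      if (illuminationGradient != 0) {
        g <- illuminationGradient *
          ((seq_len(d[2]) - 1) / max(d[2] - 1, 1) - 0.5)
        img <- img + matrix(g, nrow = d[1], ncol = d[2], byrow = TRUE)
      }
      if (noiseSd > 0)
        img <- img + matrix(stats::rnorm(length(img), sd = noiseSd),
                            nrow = d[1])
      pmin(pmax(img, 0), 1)
    })
  })
  list(slices = slices, groundTruth = volume)
}
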