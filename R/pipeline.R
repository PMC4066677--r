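#' @include AllClasses.R geometry.R lacunarity.R segmentation.R io.R
NULL

#' Compare texture heterogeneity across parallel subvolumes
#'
#' Extracts the slabs of `spec`, computes each slab's porosity and
#' lacunarity/RLF curve, and summarizes their disagreement: the divergence is
#' the maximum over box sizes of the range (max - min) of RLF across slabs.
#' Box sizes exceeding a slab's smallest extent are dropped for that slab
#' with a note; the divergence uses the box sizes common to all slabs.
#' A homogeneous structure yields curves that agree within sampling noise
#' (small divergence); regionally heterogeneous structures push the
#' divergence above the homogeneous Monte-Carlo band (see
#' [homogeneousDivergenceBand()]).
#'
#' @param volume a [BinaryVolume-class].
#' @param spec a [SubvolumeSpec-class].
#' @param rValues box sides for the per-slab curves.
#' @param threshold optional divergence threshold; when given, the smallest r
#'   whose RLF range exceeds it is reported.
#' @return list with `curves` (per-slab [LacunarityCurve-class]),
#'   `porosities`, `rlf` (matrix, box sizes x slabs), `divergence`,
#'   `divergenceR` (box size attaining it), `exceedsAtR` (smallest r over
#'   `threshold`, NA if none or no threshold), `droppedR` (per-slab notes).
#' @export
compareSubvolumeHeterogeneity <- function(volume, spec, rValues = NULL,
                                          threshold = NULL) {
  slabs <- extractSubvolumes(volume, spec)
  if (is.null(rValues))
    rValues <- seq_len(min(64L, min(vapply(slabs, function(s) min(dims(s)), 1L))))
  rValues <- as.integer(rValues)
  dropped <- character(0)
  curves <- lapply(seq_along(slabs), function(i) {
    s <- slabs[[i]]
    keep <- rValues[rValues <= min(dims(s))]
    if (length(keep) < length(rValues))
      dropped <<- c(dropped, sprintf(
        "slab %d: dropped r > %d (%s)", i, min(dims(s)),
        paste(setdiff(rValues, keep), collapse = ", ")))
    lacunarityCurve(s, keep)
  })
  common <- Reduce(intersect, lapply(curves, function(cv) cv@records$r))
  rlf <- vapply(curves, function(cv) {
    rec <- cv@records
    rec$rlf[match(common, rec$r)]
  }, numeric(length(common)))
  rlf <- matrix(rlf, nrow = length(common),
                dimnames = list(r = common, slab = seq_along(curves)))
  rng <- apply(rlf, 1, function(x) diff(range(x)))
  divergence <- max(rng, na.rm = TRUE)
  divergenceR <- common[which.max(rng)]
  exceedsAtR <- NA_integer_
  if (!is.null(threshold)) {
    hit <- which(rng > threshold)
    if (length(hit)) exceedsAtR <- common[hit[1]]
  }
  list(curves = curves,
       porosities = vapply(curves, function(cv) cv@porosity, 0),
       rlf = rlf, divergence = divergence, divergenceR = divergenceR,
       exceedsAtR = exceedsAtR, droppedR = dropped)
}

#' Monte-Carlo divergence band of a homogeneous structure
#'
#' Establishes, by re-seeded simulation of homogeneous Bernoulli volumes, the
#' subvolume RLF divergence expected from sampling noise alone. The returned
#' 95th percentile is the default threshold for calling a divergence
#' "remarkable"; the maximum bounds the band.
#'
#' @param dims volume dimensions.
#' @param p porosity of the homogeneous Bernoulli field.
#' @param spec a [SubvolumeSpec-class] applied to every replicate.
#' @param rValues box sides for the per-slab curves.
#' @param nrep number of replicates (default 100).
#' @param seed base seed; replicate i uses `seed + i`.
#' @return list with `divergences` (length `nrep`), `q95`, `max`.
#' @export
homogeneousDivergenceBand <- function(dims, p, spec, rValues, nrep = 100,
                                      seed = 0L) {
  divergences <- vapply(seq_len(nrep), function(i) {
    v <- bernoulliVolume(dims, p, seed = seed + i)
    compareSubvolumeHeterogeneity(v, spec, rValues)$divergence
  }, 0)
  list(divergences = divergences,
       q95 = unname(stats::quantile(divergences, 0.95)),
       max = max(divergences))
}

# Resolve a pipeline input description to (volume | slices).
resolveInput <- function(config) {
  input <- config$input
  if (is(input, "BinaryVolume")) return(list(volume = input))
  if (is.list(input) && !is.null(input$slices))
    return(list(slices = input$slices))
  if (is.character(input)) {
    if (grepl("\\.raw$", input)) return(list(volume = readVolume(input)))
    return(list(slices = readSliceStack(input)))
  }
  stop("pipeline input must be a BinaryVolume, a raw volume path, a slice ",
       "stack path, or list(slices = ...)")
}

#' Run the full texture-characterization pipeline
#'
#' Orchestrates the workflow: (grayscale input only) per-slice segmentation
#' with automatic strategy selection, stacking into a binary volume, optional
#' ROI extraction, porosity, the lacunarity/RLF curve, randomness-scale
#' detection, and optional parallel-subvolume heterogeneity comparison.
#' Outputs (`curve.csv`, `subvolumes.csv`, `report.json`) are written when an
#' output directory is configured; re-running an identical config on the same
#' input reproduces them byte for byte.
#'
#' @param config a named list (or path to a YAML/JSON file) with entries:
#'   `input` (BinaryVolume, `.raw` path, slice-stack path, or
#'   `list(slices = ...)` of grayscale matrices), `voxelSizeUm` (default 1),
#'   `segmentation` (list: `method` "auto"/"niblack"/"sauvola"/"otsu"/...,
#'   `windowSize`, `k`, `R`, `poreIsDark`), `roi` (list: `origin`, `size`),
#'   `rValues`, `epsilon` (randomness-scale tolerance, default 0.05),
#'   `subvolumes` (list: `axis`, `offsets`, `thickness`, `units`),
#'   `divergenceThreshold`, `outputDir`.
#' @return a [TextureReport-class].
#' @examples
#' v <- bernoulliVolume(c(16, 16, 16), 0.7, seed = 1)
#' rep <- runPipeline(list(input = v, rValues = c(1, 2, 4, 8, 16)))
#' rep
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  voxelSizeUm <- config$voxelSizeUm %||% 1

  stage <- "input"
  report <- tryCatch({
    src <- resolveInput(config)
    segLog <- NULL
    if (!is.null(src$volume)) {
      vol <- src$volume
    } else {
      stage <- "segmentation"
      seg <- config$segmentation %||% list()
      segRun <- segmentStack(src$slices,
        method = seg$method %||% "auto",
        candidates = defaultCandidates(seg$windowSize %||% 25),
        poreIsDark = seg$poreIsDark %||% TRUE)
      segLog <- segRun$log
      stage <- "reconstruction"
      vol <- stackToVolume(segRun$binaries, voxelSizeUm)
    }
    if (!is.null(config$roi)) {
      stage <- "roi"
      vol <- extractROI(vol, config$roi$origin, config$roi$size)
    }
    stage <- "porosity"
    por <- porosity(vol)
    stage <- "lacunarity"
    rValues <- config$rValues %||% seq_len(min(64L, min(dims(vol))))
    curve <- lacunarityCurve(vol, as.integer(rValues))
    stage <- "randomness scale"
    rand <- randomnessScale(curve, config$epsilon %||% 0.05)
    sub <- list()
    if (!is.null(config$subvolumes)) {
      stage <- "subvolume analysis"
      sv <- config$subvolumes
      spec <- subvolumeSpec(sv$axis %||% "z", sv$offsets, sv$thickness,
                            sv$units %||% "voxels")
      sub <- compareSubvolumeHeterogeneity(vol, spec, as.integer(rValues),
                                           threshold = config$divergenceThreshold)
    }
    new("TextureReport", porosity = por, curve = curve, randomness = rand,
        subvolumes = sub, segmentation = segLog,
        config = c(config[setdiff(names(config), c("input", "outputDir"))],
                   list(voxelSizeUm = voxelSizeUm, rValues = rValues)))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(config$outputDir)) writeTextureReport(report, config$outputDir)
  report
}

#' Write a TextureReport to disk
#'
#' Writes `curve.csv` (the whole-volume curve records), `subvolumes.csv`
#' (per-slab curves, when present) and `report.json` (porosity, randomness
#' diagnostics, divergence summary, per-slice segmentation log, config echo).
#'
#' @param report a [TextureReport-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeTextureReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@curve@records, file.path(dir, "curve.csv"),
                   row.names = FALSE)
  if (length(report@subvolumes)) {
    slabRecs <- do.call(rbind, lapply(seq_along(report@subvolumes$curves),
      function(i) cbind(slab = i, report@subvolumes$curves[[i]]@records)))
    utils::write.csv(slabRecs, file.path(dir, "subvolumes.csv"),
                     row.names = FALSE)
  }
  por <- report@porosity
  json <- list(
    porosity = list(n = por@n, pore_voxels = por@poreVoxels,
                    total_voxels = por@totalVoxels),
    curve_endpoints = list(
      lac_r1 = report@curve@records$lac[1],
      lac_rmax = report@curve@records$lac[nrow(report@curve@records)]),
    randomness = report@randomness,
    subvolume_divergence = if (length(report@subvolumes))
      list(divergence = report@subvolumes$divergence,
           divergence_r = report@subvolumes$divergenceR,
           exceeds_at_r = report@subvolumes$exceedsAtR,
           porosities = report@subvolumes$porosities)
    else NULL,
    segmentation = report@segmentation,
    config = report@config)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
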