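#' @include AllClasses.R
NULL

#' Write a binary volume as raw uint8 + JSON sidecar
#'
#' The voxel array is written as little-endian unsigned bytes with the first
#' array index fastest (x fastest, z slowest on disk), alongside a
#' `<path>.json` sidecar recording dims, voxel size in micrometres and the
#' byte order, so the file is self-describing.
#'
#' @param volume a [BinaryVolume-class].
#' @param path output path for the `.raw` file (the sidecar replaces the
#'   extension with `.json`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "BinaryVolume"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(voxels(volume)), con)
  sidecar <- sub("\\.raw$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(dims = dims(volume), voxel_size_um = voxelSize(volume),
         dtype = "uint8", order = "x-fastest", pore_value = 1),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raw uint8 volume written by [writeVolume()]
#'
#' @param path path to the `.raw` file; its `.json` sidecar must sit next to
#'   it.
#' @return a [BinaryVolume-class].
#' @export
readVolume <- function(path) {
  sidecar <- sub("\\.raw$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  raw <- readBin(path, "raw", n = prod(d))
  if (length(raw) != prod(d))
    stop("raw file shorter than dims promise: ", path)
  vox <- array(as.integer(raw), dim = d)
  BinaryVolume(vox, meta$voxel_size_um %||% 1,
               provenance = list(source = path))
}

#' Write a grayscale or binary slice stack as TIFF
#'
#' Either one multi-page TIFF (`multipage = TRUE`) or one file per slice
#' (`slice_0001.tif`, ...) in a directory.
#'
#' @param slices list of 2D matrices with values in [0, 1].
#' @param path output file (multipage) or directory (per-slice).
#' @param multipage write a single multi-page file (default) or one file per
#'   slice.
#' @return the written path(s), invisibly.
#' @export
writeSliceStack <- function(slices, path, multipage = TRUE) {
  slices <- lapply(slices, function(s) pmin(pmax(s, 0), 1))
  if (multipage) {
    tiff::writeTIFF(slices, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(path, sprintf("slice_%04d.tif", seq_along(slices)))
  for (i in seq_along(slices)) tiff::writeTIFF(slices[[i]], files[i])
  invisible(files)
}

#' Read a TIFF or PNG slice stack
#'
#' Accepts a multi-page TIFF, a single TIFF/PNG image, or a directory of
#' TIFF/PNG slices (read in lexicographic filename order). Color images are
#' collapsed to grayscale by channel averaging.
#'
#' @param path file or directory.
#' @return list of 2D grayscale matrices.
#' @export
readSliceStack <- function(path) {
  toGray <- function(img) {
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    img
  }
  readOne <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE))
      return(list(toGray(png::readPNG(f))))
    lapply(tiff::readTIFF(f, all = TRUE), toGray)
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF/PNG slices in ", path)
    return(do.call(c, lapply(files, readOne)))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  readOne(path)
}
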