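#' @include AllClasses.R utils.R
NULL

# Apply a per-pixel threshold map with the stated polarity. Pores are dark
# under the default convention (air attenuates X-rays less than material):
# pixel strictly below the threshold -> pore.
applyThreshold <- function(image, thresholdMap, poreIsDark = TRUE) {
  b <- if (poreIsDark) image < thresholdMap else image > thresholdMap
  m <- matrix(as.integer(b), nrow = nrow(image))
  m
}

#' Niblack local threshold
#'
#' Per-pixel threshold T = local mean + k * local sd over a square window
#' (reflect padding at the borders). With the default `poreIsDark = TRUE`
#' polarity a pixel strictly below its threshold becomes pore (1). On a
#' locally constant region the sd is zero, so no pixel falls strictly below
#' its own value and the region is classified solid.
#'
#' @param image 2D grayscale matrix.
#' @param windowSize odd window side >= 3, smaller than the image.
#' @param k Niblack weight; the customary value for dark objects is -0.2.
#' @param poreIsDark if TRUE (default) dark pixels become pore.
#' @return integer 0/1 matrix with the dimensions of `image`.
#' @export
niblackThreshold <- function(image, windowSize = 25, k = -0.2,
                             poreIsDark = TRUE) {
  st <- localMeanSd(image, as.integer(windowSize))
  applyThreshold(image, st$mean + k * st$sd, poreIsDark)
}

#' Sauvola local threshold
#'
#' Per-pixel threshold T = local mean * (1 + k * (local sd / R - 1)) with
#' reflect padding; `R` is the dynamic-range normalizer. More robust than
#' Niblack against locally flat background because the sd term is scaled by
#' the mean. Polarity contract as in [niblackThreshold()].
#'
#' @inheritParams niblackThreshold
#' @param k Sauvola weight, customarily 0.2 for dark objects.
#' @param R dynamic-range normalizer > 0; defaults to half the image's
#'   intensity range (0.5 for a constant image).
#' @return integer 0/1 matrix with the dimensions of `image`.
#' @export
sauvolaThreshold <- function(image, windowSize = 25, k = 0.2, R = NULL,
                             poreIsDark = TRUE) {
  if (is.null(R)) {
    R <- diff(range(image)) / 2
    if (R <= 0) R <- 0.5
  }
  if (R <= 0) stop("R must be > 0")
  st <- localMeanSd(image, as.integer(windowSize))
  applyThreshold(image, st$mean * (1 + k * (st$sd / R - 1)), poreIsDark)
}

#' Global thresholds (Otsu, mean, fixed)
#'
#' A single threshold applied image-wide: Otsu's criterion (via
#' \pkg{EBImage}), the image mean, or a user-fixed value. A fixed threshold
#' outside the intensity range yields a degenerate all-one-class image with a
#' warning.
#'
#' @inheritParams niblackThreshold
#' @param method `"otsu"`, `"mean"` or `"fixed"`.
#' @param t threshold value, required for `method = "fixed"`.
#' @return integer 0/1 matrix with the dimensions of `image`.
#' @export
globalThreshold <- function(image, method = c("otsu", "mean", "fixed"),
                            t = NULL, poreIsDark = TRUE) {
  method <- match.arg(method)
  T <- switch(method,
    otsu = {
      rng <- range(image)
      if (rng[2] > rng[1]) EBImage::otsu(image, range = rng) else rng[1]
    },
    mean = mean(image),
    fixed = {
      if (is.null(t)) stop("fixed method requires a threshold t")
      if (t < min(image) || t > max(image))
        warning("fixed threshold outside the intensity range: ",
                "output is a single class")
      t
    })
  applyThreshold(image, matrix(T, nrow(image), ncol(image)), poreIsDark)
}

#' Normalized cross-correlation of Fourier phases
#'
#' Scores how faithfully a candidate binarization preserves the spatial
#' structure of the grayscale original: both images are transformed with the
#' 2D DFT, the per-frequency phase angles (in (-pi, pi]) are extracted, and
#' the zero-lag Pearson correlation between the two phase arrays is returned,
#' excluding the DC term. Phase is invariant to positive linear intensity
#' rescaling, so the score compares structure, not contrast.
#'
#' When the pore phase is dark in the grayscale (the default polarity), pass
#' the candidate in display polarity — i.e. the solid mask `1 - binary` — so
#' that a perfect binarization is a positive linear transform of a noiseless
#' original and scores 1; [selectSegmentation()] does this automatically.
#'
#' @param original 2D grayscale matrix.
#' @param binary candidate 0/1 matrix of identical dimensions.
#' @return a score in [-1, 1]; 1 means identical phase structure.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' b <- matrix(as.integer(img < 0.5), 8, 8)
#' fourierPhaseNCC(img, b)
#' @export
fourierPhaseNCC <- function(original, binary) {
  if (!all(dim(original) == dim(binary)))
    stop("original and binary images must have identical dimensions")
  if (diff(range(original)) == 0)
    stop("degenerate input: constant grayscale image has undefined phase structure")
  if (diff(range(binary)) == 0)
    stop("degenerate input: constant binary image has undefined phase structure")
  # wrapped phase in (-pi, pi], DC term at [1, 1] dropped; coefficients that
  # are real up to numerical noise (e.g. Nyquist terms of real images) sit on
  # the +/-pi branch cut, so their phase is canonicalized from the sign of
  # the real part to keep the score deterministic
  # wrapped phase in (-pi, pi], DC term at [1, 1] dropped. Two degenerate
  # coefficient families need a fixed convention to keep the score
  # deterministic: (numerically) zero coefficients have no phase and take 0,
  # and (numerically) real coefficients — e.g. Nyquist terms of real images —
  # sit on the +/-pi branch cut and take 0 or pi from the sign of Re.
  ph <- function(m) {
    z <- stats::fft(m)
    p <- Arg(z)
    zeroish <- Mod(z) <= 1e-9 * max(Mod(z))
    p[zeroish] <- 0
    realish <- !zeroish & abs(Im(z)) <= 1e-9 * Mod(z)
    p[realish] <- ifelse(Re(z)[realish] >= 0, 0, pi)
    p[-1]
  }
  p1 <- ph(original); p2 <- ph(binary + 0)
  if (stats::sd(p1) == 0 || stats::sd(p2) == 0)
    stop("degenerate input: zero phase variance")
  stats::cor(p1, p2)
}

# Score a pore mask against the grayscale original in display polarity:
# with dark pores the solid mask (1 - binary) matches the original's
# intensity convention, so exact recovery scores +1.
scoreSegmentation <- function(image, binary, poreIsDark = TRUE) {
  fourierPhaseNCC(image, if (poreIsDark) 1L - binary else binary)
}

# Build one candidate segmentation from a parameter list.
runCandidate <- function(image, cand, poreIsDark) {
  method <- cand$method
  binary <- switch(method,
    niblack = niblackThreshold(image,
                windowSize = cand$windowSize %||% 25,
                k = cand$k %||% -0.2, poreIsDark = poreIsDark),
    sauvola = sauvolaThreshold(image,
                windowSize = cand$windowSize %||% 25,
                k = cand$k %||% 0.2, R = cand$R,
                poreIsDark = poreIsDark),
    otsu = globalThreshold(image, "otsu", poreIsDark = poreIsDark),
    mean = globalThreshold(image, "mean", poreIsDark = poreIsDark),
    fixed = globalThreshold(image, "fixed", t = cand$t,
                            poreIsDark = poreIsDark),
    stop("unknown segmentation method: ", method))
  params <- cand[setdiff(names(cand), "method")]
  new("SegmentationResult", binary = binary, method = method,
      parameters = params, phaseNCC = NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default candidate set for automatic strategy selection
#'
#' @param windowSize local window for Niblack/Sauvola.
#' @return list of candidate parameter lists for [selectSegmentation()].
#' @export
defaultCandidates <- function(windowSize = 25) {
  list(list(method = "otsu"),
       list(method = "niblack", windowSize = windowSize, k = -0.2),
       list(method = "sauvola", windowSize = windowSize, k = 0.2))
}

#' Select the best segmentation by Fourier-phase NCC
#'
#' Runs every candidate strategy on the image, scores each binarization with
#' [fourierPhaseNCC()] against the grayscale original, and returns the
#' highest-scoring one. Ties are broken by a fixed method order
#' (otsu < niblack < sauvola < mean < fixed): the later method in that order
#' wins an exact tie. Candidates whose scoring fails (degenerate output) are
#' recorded and skipped; if all fail, an error lists every failure.
#'
#' @param image 2D grayscale matrix.
#' @param candidates nonempty list of candidate parameter lists, each with a
#'   `method` element plus method-specific parameters; see
#'   [defaultCandidates()].
#' @param poreIsDark polarity flag passed to each method.
#' @return a [SegmentationResult-class] with `phaseNCC` filled in.
#' @export
selectSegmentation <- function(image, candidates = defaultCandidates(),
                               poreIsDark = TRUE) {
  if (length(candidates) == 0L) stop("candidate set must be nonempty")
  tieOrder <- c(otsu = 1, niblack = 2, sauvola = 3, mean = 4, fixed = 5)
  results <- list(); scores <- numeric(0); failures <- character(0)
  for (cand in candidates) {
    res <- tryCatch({
      sr <- runCandidate(image, cand, poreIsDark)
      sr@phaseNCC <- scoreSegmentation(image, sr@binary, poreIsDark)
      sr
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(cand$method, ": ", conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
      scores <- c(scores, res@phaseNCC)
    }
  }
  if (length(results) == 0L)
    stop("all candidates degenerate: ", paste(failures, collapse = "; "))
  ord <- tieOrder[vapply(results, function(r) r@method, "")]
  best <- order(scores, ord, decreasing = TRUE)[1]
  results[[best]]
}

#' Segment a grayscale slice stack
#'
#' Applies one strategy — or automatic per-slice selection — to every slice of
#' a grayscale stack, returning the binary slices plus a per-slice log of the
#' method used and its phase-NCC score.
#'
#' @param slices list of 2D grayscale matrices sharing dimensions.
#' @param method `"auto"` (phase-NCC selection over `candidates`) or one of
#'   the method names accepted by [selectSegmentation()] candidates.
#' @param candidates candidate set for `method = "auto"`.
#' @param poreIsDark polarity flag.
#' @param ... parameters forwarded to the single named method.
#' @return list with `binaries` (list of 0/1 matrices) and `log` (data.frame
#'   with columns slice, method, score).
#' @export
segmentStack <- function(slices, method = "auto",
                         candidates = defaultCandidates(),
                         poreIsDark = TRUE, ...) {
  stopifnot(length(slices) >= 1L)
  out <- vector("list", length(slices))
  log <- data.frame(slice = seq_along(slices), method = NA_character_,
                    score = NA_real_)
  for (i in seq_along(slices)) {
    if (method == "auto") {
      sr <- selectSegmentation(slices[[i]], candidates, poreIsDark)
    } else {
      sr <- runCandidate(slices[[i]], c(list(method = method), list(...)),
                         poreIsDark)
      sr@phaseNCC <- tryCatch(
        scoreSegmentation(slices[[i]], sr@binary, poreIsDark),
        error = function(e) NA_real_)
    }
    out[[i]] <- sr@binary
    log$method[i] <- sr@method
    log$score[i] <- sr@phaseNCC
  }
  list(binaries = out, log = log)
}
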