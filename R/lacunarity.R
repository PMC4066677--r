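#' @include AllClasses.R utils.R
NULL

# Gliding-box pore counts for one box size, via the summed-volume table.
# P may be precomputed (curve construction) to amortize the O(V) pass.
glidingCounts <- function(volume, r, P = NULL) {
  d <- dims(volume)
  r <- as.integer(r)
  if (r < 1L || r > min(d))
    stop("box size r = ", r, " outside [1, ", min(d), "]")
  if (is.null(P)) P <- summedVolume(voxels(volume))
  boxCountsFromTable(P, d, r)
}

#' Gliding-box occupancy distribution P(S, r)
#'
#' Enumerates every axis-aligned cubic box of side `r` fully inside the
#' volume at unit stride along all three axes — N(r) = prod(dims - r + 1)
#' positions — counts the pore voxels in each, and converts the occupancy
#' frequencies n(S, r) to probabilities P(S, r) = n(S, r) / N(r).
#'
#' @param volume a [BinaryVolume-class].
#' @param r box side in voxels, 1 <= r <= min(dims).
#' @return a [BoxOccupancyDistribution-class].
#' @examples
#' v <- bernoulliVolume(c(8, 8, 8), 0.5, seed = 1)
#' boxOccupancyDistribution(v, r = 2)
#' @export
boxOccupancyDistribution <- function(volume, r) {
  cnt <- glidingCounts(volume, r)
  N <- length(cnt)
  tab <- table(cnt)
  S <- as.numeric(names(tab))
  n <- as.numeric(tab)
  new("BoxOccupancyDistribution", r = as.integer(r),
      counts = data.frame(S = S, n = n, p = n / N), totalBoxes = N)
}

# Occupancy moments for one box size from raw counts.
countMoments <- function(cnt) {
  N <- length(cnt)
  mu1 <- sum(cnt) / N
  mu2 <- sum(cnt * cnt) / N
  varS <- mu2 - mu1 * mu1
  list(N = N, mu1 = mu1, mu2 = mu2, meanS = mu1, varS = max(varS, 0))
}

#' Gliding-box lacunarity LAC(r)
#'
#' LAC = mu2 / mu1^2 = 1 + var(S) / mean(S)^2, where mean and population
#' variance are taken over the pore counts S of all N(r) gliding-box
#' positions. LAC >= 1 always; LAC = 1 when every box holds the same count.
#' At r = 1 the identity LAC = 1/n holds for any spatial arrangement with
#' porosity n, and at r equal to the side of a cubic volume a single box
#' exists so LAC = 1.
#'
#' @inheritParams boxOccupancyDistribution
#' @return the lacunarity value (numeric scalar >= 1).
#' @examples
#' v <- bernoulliVolume(c(16, 16, 16), 0.7, seed = 3)
#' glidingBoxLacunarity(v, 1)     # exactly 1 / porosity(v)@n
#' glidingBoxLacunarity(v, 16)    # exactly 1 (single box)
#' @export
glidingBoxLacunarity <- function(volume, r) {
  cnt <- glidingCounts(volume, r)
  m <- countMoments(cnt)
  if (m$mu1 == 0)
    stop("lacunarity undefined for empty pore phase (no pore voxels)")
  m$mu2 / (m$mu1 * m$mu1)
}

#' Relative lacunarity function RLF
#'
#' RLF = -ln(LAC) / ln(n): lacunarity normalized by porosity so structures
#' of different void fraction can be compared. RLF >= 0, equal to 0 iff
#' LAC = 1, and identically 1 at r = 1 for any 0 < n < 1 (since
#' LAC(1) = 1/n).
#'
#' @param lac lacunarity value(s) >= 1.
#' @param n porosity strictly inside (0, 1).
#' @return RLF value(s).
#' @export
relativeLacunarity <- function(lac, n) {
  if (length(n) != 1L || !is.finite(n) || n <= 0 || n >= 1)
    stop("porosity n must lie strictly inside (0, 1) for RLF")
  if (any(lac < 1 - 1e-12, na.rm = TRUE))
    stop("inconsistent input: lacunarity below 1")
  -log(pmax(lac, 1)) / log(n)
}

#' Lacunarity curve over a range of box sizes
#'
#' Builds one record per box size with the occupancy moments, LAC, the
#' natural-log coordinates (ln r, ln LAC) of the customary log-log plots, and
#' RLF computed against the volume porosity. Default box sizes are every
#' integer from 1 to min(64, smallest dimension). Endpoints obey: maximum
#' LAC at r = 1 (where LAC = 1/n), and LAC = 1 at r equal to the side of a
#' cubic volume. The RLF normalization is undefined at porosity 0 or 1; for
#' the uniform all-pore volume (LAC identically 1) the limit convention
#' RLF = 0 is used, otherwise RLF is NA. Per-r computation failures are
#' recorded in the `failures` attribute of the records, never silently
#' dropped.
#'
#' @param volume a [BinaryVolume-class].
#' @param rValues sorted unique box sides, all <= min(dims); NULL for the
#'   default grid.
#' @param porosity porosity to use for RLF; default (`NULL`) computes it from
#'   the volume.
#' @return a [LacunarityCurve-class].
#' @examples
#' v <- bernoulliVolume(c(32, 32, 32), 0.7, seed = 1)
#' cv <- lacunarityCurve(v, c(1, 2, 4, 8, 16, 32))
#' as.data.frame(cv)
#' @export
lacunarityCurve <- function(volume, rValues = NULL, porosity = NULL) {
  d <- dims(volume)
  if (is.null(rValues)) rValues <- seq_len(min(64L, min(d)))
  rValues <- as.integer(rValues)
  if (is.unsorted(rValues, strictly = TRUE))
    stop("rValues must be sorted and unique")
  if (any(rValues < 1L) || any(rValues > min(d)))
    stop("rValues must lie in [1, ", min(d), "]")
  if (is.null(porosity)) porosity <- porosity(volume)@n
  P <- summedVolume(voxels(volume))
  rows <- vector("list", length(rValues))
  failures <- character(0)
  for (i in seq_along(rValues)) {
    r <- rValues[i]
    row <- tryCatch({
      cnt <- boxCountsFromTable(P, d, r)
      m <- countMoments(cnt)
      if (m$mu1 == 0)
        stop("lacunarity undefined for empty pore phase")
      lac <- m$mu2 / (m$mu1 * m$mu1)
      data.frame(r = r, N = m$N, meanS = m$meanS, varS = m$varS,
                 mu1 = m$mu1, mu2 = m$mu2, lac = lac, lnR = log(r),
                 lnLac = log(lac),
                 rlf = if (porosity > 0 && porosity < 1)
                   relativeLacunarity(lac, porosity)
                 else if (porosity == 1 && abs(lac - 1) < 1e-12)
                   0  # all-pore limit: LAC = 1 for every r, RLF -> 0
                 else NA_real_)
    }, error = function(e) {
      failures <<- c(failures, paste0("r=", r, ": ", conditionMessage(e)))
      data.frame(r = r, N = NA_real_, meanS = NA_real_, varS = NA_real_,
                 mu1 = NA_real_, mu2 = NA_real_, lac = NA_real_,
                 lnR = log(r), lnLac = NA_real_, rlf = NA_real_)
    })
    rows[[i]] <- row
  }
  records <- do.call(rbind, rows)
  attr(records, "failures") <- failures
  new("LacunarityCurve", records = records, porosity = porosity,
      dims = as.integer(d), voxelSize = voxelSize(volume))
}

#' Randomness scale of a lacunarity curve
#'
#' The box size beyond which box-to-box occupancy variance has essentially
#' vanished: the smallest r with LAC(r) <= 1 + epsilon. If no box size on
#' the curve qualifies, `rStar` is NA and `beyondRange` is TRUE. As a
#' secondary diagnostic the box size of the largest absolute change in slope
#' of ln LAC versus ln r (the knee of the log-log curve) is reported. On a
#' non-monotone curve both diagnostics are still computed and a warning
#' notes the disagreement.
#'
#' @param curve a [LacunarityCurve-class] with at least 3 records.
#' @param epsilon tolerance above 1 defining "close to 1"; default 0.05.
#' @return list with `rStar`, `beyondRange`, `slopeChangeR`, `epsilon`.
#' @export
randomnessScale <- function(curve, epsilon = 0.05) {
  stopifnot(is(curve, "LacunarityCurve"))
  rec <- curve@records[is.finite(curve@records$lac), ]
  if (nrow(rec) < 3L) stop("curve must have at least 3 defined records")
  if (epsilon <= 0) stop("epsilon must be > 0")
  hit <- which(rec$lac <= 1 + epsilon)
  rStar <- if (length(hit)) rec$r[hit[1]] else NA_integer_
  slope <- diff(rec$lnLac) / diff(rec$lnR)
  slopeChangeR <- if (length(slope) >= 2L)
    rec$r[which.max(abs(diff(slope))) + 1L] else NA_integer_
  if (any(diff(rec$lac) > 1e-9) && !is.na(rStar) &&
      any(rec$lac[rec$r > rStar] > 1 + epsilon))
    warning("non-monotone lacunarity curve: LAC exceeds 1 + epsilon again ",
            "beyond rStar; diagnostics may disagree")
  list(rStar = rStar, beyondRange = is.na(rStar),
       slopeChangeR = slopeChangeR, epsilon = epsilon)
}

#' Brute-force gliding-box lacunarity (independent oracle)
#'
#' Literal triple-loop enumeration of every box position with naive voxel
#' counting and moment accumulation — no shared code with the optimized
#' summed-volume path. Intended for validation on small volumes
#' (<= 20^3 recommended).
#'
#' @inheritParams boxOccupancyDistribution
#' @return the lacunarity value.
#' @export
bruteForceLacunarity <- function(volume, r) {
  v <- voxels(volume)
  d <- dim(v)
  r <- as.integer(r)
  if (r < 1L || r > min(d))
    stop("box size r = ", r, " outside [1, ", min(d), "]")
  counts <- numeric((d[1] - r + 1) * (d[2] - r + 1) * (d[3] - r + 1))
  b <- 0L
  for (k in 1:(d[3] - r + 1)) {
    for (j in 1:(d[2] - r + 1)) {
      for (i in 1:(d[1] - r + 1)) {
        b <- b + 1L
        counts[b] <- sum(v[i:(i + r - 1L), j:(j + r - 1L), k:(k + r - 1L)])
      }
    }
  }
  m <- mean(counts)
  if (m == 0)
    stop("lacunarity undefined for empty pore phase (no pore voxels)")
  va <- mean((counts - m)^2)
  1 + va / (m * m)
}
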