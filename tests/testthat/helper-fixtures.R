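# Shared fixtures and independent mini-oracles used across test files.

# Voxel-agreement fraction between a binary image/volume and its truth.
agreement <- function(binary, truth) mean(binary == truth)

# A small foam slab stack rendered to grayscale, cached per session.
foamFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- syntheticSpec(c(96, 96, 8), targetPorosity = 0.7,
                          poreRadiusMean = 5, poreRadiusSd = 1, seed = 21)
      cache <<- foamVolume(sp)
    }
    cache
  }
})

# Independent brute-force Pearson correlation of DFT phase arrays (direct
# double-loop DFT, DC excluded). Only for tiny images. Uses the same
# degenerate-coefficient conventions as the implementation: zero
# coefficients take phase 0, real ones 0 or pi by the sign of Re.
brutePhaseNCC <- function(a, b) {
  phase <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    Z <- matrix(0 + 0i, nr, nc)
    for (u in 0:(nr - 1)) for (v in 0:(nc - 1)) {
      s <- 0 + 0i
      for (x in 0:(nr - 1)) for (y in 0:(nc - 1))
        s <- s + m[x + 1, y + 1] * exp(-2i * pi * (u * x / nr + v * y / nc))
      Z[u + 1, v + 1] <- s
    }
    P <- Arg(Z)
    zeroish <- Mod(Z) <= 1e-9 * max(Mod(Z))
    P[zeroish] <- 0
    realish <- !zeroish & abs(Im(Z)) <= 1e-9 * Mod(Z)
    P[realish] <- ifelse(Re(Z)[realish] >= 0, 0, pi)
    P
  }
  pa <- phase(a)[-1]; pb <- phase(b)[-1]
  sum((pa - mean(pa)) * (pb - mean(pb))) /
    sqrt(sum((pa - mean(pa))^2) * sum((pb - mean(pb))^2))
}

# Stack binary volumes along z into one volume (for heterogeneous fixtures).
stackAlongZ <- function(volumes) {
  voxList <- lapply(volumes, voxels)
  d <- dim(voxList[[1]])
  nz <- sum(vapply(voxList, function(v) dim(v)[3], 1L))
  out <- array(0L, c(d[1], d[2], nz))
  at <- 1L
  for (v in voxList) {
    out[, , at:(at + dim(v)[3] - 1L)] <- v
    at <- at + dim(v)[3]
  }
  BinaryVolume(out)
}
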