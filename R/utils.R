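# Internal numerics shared across modules.

# 3D cumulative sum along all three axes (summed-volume table core).
csum3 <- function(a) {
  a <- apply(a, c(2, 3), cumsum)
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
}

# Zero-padded summed-volume table: P has dim(a)+1, P[i+1,j+1,k+1] = sum of
# a[1:i,1:j,1:k]. Counts stay exact in doubles up to 2^53 (far beyond 256^3).
summedVolume <- function(a) {
  d <- dim(a)
  P <- array(0, d + 1L)
  P[-1, -1, -1] <- csum3(a)
  P
}

# Pore counts of every axis-aligned r-box fully inside the volume, unit
# stride, from a precomputed summed-volume table. Returns a 3D array of
# dimensions (d - r + 1).
boxCountsFromTable <- function(P, d, r) {
  i2 <- seq.int(r + 1L, d[1] + 1L); i1 <- i2 - r
  j2 <- seq.int(r + 1L, d[2] + 1L); j1 <- j2 - r
  k2 <- seq.int(r + 1L, d[3] + 1L); k1 <- k2 - r
  P[i2, j2, k2, drop = FALSE] - P[i1, j2, k2, drop = FALSE] -
    P[i2, j1, k2, drop = FALSE] - P[i2, j2, k1, drop = FALSE] +
    P[i1, j1, k2, drop = FALSE] + P[i1, j2, k1, drop = FALSE] +
    P[i2, j1, k1, drop = FALSE] - P[i1, j1, k1, drop = FALSE]
}

# Run code under an explicit seed without touching the global RNG stream.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Reflection (symmetric, edge repeated) index vector for padding a length-n
# axis by h on both sides.
reflectIndex <- function(n, h) {
  if (h == 0L) return(seq_len(n))
  if (h > n) stop("padding exceeds image extent")
  c(seq.int(h, 1L), seq_len(n), seq.int(n, n - h + 1L))
}

# Local mean and sd over a w x w window (w odd) with reflect padding,
# via integral images of x and x^2.
localMeanSd <- function(img, w) {
  if (w %% 2L == 0L || w < 3L) stop("window size must be odd and >= 3")
  nr <- nrow(img); nc <- ncol(img)
  if (w > nr || w > nc) stop("window larger than image")
  h <- (w - 1L) %/% 2L
  p <- img[reflectIndex(nr, h), reflectIndex(nc, h)]
  ii <- function(m) {
    m <- apply(m, 2, cumsum)
    m <- t(apply(m, 1, cumsum))
    rbind(0, cbind(0, m))
  }
  S1 <- ii(p); S2 <- ii(p * p)
  winsum <- function(S) {
    i2 <- seq.int(w + 1L, nr + w); i1 <- i2 - w
    j2 <- seq.int(w + 1L, nc + w); j1 <- j2 - w
    S[i2, j2] - S[i1, j2] - S[i2, j1] + S[i1, j1]
  }
  nwin <- as.numeric(w)^2
  m <- winsum(S1) / nwin
  v <- pmax(winsum(S2) / nwin - m * m, 0)
  list(mean = m, sd = sqrt(v))
}

# Internal: coerce an axis name to its array margin index.
axisMargin <- function(axis) {
  match(axis, c("x", "y", "z"))
}
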