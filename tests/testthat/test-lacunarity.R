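test_that("box occupancy distribution matches definitional cases and brute enumeration", {
  v <- bernoulliVolume(c(4, 4, 4), 0.5, seed = 12)
  n <- porosity(v)@n

  # r = 1: N = total voxels, P(1,1) = n, P(0,1) = 1 - n
  d1 <- boxOccupancyDistribution(v, 1)
  expect_equal(d1@totalBoxes, 64)
  expect_equal(d1@counts$p[d1@counts$S == 1], n)
  expect_equal(d1@counts$p[d1@counts$S == 0], 1 - n)

  # r = min(dims): one box, point mass at the total pore count
  d4 <- boxOccupancyDistribution(v, 4)
  expect_equal(d4@totalBoxes, 1)
  expect_equal(d4@counts$S, sum(voxels(v)))
  expect_equal(d4@counts$p, 1)

  # r = 2: exhaustive 27-box enumeration, independent loop
  vox <- voxels(v)
  cnt <- c()
  for (k in 1:3) for (j in 1:3) for (i in 1:3)
    cnt <- c(cnt, sum(vox[i:(i + 1), j:(j + 1), k:(k + 1)]))
  d2 <- boxOccupancyDistribution(v, 2)
  expect_equal(d2@totalBoxes, 27)
  tab <- table(cnt)
  expect_equal(d2@counts$S, as.numeric(names(tab)))
  expect_equal(d2@counts$n, as.numeric(tab))
  expect_equal(sum(d2@counts$p), 1, tolerance = 1e-12)

  expect_error(boxOccupancyDistribution(v, 5), "outside")
})

test_that("lacunarity endpoint identities hold exactly", {
  v <- bernoulliVolume(c(16, 16, 16), 0.7, seed = 3)
  n <- porosity(v)@n
  expect_equal(glidingBoxLacunarity(v, 1), 1 / n, tolerance = 1e-13)
  expect_equal(glidingBoxLacunarity(v, 16), 1)

  allPore <- BinaryVolume(array(1L, c(8, 8, 8)))
  for (r in c(1, 3, 8)) expect_equal(glidingBoxLacunarity(allPore, r), 1)

  allSolid <- BinaryVolume(array(0L, c(8, 8, 8)))
  expect_error(glidingBoxLacunarity(allSolid, 2), "empty pore phase")
})

test_that("a regular lattice has LAC exactly 1 at multiples of its period", {
  v <- regularLattice(c(24, 24, 24), period = 4, poresPerPeriod = 13)
  for (r in c(4, 8, 12, 24))
    expect_equal(glidingBoxLacunarity(v, r), 1)
  # off-multiple box sizes may straddle period boundaries: only >= 1 is owed
  expect_gte(glidingBoxLacunarity(v, 3), 1)
})

test_that("relative lacunarity follows -ln(LAC)/ln(n)", {
  expect_equal(relativeLacunarity(1, 0.5), 0)
  # r = 1 identity: LAC = 1/n gives RLF = 1 for every porosity level
  for (n in c(0.81, 0.70, 0.68))
    expect_equal(relativeLacunarity(1 / n, n), 1)
  expect_equal(relativeLacunarity(1 / 0.5^2, 0.5), 2)
  expect_error(relativeLacunarity(1.5, 1), "strictly inside")
  expect_error(relativeLacunarity(1.5, 0), "strictly inside")
  expect_error(relativeLacunarity(0.8, 0.5), "inconsistent")
})

test_that("optimized lacunarity equals the brute-force oracle (property sweep)", {
  cases <- expand.grid(seed = 1:8, p = c(0.2, 0.5, 0.8))
  for (i in seq_len(nrow(cases))) {
    dim1 <- 8L + (cases$seed[i] %% 5L)
    v <- bernoulliVolume(rep(dim1, 3), cases$p[i], seed = 100 + i)
    for (r in c(1, 2, 3, 5))
      expect_equal(glidingBoxLacunarity(v, r), bruteForceLacunarity(v, r),
                   tolerance = 1e-13)
  }
  # non-cubic volume too
  v <- bernoulliVolume(c(9, 12, 7), 0.5, seed = 77)
  expect_equal(glidingBoxLacunarity(v, 3), bruteForceLacunarity(v, 3),
               tolerance = 1e-13)
  # N(r) = prod(dims - r + 1) for non-cubic volumes
  expect_equal(boxOccupancyDistribution(v, 3)@totalBoxes, 7 * 10 * 5)
})

test_that("curves carry consistent records and obey the endpoint claims", {
  v <- bernoulliVolume(c(32, 32, 32), 0.7, seed = 2)
  cv <- lacunarityCurve(v, c(1, 2, 4, 8, 16, 32))
  rec <- as.data.frame(cv)
  expect_equal(rec$lac, 1 + rec$varS / rec$meanS^2, tolerance = 1e-9)
  expect_equal(rec$lac, rec$mu2 / rec$mu1^2, tolerance = 1e-9)
  expect_equal(rec$lnLac, log(rec$lac))
  expect_equal(rec$rlf, -log(rec$lac) / log(cv@porosity))
  expect_equal(which.max(rec$lac), 1L)          # max LAC at r = 1
  expect_equal(rec$lac[rec$r == 32], 1)         # single box at full side
  expect_equal(rec$rlf[1], 1)                   # RLF(1) = 1
  expect_true(all(rec$lac >= 1))

  # i.i.d. closed form within 10% for r <= 8
  cf <- 1 + (1 - 0.7) / (0.7 * rec$r^3)
  expect_lt(max(abs(rec$lac[rec$r <= 8] / cf[rec$r <= 8] - 1)), 0.1)

  # all-pore cube: LAC identically 1, RLF identically 0 (limit convention)
  ap <- lacunarityCurve(BinaryVolume(array(1L, c(8, 8, 8))))
  expect_true(all(as.data.frame(ap)$lac == 1))
  expect_true(all(as.data.frame(ap)$rlf == 0))

  expect_error(lacunarityCurve(v, c(2, 1)), "sorted")
  expect_error(lacunarityCurve(v, c(1, 64)), "rValues")
})

test_that("curves match the brute-force oracle record for record", {
  sp <- syntheticSpec(c(16, 16, 16), targetPorosity = 0.7,
                      poreRadiusMean = 2.5, poreRadiusSd = 0.5, seed = 14)
  v <- foamVolume(sp)
  rs <- c(1, 2, 3, 5, 8, 16)
  rec <- as.data.frame(lacunarityCurve(v, rs))
  for (i in seq_along(rs))
    expect_equal(rec$lac[i], bruteForceLacunarity(v, rs[i]),
                 tolerance = 1e-13)
})

test_that("randomness scale detects where LAC approaches 1", {
  # closed form: p = 0.7 gives LAC <= 1.01 first at r^3 >= 0.3/0.007 -> r = 4
  v <- bernoulliVolume(c(32, 32, 32), 0.7, seed = 2)
  cv <- lacunarityCurve(v, 1:16)
  rs <- randomnessScale(cv, epsilon = 0.01)
  expect_equal(rs$rStar, 4L)
  expect_false(rs$beyondRange)

  # all-pore volume: any epsilon -> smallest r on the curve
  ap <- lacunarityCurve(BinaryVolume(array(1L, c(8, 8, 8))), c(2, 4, 8))
  expect_equal(randomnessScale(ap, 0.05)$rStar, 2L)

  # clustered foam needs a larger box than Bernoulli at equal porosity
  sp <- syntheticSpec(c(48, 48, 48), targetPorosity = 0.7,
                      poreRadiusMean = 5, poreRadiusSd = 1, seed = 31)
  foam <- foamVolume(sp)
  bern <- bernoulliVolume(c(48, 48, 48), porosity(foam)@n, seed = 32)
  rs <- 1:24
  rF <- randomnessScale(lacunarityCurve(foam, rs), 0.05)$rStar
  rB <- randomnessScale(lacunarityCurve(bern, rs), 0.05)$rStar
  expect_gte(rF, rB)

  expect_error(randomnessScale(lacunarityCurve(v, c(1, 2)), 0.05),
               "at least 3")
})

test_that("matched porosity, fewer-but-larger pores give higher LAC at small r", {
  # one 8-voxel cubic pore vs eight scattered single-voxel pores
  big <- array(0L, c(12, 12, 12)); big[5:6, 5:6, 5:6] <- 1L
  scattered <- array(0L, c(12, 12, 12))
  scattered[cbind(c(2, 2, 10, 10, 5, 8, 3, 11),
                  c(2, 10, 2, 10, 6, 3, 8, 6),
                  c(2, 6, 9, 3, 11, 7, 4, 10))] <- 1L
  a <- BinaryVolume(big); b <- BinaryVolume(scattered)
  expect_equal(porosity(a)@n, porosity(b)@n)  # matched n = 8/1728
  for (r in 2:4)
    expect_gt(glidingBoxLacunarity(a, r), glidingBoxLacunarity(b, r))

  # paired seeded foams: larger mean pore radius -> higher LAC at small r
  mk <- function(rad, seed) {
    sp <- syntheticSpec(c(32, 32, 32), targetPorosity = 0.5,
                        poreRadiusMean = rad, poreRadiusSd = 0, seed = seed)
    foamVolume(sp)
  }
  large <- mk(6, 51); small <- mk(2, 52)
  nL <- porosity(large)@n; nS <- porosity(small)@n
  expect_lt(abs(nL - nS), 0.05)
  for (r in c(2, 4))
    expect_gt(glidingBoxLacunarity(large, r), glidingBoxLacunarity(small, r))
})
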