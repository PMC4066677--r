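test_that("regular lattice is exactly periodic with the requested porosity", {
  v <- regularLattice(c(8, 8, 8), period = 2, poresPerPeriod = 1)
  expect_equal(porosity(v)@n, 1 / 8)
  vox <- voxels(v)
  # every period-shifted copy equals the original pattern
  expect_identical(vox[1:2, 1:2, 1:2], vox[3:4, 5:6, 7:8])
  expect_identical(vox, vox[c(3:8, 1:2), , ])

  allPore <- regularLattice(c(4, 4, 4), period = 1, poresPerPeriod = 1)
  expect_equal(porosity(allPore)@n, 1)

  expect_error(regularLattice(c(9, 8, 8), period = 2, poresPerPeriod = 1),
               "divide")
  expect_error(regularLattice(c(8, 8, 8), period = 2, poresPerPeriod = 9),
               "poresPerPeriod")
})

test_that("Bernoulli volumes hit degenerate p exactly and p = 0.7 within 4 SE", {
  expect_equal(porosity(bernoulliVolume(c(8, 8, 8), 0, seed = 1))@n, 0)
  expect_equal(porosity(bernoulliVolume(c(8, 8, 8), 1, seed = 1))@n, 1)
  n <- porosity(bernoulliVolume(c(32, 32, 32), 0.7, seed = 4))@n
  se <- sqrt(0.7 * 0.3 / 32768)
  expect_lt(abs(n - 0.7), 4 * se)
})

test_that("generators are bit-reproducible and leave the global RNG untouched", {
  set.seed(999)
  before <- .Random.seed
  v1 <- bernoulliVolume(c(16, 16, 16), 0.5, seed = 7)
  expect_identical(.Random.seed, before)
  v2 <- bernoulliVolume(c(16, 16, 16), 0.5, seed = 7)
  expect_identical(voxels(v1), voxels(v2))

  sp <- syntheticSpec(c(24, 24, 24), targetPorosity = 0.7,
                      poreRadiusMean = 3, poreRadiusSd = 0.5, seed = 5)
  expect_identical(voxels(foamVolume(sp)), voxels(foamVolume(sp)))
})

test_that("foam reaches its target porosity and books it by direct count", {
  sp <- syntheticSpec(c(64, 64, 64), targetPorosity = 0.81,
                      poreRadiusMean = 7.5, poreRadiusSd = 1.5, seed = 11)
  v <- foamVolume(sp, voxelSize = 8.7)
  n <- porosity(v)@n
  expect_gte(n, 0.81)          # stop at first crossing
  expect_gte(n, 0.76); expect_lte(n, 0.86)
  expect_equal(v@provenance$realizedPorosity, sum(voxels(v)) / 64^3)

  expect_error(foamVolume(syntheticSpec(c(8, 8, 8), targetPorosity = 0.5,
                                        poreRadiusMean = 9, seed = 1)),
               "unreachable")
})

test_that("sphere voxelization matches a brute-force centre-in-sphere count", {
  # tiny target -> the foam stops after its very first sphere
  sp <- syntheticSpec(c(32, 32, 32), targetPorosity = 0.005,
                      poreRadiusMean = 4, poreRadiusSd = 0, seed = 9)
  v <- foamVolume(sp)
  s <- v@provenance$spheres
  expect_equal(nrow(s), 1L)
  expect_equal(unname(s[1, "radius"]), 4)
  g <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  inside <- (g$x - s[1, "cx"])^2 + (g$y - s[1, "cy"])^2 +
    (g$z - s[1, "cz"])^2 <= s[1, "radius"]^2
  expect_equal(sum(voxels(v)), sum(inside))
})

test_that("pore occlusion is the identity at 0, total at 1, and monotone", {
  v <- bernoulliVolume(c(12, 12, 12), 0.6, seed = 3)
  expect_identical(voxels(occludePores(v, 0, seed = 1)), voxels(v))
  expect_equal(porosity(occludePores(v, 1, seed = 1))@n, 0)

  # erosion mode removes the exact voxel budget
  half <- occludePores(v, 0.5, seed = 1)
  expect_equal(sum(voxels(half)),
               sum(voxels(v)) - round(0.5 * sum(voxels(v))))

  sp <- syntheticSpec(c(32, 32, 32), targetPorosity = 0.8,
                      poreRadiusMean = 4, poreRadiusSd = 1, seed = 6)
  foam <- foamVolume(sp)
  for (vol in list(v, foam)) {
    ns <- vapply(c(0, 0.2, 0.4, 0.7, 1),
                 function(f) porosity(occludePores(vol, f, seed = 5))@n, 0)
    expect_true(all(diff(ns) <= 0))
  }
  expect_equal(porosity(occludePores(foam, 1, seed = 2))@n, 0)
})

test_that("occluded foam removes whole pores, keeping survivors full-size", {
  sp <- syntheticSpec(c(32, 32, 32), targetPorosity = 0.8,
                      poreRadiusMean = 4, poreRadiusSd = 1, seed = 6)
  foam <- foamVolume(sp)
  occ <- occludePores(foam, 0.3, seed = 5)
  expect_identical(occ@provenance$occlusionMode, "pores")
  # occluded pore set is a strict subset of the parent pore set
  expect_true(all(voxels(occ) <= voxels(foam)))
  expect_lt(porosity(occ)@n, porosity(foam)@n)
})

test_that("grayscale rendering is two-valued without noise and recoverable with it", {
  v <- foamFixture()
  st <- renderGrayscaleStack(v, noiseSd = 0, illuminationGradient = 0)
  img <- st$slices[[1]]
  expect_setequal(unique(as.vector(img)), c(0.2, 0.8))
  # any sensible threshold recovers the volume exactly
  expect_equal(agreement(matrix(as.integer(img < 0.5), nrow(img)),
                         voxels(v)[, , 1]), 1)

  stn <- renderGrayscaleStack(v, noiseSd = 0.05, seed = 5)
  rec <- globalThreshold(stn$slices[[1]], "otsu")
  expect_gte(agreement(rec, voxels(v)[, , 1]), 0.99)

  # determinism of the noise draw
  a <- renderGrayscaleStack(v, noiseSd = 0.1, seed = 8)$slices[[2]]
  b <- renderGrayscaleStack(v, noiseSd = 0.1, seed = 8)$slices[[2]]
  expect_identical(a, b)
})
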