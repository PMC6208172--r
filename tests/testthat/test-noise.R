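# Pseudo-residual noise estimation and the automatic smoothing parameter.

test_that("pseudo-residuals vanish on constant volumes and match the
          closed form on an isolated spike", {
  expect_true(all(pseudoResiduals(constantVolume(42, 8)) == 0))

  u <- array(0, c(5, 5, 5))
  u[3, 3, 3] <- 7
  eps <- pseudoResiduals(Volume(u))
  # spike voxel: neighbours all zero -> sqrt(6/7) * 7
  expect_equal(eps[3, 3, 3], sqrt(6 / 7) * 7)
  # face neighbour of the spike: mean of its 6 neighbours is 7/6
  expect_equal(eps[2, 3, 3], sqrt(6 / 7) * (0 - 7 / 6))

  expect_error(pseudoResiduals(Volume(array(0, c(1, 4, 4)))), "too thin")
})

test_that("residual RMS recovers the AGWN standard deviation", {
  v <- addNoise(constantVolume(100, 32),
                noiseModel("gaussian", sigma = 5, seed = 5))
  expect_gt(sqrt(mean(pseudoResiduals(v)^2)), 4.5)
  expect_lt(sqrt(mean(pseudoResiduals(v)^2)), 5.5)
})

test_that("local noise map: grid geometry and degenerate inputs", {
  nm <- estimateNoiseLocal(constantVolume(7, 32), 16)
  expect_identical(gridShape(nm), c(2L, 2L, 2L))
  expect_true(all(noiseSigma(nm) == 0))

  # ceiling partition: 20^3 with blocks of 16 -> 2 blocks per axis,
  # edge blocks only 4 voxels deep
  nm20 <- estimateNoiseLocal(constantVolume(1, 20), 16)
  expect_identical(gridShape(nm20), c(2L, 2L, 2L))

  expect_error(estimateNoiseLocal(constantVolume(1, 8), 3), "block too small")
  expect_output(show(nm), "blocks")
})

test_that("block sigma-hat recovers spatially varying noise per half", {
  v <- twoSigmaVolume(64, c(2, 10), seed = 11)
  s <- noiseSigma(estimateNoiseLocal(v, 16))
  expect_gt(median(s[, , 1:2]), 1.8)
  expect_lt(median(s[, , 1:2]), 2.2)
  expect_gt(median(s[, , 3:4]), 9)
  expect_lt(median(s[, , 3:4]), 11)
})

test_that("sigma-hat estimate tightens as blocks grow", {
  v <- addNoise(constantVolume(100, 32),
                noiseModel("gaussian", sigma = 5, seed = 21))
  err <- function(bs) {
    abs(median(noiseSigma(estimateNoiseLocal(v, bs))) - 5)
  }
  expect_lt(err(32), err(8))
})

test_that("sigma-hat is shift invariant and scales linearly", {
  v <- addNoise(constantVolume(100, 16),
                noiseModel("gaussian", sigma = 3, seed = 2))
  s0 <- noiseSigma(estimateNoiseLocal(v, 8))
  shifted <- Volume(volData(v) + 55, gsvLevels = 256)
  scaled <- Volume(volData(v) * 4, gsvLevels = 256)
  expect_equal(noiseSigma(estimateNoiseLocal(shifted, 8)), s0)
  expect_equal(noiseSigma(estimateNoiseLocal(scaled, 8)), 4 * s0)
})

test_that("smoothing parameter follows the adaptive bandwidth rule", {
  # sigma-hat 0 -> the floor
  pol <- smoothingPolicy()
  expect_equal(smoothingParameter(0, 27, pol, 256), pol@hMin)
  # direct evaluation: beta 1, sigma 10, |N| 27
  expect_equal(smoothingParameter(10, 27, pol, 256), sqrt(2 * 100 * 27))
  # linear in sigma away from the floor
  expect_equal(smoothingParameter(20, 27, pol, 256),
               2 * smoothingParameter(10, 27, pol, 256))
  # monotone in sigma, beta and patch size
  expect_true(all(diff(smoothingParameter(c(1, 2, 5), 27, pol, 256)) > 0))
  expect_gt(smoothingParameter(5, 27, smoothingPolicy(beta = 2), 256),
            smoothingParameter(5, 27, pol, 256))
  expect_gt(smoothingParameter(5, 125, pol, 256),
            smoothingParameter(5, 27, pol, 256))
  # the floor scales with the volume's gsv levels
  expect_equal(smoothingParameter(0, 27, pol, 65536), pol@hMin * 256)
  expect_error(smoothingParameter(-1, 27), "sigmaHat")
})

test_that("noise map exports to netCDF", {
  nm <- estimateNoiseLocal(twoSigmaVolume(32, c(2, 10), seed = 3), 16)
  p <- tempfile(fileext = ".nc")
  writeNoiseMap(nm, p)
  back <- readNetcdf(p, "sigma")
  expect_equal(volData(back), noiseSigma(nm))
})
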