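# The denoiser core: brute-force SSD oracle, MAF-accelerated SSD, weights
# and the full weighted average.

test_that("ssdNaive computes patch SSD with mirror padding", {
  v <- constantVolume(9, 8)
  expect_equal(as.numeric(ssdNaive(v, c(4, 4, 4), c(0, 0, 0), 1)), 0)
  expect_equal(as.numeric(ssdNaive(v, c(4, 4, 4), c(2, -1, 3), 1)), 0)

  expect_equal(attr(ssdNaive(v, c(4, 4, 4), c(1, 1, 1), 1), "diffOps"), 27)

  # patches [1,2,3] vs [1,2,4] along x (degenerate 1D fixture): the only
  # contribution is (3-4)^2 = 1 from the differing voxel
  v1d <- Volume(array(c(1, 2, 3, 1, 2, 4), c(1, 1, 6)))
  expect_equal(as.numeric(ssdNaive(v1d, c(1, 1, 2), c(0, 0, 3), 1)), 1)
})

test_that("MAF SSD map equals the brute-force oracle exactly on integers", {
  v <- randomIntVolume(7, 50, seed = 4)
  p <- nlmParams(patchRadius = 1, searchRadius = 2, blockSize = 4)
  m <- ssdMapMAF(v, p)
  for (center in list(c(1, 1, 1), c(4, 4, 4), c(7, 2, 5), c(2, 7, 1))) {
    for (off in list(c(0, 0, 0), c(2, -2, 1), c(-1, 0, 2), c(2, 2, 2))) {
      expect_identical(
        m[off[1] + 3, off[2] + 3, off[3] + 3,
          center[1], center[2], center[3]],
        as.numeric(ssdNaive(v, center, off, 1))
      )
    }
  }
})

test_that("MAF SSD map tracks the oracle within 1e-6 relative on floats", {
  set.seed(8)
  v <- Volume(array(rnorm(7^3, 100, 25), c(7, 7, 7)))
  p <- nlmParams(patchRadius = 1, searchRadius = 2, blockSize = 4)
  m <- ssdMapMAF(v, p)
  for (center in list(c(1, 3, 7), c(4, 4, 4), c(6, 2, 5))) {
    for (off in list(c(1, 0, -2), c(-2, 2, 2), c(0, 0, 2))) {
      expected <- as.numeric(ssdNaive(v, center, off, 1))
      got <- m[off[1] + 3, off[2] + 3, off[3] + 3,
               center[1], center[2], center[3]]
      expect_lt(abs(got - expected), 1e-6 * max(expected, 1))
    }
  }
})

test_that("SSD structures satisfy their invariants", {
  v <- randomIntVolume(7)
  p <- nlmParams(patchRadius = 1, searchRadius = 2, blockSize = 4)
  f <- ssdField(v, c(4, 4, 4), p)
  expect_identical(dim(f@values), c(5L, 5L, 5L))
  expect_true(all(f@values >= 0))
  expect_equal(f@values[3, 3, 3], 0) # zero offset
  m <- ssdMapMAF(constantVolume(3, 6), nlmParams(searchRadius = 2,
                                                 blockSize = 4))
  expect_true(all(m == 0))
})

test_that("nlm weights follow exp(-(ssd/h^2)^p)", {
  expect_equal(nlmWeight(0, 5, 1), 1)
  expect_equal(nlmWeight(0, 5, 7), 1)
  expect_equal(nlmWeight(25, 5, 1), exp(-1))
  expect_equal(nlmWeight(25, 5, 2), exp(-1))
  expect_equal(nlmWeight(50, 5, 2), exp(-4))
  expect_error(nlmWeight(1, 0), "h must be")
  expect_error(nlmWeight(1, 1, -1), "shapeP")
})

test_that("denoising a constant volume is an exact fixed point", {
  v <- constantVolume(100, 16)
  out <- denoise(v, nlmParams(searchRadius = 3, blockSize = 8))
  expect_identical(volData(out), volData(v))
  expect_equal(volSpacing(out), volSpacing(v))
  expect_equal(gsvLevels(out), gsvLevels(v))
})

test_that("output voxels stay within the input intensity range", {
  v <- addNoise(stepPhantom(16), noiseModel("gaussian", 10, seed = 9))
  out <- denoise(v, nlmParams(searchRadius = 3, blockSize = 8))
  expect_gte(min(volData(out)), min(volData(v)))
  expect_lte(max(volData(out)), max(volData(v)))
})

test_that("denoising reduces noise on constant + AGWN", {
  v <- addNoise(constantVolume(100, 24), noiseModel("gaussian", 8, seed = 3))
  out <- denoise(v, nlmParams(searchRadius = 3, blockSize = 8))
  expect_lt(sd(volData(out)), sd(volData(v)))
})

test_that("denoise rejects volumes thinner than the patch", {
  expect_error(denoise(Volume(array(0, c(2, 8, 8))),
                       nlmParams(searchRadius = 2, blockSize = 4)),
               "too small")
})

test_that("single-slice volumes run in degenerate 2D mode", {
  set.seed(10)
  v <- Volume(array(rnorm(32 * 32, 100, 5), c(1, 32, 32)), gsvLevels = 256)
  out <- denoise(v, nlmParams(searchRadius = 3, blockSize = 8))
  expect_identical(dim(out), dim(v))
  expect_lt(sd(volData(out)), sd(volData(v)))
})

test_that("instrumented MAF op count matches the analytic model", {
  for (m in c(3L, 5L)) {
    for (N in c(10L, 100L)) {
      pr <- (m - 1L) %/% 2L
      set.seed(m + N)
      v <- Volume(array(sample(0:9, m * m * N, TRUE), c(m, m, N)))
      r <- mafRowSSD(v, (m + 1) %/% 2, (m + 1) %/% 2, c(0, 1, 1), pr)
      expect_identical(r$diffOps, countDifferenceOps(m, N, "maf"))
      naiveOps <- sum(vapply(seq_len(N), function(x) {
        attr(ssdNaive(v, c((m + 1) %/% 2, (m + 1) %/% 2, x), c(0, 1, 1),
                      pr), "diffOps")
      }, numeric(1)))
      expect_identical(naiveOps, countDifferenceOps(m, N, "naive"))
      # and the values agree with the oracle
      expect_equal(r$ssd[3], as.numeric(
        ssdNaive(v, c((m + 1) %/% 2, (m + 1) %/% 2, 3), c(0, 1, 1), pr)
      ))
    }
  }
})

test_that("zero padding is honoured as an alternative boundary", {
  v <- randomIntVolume(5, 9, seed = 6)
  pZ <- nlmParams(searchRadius = 2, blockSize = 4, boundary = "zero")
  m <- ssdMapMAF(v, pZ)
  expect_identical(
    m[5, 3, 3, 1, 3, 3],
    as.numeric(ssdNaive(v, c(1, 3, 3), c(2, 0, 0), 1, boundary = "zero"))
  )
})
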