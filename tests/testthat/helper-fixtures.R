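# Fixtures are generated in code; nothing is read from disk.

# the standard two-intensity phantom: 50/150 step along x, 8-bit scale
stepPhantom <- function(n = 32L, lo = 50, hi = 150) {
  generatePhantom(phantomSpec(
    shape = c(n, n, n), background = lo,
    shapes = list(boxShape(c(1, 1, n / 2 + 1), c(n, n, n / 2), hi)),
    gsvLevels = 256
  ))
}

# constant volume with spatially varying noise: sigma[1] on the low-x
# half, sigma[2] on the high-x half
twoSigmaVolume <- function(n = 64L, sigma = c(2, 10), level = 100,
                           seed = 11L) {
  set.seed(seed)
  sig <- array(sigma[2], c(n, n, n))
  sig[, , seq_len(n / 2)] <- sigma[1]
  Volume(array(level, c(n, n, n)) + array(rnorm(n^3), c(n, n, n)) * sig,
         gsvLevels = 256, provenance = "two-sigma fixture")
}

constantVolume <- function(value = 100, n = 16L, gsv = 256) {
  Volume(array(value, c(n, n, n)), gsvLevels = gsv)
}

randomIntVolume <- function(n = 7L, maxval = 50L, seed = 4L) {
  set.seed(seed)
  Volume(array(sample(0:maxval, n^3, replace = TRUE), c(n, n, n)),
         gsvLevels = 256)
}

flipVol <- function(volume, axis) {
  u <- volData(volume)
  idx <- rev(seq_len(dim(u)[axis]))
  u <- switch(axis, u[idx, , , drop = FALSE], u[, idx, , drop = FALSE],
              u[, , idx, drop = FALSE])
  Volume(u, volSpacing(volume), gsvLevels(volume), provenance(volume))
}
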