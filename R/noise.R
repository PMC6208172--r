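#' Smoothing policy constructor
#'
#' Defaults give the classical Gaussian NLM kernel (`shapeP = 1`) with the
#' Coupé-style bandwidth \eqn{h = \sqrt{2\beta\hat\sigma^2 |N|}} at
#' `beta = 1`, floored at `hMin`. The floor is stated at `gsvRef = 256`
#' intensity levels and rescales linearly with the actual gsv level count
#' of the volume being denoised, so an 8-bit scene and its 16-bit
#' 256x-stretched recoding denoise identically (after the stretch).
#'
#' @param beta dimensionless bandwidth multiplier, > 0.
#' @param gsvRef reference intensity-level count for `hMin`.
#' @param shapeP kernel-shape exponent, > 0; 1 = Gaussian kernel.
#' @param hMin smoothing-parameter floor (intensity units at `gsvRef`
#'   levels). Default `1e-6 * gsvRef`: negligible against any real noise
#'   level, but keeps weights defined in noise-free blocks, where NLM then
#'   averages only exactly-identical patches.
#' @return a [SmoothingPolicy-class] object.
#' @export
smoothingPolicy <- function(beta = 1, gsvRef = 256, shapeP = 1,
                            hMin = 1e-6 * gsvRef) {
  new("SmoothingPolicy", beta = as.numeric(beta), gsvRef = as.numeric(gsvRef),
      shapeP = as.numeric(shapeP), hMin = as.numeric(hMin))
}

#' Pseudo-residuals of a volume
#'
#' The noise field is exposed by removing local structure: for every voxel,
#' \eqn{\epsilon_i = \sqrt{6/7}\,(u_i - \bar u_{6})} where \eqn{\bar u_6}
#' is the mean of the six face neighbours (mirror-padded at the boundary).
#' For i.i.d. additive Gaussian noise on a locally constant field,
#' \eqn{Var(\epsilon)} equals the noise variance in expectation — the
#' \eqn{\sqrt{6/7}} factor removes the bias introduced by the neighbour
#' mean itself being noisy.
#'
#' @param volume a [Volume-class] with every axis of length >= 2.
#' @return numeric array of residuals, same dim as the volume.
#' @export
pseudoResiduals <- function(volume) {
  u <- volData(volume)
  if (any(dim(u) < 2L)) {
    stop2("volume too thin for 3D residuals", "contract")
  }
  .residualCore(u)
}

# face-neighbour residuals over the non-degenerate axes: 2k neighbours
# give the unbiasing factor sqrt(2k / (2k + 1)); k = 3 is the 3D case,
# k = 2 serves single-slice volumes in their degenerate 2D mode
.residualCore <- function(u) {
  d <- dim(u)
  active <- which(d >= 2L)
  if (length(active) < 2L) {
    stop2("volume too thin for residual estimation", "contract")
  }
  shift <- function(axis, by) {
    idx0 <- reflectIndex(seq_len(d[axis]) - 1L + by, d[axis]) + 1L
    switch(axis, u[idx0, , , drop = FALSE],
           u[, idx0, , drop = FALSE],
           u[, , idx0, drop = FALSE])
  }
  nb <- 0
  for (axis in active) nb <- nb + shift(axis, -1L) + shift(axis, 1L)
  m <- 2L * length(active)
  sqrt(m / (m + 1)) * (u - nb / m)
}

#' Local noise estimation over sub-blocks
#'
#' Partitions the volume into cubes of `blockSize` voxels anchored at voxel
#' (1,1,1) — edge blocks truncated at the boundary use their actual voxel
#' count — and estimates the noise standard deviation in each block as the
#' root mean square of the pseudo-residuals it contains. This local
#' estimate, rather than a single whole-volume value, is what lets the
#' smoothing parameter adapt to spatially varying noise.
#'
#' @param volume a [Volume-class].
#' @param blockSize voxels per block edge, >= 4.
#' @return a [NoiseMap-class] with
#'   `gridShape[i] = ceiling(dim(volume)[i] / blockSize)`.
#' @export
estimateNoiseLocal <- function(volume, blockSize = 16L) {
  blockSize <- as.integer(blockSize)
  if (is.na(blockSize) || blockSize < 4L) {
    stop2("block too small for stable estimate", "contract")
  }
  eps2 <- .residualCore(volData(volume))^2
  d <- dim(eps2)
  grid <- as.integer(ceiling(d / blockSize))
  bz <- (seq_len(d[1]) - 1L) %/% blockSize + 1L
  by <- (seq_len(d[2]) - 1L) %/% blockSize + 1L
  bx <- (seq_len(d[3]) - 1L) %/% blockSize + 1L
  idx <- bz[slice.index(eps2, 1L)] +
    grid[1] * (by[slice.index(eps2, 2L)] - 1L) +
    grid[1] * grid[2] * (bx[slice.index(eps2, 3L)] - 1L)
  ms <- vapply(split(as.vector(eps2), idx), mean, numeric(1))
  sigma <- array(0, dim = grid)
  sigma[as.integer(names(ms))] <- sqrt(ms)
  new("NoiseMap", sigma = sigma, blockSize = blockSize,
      method = "pseudo-residual")
}

#' Automatic NLM smoothing parameter
#'
#' Combines a local noise estimate with the patch size and the volume's
#' gray-scale range into the NLM bandwidth:
#' \deqn{h = \max\left(h_{\min}\frac{g}{g_{ref}},\;
#'       \sqrt{2\,\beta\,\hat\sigma^2\,|N|}\right)}
#' with \eqn{g} the volume's gsv level count. Only the floor carries the
#' gsv factor: \eqn{\hat\sigma} is measured in the volume's own intensity
#' units, so the main term is already covariant with intensity rescaling.
#'
#' @param sigmaHat local noise standard deviation estimate, >= 0.
#' @param patchVoxels patch voxel count |N|, >= 1 (27 for a 3^3 patch).
#' @param policy a [SmoothingPolicy-class].
#' @param gsvLevels intensity-level count of the volume being denoised.
#' @return h, strictly positive, vectorized over `sigmaHat`.
#' @examples
#' smoothingParameter(10, 27) # sqrt(2 * 100 * 27) = 73.48
#' @export
smoothingParameter <- function(sigmaHat, patchVoxels,
                               policy = smoothingPolicy(),
                               gsvLevels = 256) {
  if (any(sigmaHat < 0)) stop2("sigmaHat must be >= 0", "contract")
  if (patchVoxels < 1) stop2("patchVoxels must be >= 1", "contract")
  floorH <- policy@hMin * gsvLevels / policy@gsvRef
  pmax(floorH, sqrt(2 * policy@beta * sigmaHat^2 * patchVoxels))
}

# expand per-block sigma-hat to a per-voxel h array (piecewise-constant
# nearest-block lookup, no interpolation)
hFieldFromNoiseMap <- function(noiseMap, volDim, patchVoxels, policy,
                               gsvLevels) {
  bs <- noiseMap@blockSize
  hb <- array(smoothingParameter(noiseMap@sigma, patchVoxels, policy,
                                 gsvLevels),
              dim = dim(noiseMap@sigma))
  iz <- (seq_len(volDim[1]) - 1L) %/% bs + 1L
  iy <- (seq_len(volDim[2]) - 1L) %/% bs + 1L
  ix <- (seq_len(volDim[3]) - 1L) %/% bs + 1L
  array(hb[iz, iy, ix, drop = FALSE], dim = volDim)
}

#' Export a noise map as netCDF
#'
#' Writes the per-block sigma-hat grid as a 3D variable `sigma` for QC in
#' external viewers.
#'
#' @param noiseMap a [NoiseMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNoiseMap <- function(noiseMap, path) {
  g <- dim(noiseMap@sigma)
  dims <- list(
    ncdf4::ncdim_def("bz", "block", seq_len(g[1])),
    ncdf4::ncdim_def("by", "block", seq_len(g[2])),
    ncdf4::ncdim_def("bx", "block", seq_len(g[3]))
  )
  var <- ncdf4::ncvar_def("sigma", "intensity", dims, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, noiseMap@sigma)
  ncdf4::ncatt_put(nc, 0, "block_size", noiseMap@blockSize)
  invisible(path)
}
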