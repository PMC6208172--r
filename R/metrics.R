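#' Grayscale line profile through a volume
#'
#' Samples the volume by trilinear interpolation at `nSamples` equally
#' spaced positions along the segment from `start` to `end` (1-based voxel
#' coordinates, (z, y, x) order). The spread of the profile about its
#' local structure indexes the image noise; comparing profiles before and
#' after denoising quantifies the reduction in intensity variability.
#'
#' @param volume a [Volume-class].
#' @param start,end voxel coordinates inside the volume (may be
#'   fractional).
#' @param nSamples number of samples, >= 2.
#' @return a [LineProfile-class].
#' @export
lineProfile <- function(volume, start, end, nSamples = 100L) {
  u <- volData(volume)
  d <- dim(u)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (nSamples < 2L) stop2("nSamples must be >= 2", "contract")
  if (any(start < 1 | start > d) || any(end < 1 | end > d)) {
    stop2("profile endpoints must lie inside the volume", "contract")
  }
  if (all(start == end)) {
    stop2("profile endpoints must differ", "contract")
  }
  t <- seq(0, 1, length.out = nSamples)
  pts <- outer(t, end - start) + rep(start, each = nSamples)
  lo <- pmin(pmax(floor(pts), 1), rep(d, each = nSamples))
  hi <- pmin(lo + 1, rep(d, each = nSamples))
  fr <- pts - lo
  val <- numeric(nSamples)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    iz <- if (cz) hi[, 1] else lo[, 1]
    iy <- if (cy) hi[, 2] else lo[, 2]
    ix <- if (cx) hi[, 3] else lo[, 3]
    wt <- (if (cz) fr[, 1] else 1 - fr[, 1]) *
          (if (cy) fr[, 2] else 1 - fr[, 2]) *
          (if (cx) fr[, 3] else 1 - fr[, 3])
    val <- val + wt * u[cbind(iz, iy, ix)]
  }
  new("LineProfile", start = start, end = end,
      positions = t * sqrt(sum((end - start)^2)), intensities = val)
}

#' Detrended variability of a line profile
#'
#' Standard deviation of the residuals about a running median of the
#' profile. The running median tracks the anatomical structure (plateaus
#' and edges) so that the statistic measures spread about local structure
#' — noise — rather than the structure itself.
#'
#' @param profile a [LineProfile-class].
#' @param detrendWindow odd window width in samples, >= 3, <= number of
#'   samples.
#' @return non-negative scalar (intensity units).
#' @export
profileVariability <- function(profile, detrendWindow = 9L) {
  x <- profile@intensities
  k <- as.integer(detrendWindow)
  if (k < 3L || k %% 2L == 0L || k > length(x)) {
    stop2("detrendWindow must be odd, >= 3 and <= n samples", "contract")
  }
  trend <- stats::runmed(x, k, endrule = "median")
  stats::sd(x - trend)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(peak^2 / MSE)} between a reference and a test volume;
#' `Inf` when identical.
#'
#' @param reference,test [Volume-class] objects of equal shape.
#' @param peak peak intensity of the scale (> 0); defaults to the
#'   reference's gsv level count minus 1.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, peak = gsvLevels(reference) - 1) {
  if (!all(dim(reference) == dim(test))) {
    stop2("volumes must have equal shape", "contract")
  }
  if (peak <= 0) stop2("peak must be > 0", "contract")
  mse <- mean((volData(reference) - volData(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Difference-operation counts of the SSD computation
#'
#' The cost model of the sliding-window acceleration, with `M` the patch
#' edge length (so the patch holds M^3 voxels) and `N` the number of SSD
#' centers along the traversal: the brute-force path performs N * M^3
#' difference operations, the moving-average-filter path
#' M^3 + (N - 1) * 2 * M^2 — after the first center only the two end
#' slices of the patch change. [mafRowSSD()] counts the implementation's
#' actual operations for comparison with this model.
#'
#' @param M patch edge length in voxels, odd, >= 1.
#' @param N number of SSD evaluations (centers), >= 1.
#' @param method "naive" or "maf".
#' @return exact operation count (as a double; exact below 2^53).
#' @examples
#' countDifferenceOps(3, 1000, "naive") # 27000
#' countDifferenceOps(3, 1000, "maf")   # 18009
#' @export
countDifferenceOps <- function(M, N, method = c("naive", "maf")) {
  method <- match.arg(method)
  M <- as.numeric(M)
  N <- as.numeric(N)
  if (any(M < 1 | M %% 2 != 1)) stop2("M must be odd and >= 1", "contract")
  if (any(N < 1)) stop2("N must be >= 1", "contract")
  switch(method,
    naive = N * M^3,
    maf = M^3 + (N - 1) * 2 * M^2
  )
}
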