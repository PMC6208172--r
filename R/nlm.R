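#' NLM parameter set
#'
#' Defaults follow the fixed-window policy of 3D patch-based denoising:
#' a 3^3 patch (`patchRadius = 1`) compared across an 11^3 search window
#' (`searchRadius = 5`). Larger search windows rarely improve quality —
#' patch similarity statistics degrade with distance — and cost cubically.
#'
#' @param patchRadius inner SSD patch half-width (>= 1); patch edge
#'   m = 2 * patchRadius + 1.
#' @param searchRadius outer search window half-width (>= patchRadius).
#' @param policy a [SmoothingPolicy-class]; see [smoothingPolicy()].
#' @param blockSize sub-block edge for local noise estimation (>= 4).
#' @param boundary padding outside the volume: "mirror" (default;
#'   preserves local statistics) or "zero".
#' @return an [NLMParams-class] object.
#' @export
nlmParams <- function(patchRadius = 1L, searchRadius = 5L,
                      policy = smoothingPolicy(), blockSize = 16L,
                      boundary = c("mirror", "zero")) {
  boundary <- match.arg(boundary)
  new("NLMParams", patchRadius = as.integer(patchRadius),
      searchRadius = as.integer(searchRadius), policy = policy,
      blockSize = as.integer(blockSize), boundary = boundary)
}

# per-axis effective radii: axes of length 1 run in degenerate 2D mode
# (radius clamped to 0); other axes must fit the full patch edge
effectiveRadii <- function(volDim, patchRadius, searchRadius) {
  degenerate <- volDim == 1L
  if (any(!degenerate & volDim < 2L * patchRadius + 1L)) {
    stop2("volume too small for patch size", "contract")
  }
  list(
    patch = ifelse(degenerate, 0L, patchRadius),
    search = ifelse(degenerate, 0L, searchRadius)
  )
}

#' Brute-force patch SSD (reference path)
#'
#' Sums squared intensity differences over the full m^3 patch between the
#' patch at `center` and the patch at `center + offset`, re-walking every
#' voxel pair. This is the reference the accelerated sliding-window path
#' is validated against; it costs m^3 difference operations per call
#' (returned in attribute `diffOps`).
#'
#' @param volume a [Volume-class].
#' @param center voxel index (z, y, x), 1-based.
#' @param offset integer displacement (dz, dy, dx).
#' @param patchRadius patch half-width.
#' @param boundary "mirror" or "zero" padding.
#' @return the SSD value with attribute `diffOps`.
#' @export
ssdNaive <- function(volume, center, offset, patchRadius = 1L,
                     boundary = c("mirror", "zero")) {
  boundary <- match.arg(boundary)
  u <- volData(volume)
  d <- dim(u)
  p <- rep_len(as.integer(patchRadius), 3L)
  p[d == 1L] <- 0L
  center <- as.integer(center)
  offset <- as.integer(offset)
  grab <- function(c0) {
    # 0-based axis index vectors of the patch around c0
    ax <- lapply(1:3, function(a) c0[a] - 1L + seq(-p[a], p[a]))
    if (boundary == "mirror") {
      ax <- lapply(1:3, function(a) reflectIndex(ax[[a]], d[a]) + 1L)
      u[ax[[1]], ax[[2]], ax[[3]], drop = FALSE]
    } else {
      out <- array(0, 2L * p + 1L)
      ok <- lapply(1:3, function(a) ax[[a]] >= 0L & ax[[a]] < d[a])
      out[ok[[1]], ok[[2]], ok[[3]]] <-
        u[ax[[1]][ok[[1]]] + 1L, ax[[2]][ok[[2]]] + 1L,
          ax[[3]][ok[[3]]] + 1L, drop = FALSE]
      out
    }
  }
  a <- grab(center)
  b <- grab(center + offset)
  structure(sum((a - b)^2), diffOps = length(a))
}

#' Patch SSD field for one center voxel
#'
#' @param volume a [Volume-class].
#' @param center voxel index (z, y, x), 1-based.
#' @param params an [NLMParams-class].
#' @return an [SSDField-class] over all search offsets.
#' @export
ssdField <- function(volume, center, params = nlmParams()) {
  d <- dim(volume)
  r <- effectiveRadii(d, params@patchRadius, params@searchRadius)
  vals <- .cpp_ssd_field(as.vector(volData(volume)), as.integer(d),
                         as.integer(center) - 1L, as.integer(r$patch),
                         rep(params@searchRadius, 3L),
                         as.integer(params@boundary == "zero"))
  new("SSDField", center = as.numeric(center), values = vals,
      offsetsRadius = params@searchRadius)
}

#' Full SSD map via the moving-average-filter acceleration
#'
#' Computes the patch SSD for every (voxel, search offset) pair using the
#' incremental sliding update along x: adjacent centers' patches differ
#' only in two end slices, so after the first center of a row each step
#' costs 2 m^2 squared differences instead of m^3. Intended for validation
#' and small fixtures — the result holds w^3 values per voxel. The counted
#' number of squared-difference evaluations is returned in attribute
#' `diffOps`.
#'
#' @param volume a [Volume-class].
#' @param params an [NLMParams-class].
#' @param maxValues guard on the total number of SSD values materialized.
#' @return numeric array, dim (w, w, w, nz, ny, nx): SSD at
#'   `[dz+s+1, dy+s+1, dx+s+1, z, y, x]` for offset (dz,dy,dx) and center
#'   (z,y,x); attribute `diffOps` carries the instrumented operation count.
#' @export
ssdMapMAF <- function(volume, params = nlmParams(), maxValues = 5e7) {
  d <- dim(volume)
  r <- effectiveRadii(d, params@patchRadius, params@searchRadius)
  w <- 2L * r$search + 1L
  if (prod(w) * prod(d) > maxValues) {
    stop2("ssd map too large to materialize; use denoise() directly",
          "contract")
  }
  res <- .cpp_ssd_map(as.vector(volData(volume)), as.integer(d),
                      as.integer(r$patch), as.integer(r$search),
                      as.integer(params@boundary == "zero"))
  structure(res$ssd, diffOps = res$diffOps)
}

#' Instrumented MAF traversal of one row
#'
#' Runs the sliding SSD update along one x-row of centers for a single
#' search offset and reports the SSD values together with the counted
#' squared-difference operations — the measured counterpart of the
#' operation-count model in [countDifferenceOps()]: a row of N centers
#' with patch edge m costs m^3 + (N - 1) * 2 * m^2.
#'
#' @param volume a [Volume-class].
#' @param z,y 1-based row coordinates.
#' @param offset integer displacement (dz, dy, dx).
#' @param patchRadius patch half-width.
#' @param boundary "mirror" or "zero".
#' @return list with `ssd` (length nx) and `diffOps` (counted operations).
#' @export
mafRowSSD <- function(volume, z, y, offset, patchRadius = 1L,
                      boundary = c("mirror", "zero")) {
  boundary <- match.arg(boundary)
  d <- dim(volume)
  p <- rep_len(as.integer(patchRadius), 3L)
  p[d == 1L] <- 0L
  .cpp_maf_row(as.vector(volData(volume)), as.integer(d),
               as.integer(z) - 1L, as.integer(y) - 1L, as.integer(offset),
               p, as.integer(boundary == "zero"))
}

#' NLM patch weight
#'
#' \eqn{w = \exp(-(ssd/h^2)^p)}. With `shapeP = 1` this is the standard
#' Gaussian NLM kernel; other exponents reshape the kernel to better match
#' non-Gaussian noise (p > 1 cuts off dissimilar patches more sharply).
#'
#' @param ssd patch sum of squared differences, >= 0 (vectorized).
#' @param h smoothing parameter, > 0.
#' @param shapeP kernel-shape exponent, > 0.
#' @return weight in \[0, 1\].
#' @examples
#' nlmWeight(0, 10)          # 1
#' nlmWeight(100, 10)        # exp(-1)
#' @export
nlmWeight <- function(ssd, h, shapeP = 1) {
  if (any(h <= 0)) stop2("smoothing parameter h must be > 0", "contract")
  if (any(shapeP <= 0)) stop2("shapeP must be > 0", "contract")
  exp(-(ssd / h^2)^shapeP)
}

#' Denoise a volume with locally adaptive non-local means
#'
#' Each output voxel is the weight-normalized average of the intensities in
#' its search window, with weights \eqn{\exp(-(ssd/h^2)^p)} driven by patch
#' similarity. The smoothing parameter h is derived per voxel from the
#' noise standard deviation of the sub-block containing it (see
#' [estimateNoiseLocal()] and [smoothingParameter()]); no manual noise or
#' bandwidth input is needed. The center's own weight is set to the
#' maximum of the other offsets' weights before normalization.
#'
#' @param volume a [Volume-class]; axes of length 1 run in degenerate 2D
#'   mode, other axes must be at least one patch edge long.
#' @param params an [NLMParams-class].
#' @param adaptive if `TRUE` (default) h follows the per-block noise map;
#'   if `FALSE` a single whole-volume noise estimate is used everywhere
#'   (the classical global-h variant, kept for comparison).
#' @param noiseMap optionally a precomputed [NoiseMap-class] (adaptive
#'   mode only); must match `params@blockSize`.
#' @return the denoised [Volume-class]; shape, spacing and gsv levels are
#'   those of the input.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(16, 16, 16), background = 80))
#' noisy <- addNoise(ph, noiseModel("gaussian", sigma = 5, seed = 1))
#' den <- denoise(noisy, nlmParams(searchRadius = 3))
#' sd(volData(den) - 80) < sd(volData(noisy) - 80)
#' @export
denoise <- function(volume, params = nlmParams(), adaptive = TRUE,
                    noiseMap = NULL) {
  d <- dim(volume)
  r <- effectiveRadii(d, params@patchRadius, params@searchRadius)
  patchVoxels <- prod(2L * r$patch + 1L)
  if (adaptive) {
    if (is.null(noiseMap)) {
      noiseMap <- estimateNoiseLocal(volume, params@blockSize)
    } else if (noiseMap@blockSize != params@blockSize) {
      stop2("noiseMap blockSize does not match params", "contract")
    }
    hField <- hFieldFromNoiseMap(noiseMap, d, patchVoxels, params@policy,
                                 gsvLevels(volume))
  } else {
    sigmaGlobal <- sqrt(mean(.residualCore(volData(volume))^2))
    h <- smoothingParameter(sigmaGlobal, patchVoxels, params@policy,
                            gsvLevels(volume))
    hField <- array(h, dim = d)
  }
  out <- .cpp_denoise(as.vector(volData(volume)), as.integer(d),
                      as.integer(r$patch), as.integer(r$search),
                      as.vector(hField), params@policy@shapeP,
                      as.integer(params@boundary == "zero"))
  Volume(out, spacing = volSpacing(volume), gsvLevels = gsvLevels(volume),
         provenance = paste0(provenance(volume), "+nlm"))
}
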