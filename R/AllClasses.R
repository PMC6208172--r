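#' @import methods
#' @importFrom stats rnorm rpois runmed sd median
#' @importFrom utils write.table
#' @importFrom tools file_ext
#' @useDynLib nlm3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Volume: a 3D grayscale intensity grid
#'
#' The central data container of the package: a 3D scalar field with voxel
#' spacing and a declared gray-scale value (gsv) range. Intensities are held
#' as doubles regardless of the bit depth of the source file; the number of
#' representable levels of the source (256 for 8-bit, 65536 for 16-bit) is
#' kept as metadata because it enters the automatic smoothing-parameter
#' floor.
#'
#' Axis convention: the array is indexed \code{[z, y, x]}, slice axis first.
#' All offsets and coordinates in the package follow this order.
#'
#' @slot data 3D numeric array of intensities, dim \code{(nz, ny, nx)}.
#' @slot spacing numeric(3), voxel edge length per axis in micrometres.
#' @slot gsvLevels declared number of representable intensity levels (>= 2).
#' @slot provenance free-text source tag (file path, "phantom", ...).
#'
#' @seealso [Volume()] for the user-facing constructor.
#' @exportClass Volume
setClass("Volume",
  representation(
    data = "array",
    spacing = "numeric",
    gsvLevels = "numeric",
    provenance = "character"
  )
)

setValidity("Volume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) {
    return("data must be a 3D array")
  }
  if (any(dim(d) < 1L)) {
    return("all axis lengths must be >= 1")
  }
  if (!all(is.finite(d))) {
    return("all intensities must be finite")
  }
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be 3 positive finite values (micrometres)")
  }
  if (length(object@gsvLevels) != 1L || !is.finite(object@gsvLevels) ||
      object@gsvLevels < 2) {
    return("gsvLevels must be a single value >= 2")
  }
  TRUE
})

#' SmoothingPolicy: how the NLM smoothing parameter h is derived
#'
#' Houses the knobs of the automatic bandwidth rule
#' \eqn{h = \max(h_{\min}, \sqrt{2 \beta \hat\sigma^2 |N|})}, where
#' \eqn{\hat\sigma} is the local noise standard deviation and \eqn{|N|} the
#' patch voxel count. The floor \code{hMin} scales with the volume's
#' gsv level count relative to \code{gsvRef} so that the same scene coded at
#' a different bit depth (with the matching intensity stretch) denoises
#' identically; \code{beta} is dimensionless and does not scale, because
#' \eqn{\hat\sigma} already carries the intensity units.
#'
#' @slot beta dimensionless scale multiplier (> 0).
#' @slot gsvRef reference intensity-level count the defaults are stated at.
#' @slot shapeP kernel-shape exponent p (> 0); p = 1 is the Gaussian NLM
#'   kernel, p > 1 sharpens the cutoff for non-Gaussian noise.
#' @slot hMin floor for h in intensity units at \code{gsvRef} levels; the
#'   effective floor is \code{hMin * gsvLevels / gsvRef}.
#' @exportClass SmoothingPolicy
setClass("SmoothingPolicy",
  representation(
    beta = "numeric",
    gsvRef = "numeric",
    shapeP = "numeric",
    hMin = "numeric"
  )
)

setValidity("SmoothingPolicy", function(object) {
  one_pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!one_pos(object@beta)) return("beta must be a single value > 0")
  if (!one_pos(object@shapeP)) return("shapeP must be a single value > 0")
  if (!one_pos(object@hMin)) return("hMin must be a single value > 0")
  if (length(object@gsvRef) != 1L || !is.finite(object@gsvRef) ||
      object@gsvRef < 2) {
    return("gsvRef must be a single value >= 2")
  }
  TRUE
})

#' NLMParams: the full parameter set of the denoiser
#'
#' @slot patchRadius half-width of the inner SSD patch; patch edge
#'   m = 2 * patchRadius + 1, patch voxel count |N| = m^3.
#' @slot searchRadius half-width of the outer search window; window edge
#'   w = 2 * searchRadius + 1.
#' @slot policy a [SmoothingPolicy-class] object.
#' @slot blockSize edge length (voxels) of the sub-blocks used for local
#'   noise estimation.
#' @slot boundary padding mode outside the volume: "mirror" or "zero".
#' @exportClass NLMParams
setClass("NLMParams",
  representation(
    patchRadius = "integer",
    searchRadius = "integer",
    policy = "SmoothingPolicy",
    blockSize = "integer",
    boundary = "character"
  )
)

setValidity("NLMParams", function(object) {
  if (object@patchRadius < 1L) return("patchRadius must be >= 1")
  if (object@searchRadius < object@patchRadius) {
    return("searchRadius must be >= patchRadius")
  }
  if (object@blockSize < 4L) return("blockSize must be >= 4")
  if (!object@boundary %in% c("mirror", "zero")) {
    return("boundary must be 'mirror' or 'zero'")
  }
  TRUE
})

#' NoiseMap: per-block noise standard deviation estimates
#'
#' One \eqn{\hat\sigma} per sub-block of the volume, estimated from
#' pseudo-residuals. The block grid is anchored at voxel (1,1,1);
#' \code{gridShape[i] = ceiling(volumeShape[i] / blockSize)}, edge blocks
#' truncated at the volume boundary use their actual voxel count.
#'
#' @slot sigma 3D array of per-block noise standard deviations (intensity
#'   units), dim = grid shape.
#' @slot blockSize voxels per block edge.
#' @slot method estimator tag ("pseudo-residual").
#' @exportClass NoiseMap
setClass("NoiseMap",
  representation(
    sigma = "array",
    blockSize = "integer",
    method = "character"
  )
)

setValidity("NoiseMap", function(object) {
  if (length(dim(object@sigma)) != 3L) return("sigma must be a 3D array")
  if (any(!is.finite(object@sigma)) || any(object@sigma < 0)) {
    return("all sigma estimates must be finite and >= 0")
  }
  if (object@blockSize < 4L) return("blockSize must be >= 4")
  TRUE
})

#' PhantomSpec: declarative description of a synthetic test volume
#'
#' Piecewise-constant anatomy-like structures on a constant background.
#' Primitives are drawn in list order, later ones overwriting earlier ones.
#' The same spec always yields a bitwise-identical phantom.
#'
#' @slot shape integer(3) voxel counts (nz, ny, nx).
#' @slot background background intensity.
#' @slot shapes list of primitives from [sphereShape()], [boxShape()],
#'   [lamellaeShape()].
#' @slot gsvLevels declared intensity-level count of the phantom.
#' @slot seed integer seed recorded with the spec (used by noise streams
#'   that default to it; geometry itself is deterministic).
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    shape = "integer",
    background = "numeric",
    shapes = "list",
    gsvLevels = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L)) {
    return("shape must be 3 positive voxel counts")
  }
  if (object@gsvLevels < 2) return("gsvLevels must be >= 2")
  ok <- vapply(object@shapes, function(s) {
    is.list(s) && !is.null(s$kind) &&
      s$kind %in% c("sphere", "box", "lamellae")
  }, logical(1))
  if (!all(ok)) return("shapes must be sphere/box/lamellae primitives")
  TRUE
})

#' NoiseModel: the stochastic corruption applied to a phantom
#'
#' \describe{
#'   \item{gaussian}{additive white Gaussian noise, v + N(0, sigma^2) —
#'     the baseline model of standard NLM.}
#'   \item{poisson_gaussian}{Poisson(gain * v)/gain + N(0, sigma^2) —
#'     photon-counting noise with additive readout noise.}
#'   \item{rician}{sqrt((v + n1)^2 + n2^2), n1, n2 ~ N(0, sigma^2) —
#'     magnitude noise; requires non-negative input.}
#' }
#'
#' @slot kind "gaussian", "poisson_gaussian" or "rician".
#' @slot sigma standard deviation of the Gaussian component (>= 0).
#' @slot gain photons per intensity unit for the Poisson component (> 0).
#' @slot seed integer seed; the same seed reproduces the same noise.
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(
    kind = "character",
    sigma = "numeric",
    gain = "numeric",
    seed = "integer"
  )
)

setValidity("NoiseModel", function(object) {
  if (!object@kind %in% c("gaussian", "poisson_gaussian", "rician")) {
    return("kind must be gaussian, poisson_gaussian or rician")
  }
  if (!is.finite(object@sigma) || object@sigma < 0) {
    return("sigma must be finite and >= 0")
  }
  if (object@kind == "poisson_gaussian" &&
      (!is.finite(object@gain) || object@gain <= 0)) {
    return("gain must be > 0 for poisson_gaussian")
  }
  TRUE
})

#' SSDField: patch SSD values for one center voxel across all search offsets
#'
#' @slot center voxel index (z, y, x), 1-based.
#' @slot values 3D array over search offsets, dim (w, w, w) with
#'   w = 2 * offsetsRadius + 1; entry [sz+dz+1, sy+dy+1, sx+dx+1] is the
#'   SSD between the patch at `center` and the patch at `center + (dz,dy,dx)`.
#' @slot offsetsRadius the search radius the field was computed at.
#' @exportClass SSDField
setClass("SSDField",
  representation(
    center = "numeric",
    values = "array",
    offsetsRadius = "integer"
  )
)

setValidity("SSDField", function(object) {
  w <- 2L * object@offsetsRadius + 1L
  if (!all(dim(object@values) == w)) {
    return("values must have dim (w, w, w), w = 2 * offsetsRadius + 1")
  }
  if (any(object@values < 0)) return("SSD values must be >= 0")
  TRUE
})

#' LineProfile: intensities sampled along a segment through a volume
#'
#' Trilinear samples at equally spaced arc-length positions between two
#' voxel coordinates; the spread of the profile about its local structure
#' indexes the image noise.
#'
#' @slot start,end numeric(3) voxel coordinates (z, y, x), 1-based.
#' @slot positions arc length of each sample in voxels, strictly increasing.
#' @slot intensities sampled intensity at each position.
#' @exportClass LineProfile
setClass("LineProfile",
  representation(
    start = "numeric",
    end = "numeric",
    positions = "numeric",
    intensities = "numeric"
  )
)

setValidity("LineProfile", function(object) {
  n <- length(object@positions)
  if (n < 2L) return("at least 2 samples required")
  if (length(object@intensities) != n) {
    return("positions and intensities must have equal length")
  }
  if (any(diff(object@positions) <= 0)) {
    return("positions must be strictly increasing")
  }
  TRUE
})
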