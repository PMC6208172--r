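#' Phantom primitives
#'
#' Building blocks for [phantomSpec()]. All coordinates are 1-based voxel
#' indices in (z, y, x) order; primitives extending beyond the volume are
#' clipped silently. Primitives are painted in list order, later ones
#' overwriting earlier ones.
#'
#' @param center,corner,origin position of the primitive (voxels).
#' @param radius sphere radius in voxels; a voxel belongs to the sphere if
#'   its center lies within `radius` of `center`.
#' @param size box edge lengths (voxels) along (z, y, x).
#' @param period,thickness lamellae stripe repeat and stripe width along
#'   `axis` (voxels); emulates layered structures such as cerebellar
#'   folia at phantom scale.
#' @param axis axis the lamellae repeat along (1 = z, 2 = y, 3 = x).
#' @param intensity intensity painted into the primitive.
#' @return a primitive description for the `shapes` list of a spec.
#' @name phantom-primitives
NULL

#' @rdname phantom-primitives
#' @export
sphereShape <- function(center, radius, intensity) {
  list(kind = "sphere", center = as.numeric(center),
       radius = as.numeric(radius), intensity = as.numeric(intensity))
}

#' @rdname phantom-primitives
#' @export
boxShape <- function(corner, size, intensity) {
  list(kind = "box", corner = as.numeric(corner),
       size = as.numeric(size), intensity = as.numeric(intensity))
}

#' @rdname phantom-primitives
#' @export
lamellaeShape <- function(origin, period, thickness, intensity, axis = 3L) {
  stopifnot(period >= 1, thickness >= 1, thickness <= period,
            axis %in% 1:3)
  list(kind = "lamellae", origin = as.numeric(origin),
       period = as.numeric(period), thickness = as.numeric(thickness),
       intensity = as.numeric(intensity), axis = as.integer(axis))
}

#' Declarative phantom specification
#'
#' @param shape voxel counts (nz, ny, nx).
#' @param background background intensity.
#' @param shapes list of primitives; see [phantom-primitives].
#' @param gsvLevels declared intensity-level count.
#' @param seed integer seed recorded with the spec; noise models created
#'   from the spec default to it. The geometry itself is deterministic.
#' @return a [PhantomSpec-class] object.
#' @export
phantomSpec <- function(shape, background = 0, shapes = list(),
                        gsvLevels = 256, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape),
      background = as.numeric(background), shapes = shapes,
      gsvLevels = as.numeric(gsvLevels), seed = as.integer(seed))
}

#' Generate a noiseless phantom volume
#'
#' Deterministic: the same spec always yields a bitwise-identical volume.
#'
#' @param spec a [PhantomSpec-class].
#' @param spacing voxel spacing (micrometres) stamped on the volume.
#' @return a [Volume-class].
#' @examples
#' spec <- phantomSpec(c(32, 32, 32), background = 0,
#'                     shapes = list(sphereShape(c(16, 16, 16), 8, 100)))
#' v <- generatePhantom(spec)
#' sum(volData(v) == 100) # close to 4/3 * pi * 8^3
#' @export
generatePhantom <- function(spec, spacing = c(1, 1, 1)) {
  d <- spec@shape
  u <- array(spec@background, dim = d)
  zc <- slice.index(u, 1L)
  yc <- slice.index(u, 2L)
  xc <- slice.index(u, 3L)
  for (s in spec@shapes) {
    inside <- switch(s$kind,
      sphere = (zc - s$center[1])^2 + (yc - s$center[2])^2 +
        (xc - s$center[3])^2 <= s$radius^2,
      box = zc >= s$corner[1] & zc < s$corner[1] + s$size[1] &
        yc >= s$corner[2] & yc < s$corner[2] + s$size[2] &
        xc >= s$corner[3] & xc < s$corner[3] + s$size[3],
      lamellae = {
        coord <- switch(s$axis, zc, yc, xc)
        ((coord - s$origin[s$axis]) %% s$period) < s$thickness
      }
    )
    u[inside] <- s$intensity
  }
  Volume(u, spacing = spacing, gsvLevels = spec@gsvLevels,
         provenance = "phantom")
}

#' Noise model constructor
#'
#' @param kind "gaussian" (additive white Gaussian noise, the baseline
#'   model of standard NLM), "poisson_gaussian" or "rician" (stand-ins for
#'   scanners whose noise is not additive Gaussian).
#' @param sigma Gaussian standard deviation in intensity units, >= 0.
#' @param gain photons per intensity unit for the Poisson component.
#' @param seed integer seed; identical seeds reproduce identical noise.
#' @return a [NoiseModel-class] object.
#' @export
noiseModel <- function(kind = c("gaussian", "poisson_gaussian", "rician"),
                       sigma = 1, gain = 1, seed = 1L) {
  kind <- match.arg(kind)
  new("NoiseModel", kind = kind, sigma = as.numeric(sigma),
      gain = as.numeric(gain), seed = as.integer(seed))
}

# run expr under a private RNG stream, restoring the caller's RNG state;
# each operation derives its own sub-stream so phantom geometry and noise
# draws stay reproducible independently of call order
withSeed <- function(seed, streamOffset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.double(seed) + streamOffset) %% .Machine$integer.max)
  expr
}

#' Corrupt a volume with a noise model
#'
#' Models: `gaussian` adds i.i.d. N(0, sigma^2); `poisson_gaussian` draws
#' Poisson(gain * v) / gain and adds N(0, sigma^2); `rician` returns
#' sqrt((v + n1)^2 + n2^2) with independent n1, n2 ~ N(0, sigma^2).
#' Intensities are not clamped to the gsv range — noise statistics stay
#' exact for estimator tests; clamp on export if needed.
#'
#' @param volume a [Volume-class]; rician and poisson_gaussian require
#'   non-negative intensities.
#' @param model a [NoiseModel-class].
#' @return the corrupted [Volume-class].
#' @export
addNoise <- function(volume, model) {
  u <- volData(volume)
  n <- length(u)
  out <- switch(model@kind,
    gaussian = withSeed(model@seed, 101L, u + rnorm(n, 0, model@sigma)),
    poisson_gaussian = {
      if (any(u < 0)) {
        stop2("poisson_gaussian requires non-negative input", "contract")
      }
      withSeed(model@seed, 211L,
               array(rpois(n, model@gain * u) / model@gain, dim(u)) +
                 rnorm(n, 0, model@sigma))
    },
    rician = {
      if (any(u < 0)) {
        stop2("rician requires non-negative input", "contract")
      }
      withSeed(model@seed, 307L, {
        n1 <- rnorm(n, 0, model@sigma)
        n2 <- rnorm(n, 0, model@sigma)
        sqrt((u + n1)^2 + array(n2, dim(u))^2)
      })
    }
  )
  out <- array(out, dim(u))
  Volume(out, spacing = volSpacing(volume), gsvLevels = gsvLevels(volume),
         provenance = paste0(provenance(volume), "+", model@kind))
}
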