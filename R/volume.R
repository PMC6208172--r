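#' Construct a Volume
#'
#' @param data 3D numeric array (or a vector with a `dim` to set via
#'   `shape`), indexed \code{[z, y, x]}.
#' @param spacing voxel edge length per axis in micrometres; a scalar is
#'   recycled to all three axes.
#' @param gsvLevels declared number of representable intensity levels
#'   (256 for 8-bit sources, 65536 for 16-bit).
#' @param provenance free-text source tag.
#' @return a [Volume-class] object.
#' @examples
#' v <- Volume(array(0, c(4, 4, 4)), spacing = 10.7, gsvLevels = 256)
#' dim(v)
#' @export
Volume <- function(data, spacing = c(1, 1, 1), gsvLevels = 65536,
                   provenance = "memory") {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop2("data must be a 3D array", "contract")
  }
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("Volume", data = data, spacing = spacing,
      gsvLevels = as.numeric(gsvLevels), provenance = provenance)
}

#' @describeIn Volume the intensity array, dim (nz, ny, nx)
#' @param x,object a `Volume`
#' @export
volData <- function(x) x@data

#' @describeIn Volume voxel spacing in micrometres, length 3 (z, y, x)
#' @export
volSpacing <- function(x) x@spacing

#' @describeIn Volume declared intensity-level count of the source
#' @export
gsvLevels <- function(x) x@gsvLevels

#' @describeIn Volume free-text source tag
#' @export
provenance <- function(x) x@provenance

#' @describeIn Volume voxel counts (nz, ny, nx)
#' @export
setMethod("dim", "Volume", function(x) dim(x@data))

#' @describeIn Volume compact display
#' @export
setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "Volume %d x %d x %d voxels (z,y,x), spacing %s um, %s gsv levels\n",
    d[1], d[2], d[3],
    paste(format(object@spacing, digits = 4), collapse = " x "),
    format(object@gsvLevels, big.mark = "")
  ))
  cat(sprintf("  intensity range [%g, %g], source: %s\n",
              min(object@data), max(object@data), object@provenance))
})

#' @describeIn NoiseMap-class per-block sigma-hat array
#' @param x,object a `NoiseMap`
#' @export
noiseSigma <- function(x) x@sigma

#' @describeIn NoiseMap-class block grid shape (blocks per axis)
#' @export
gridShape <- function(x) dim(x@sigma)

#' @describeIn NoiseMap-class compact display
#' @export
setMethod("show", "NoiseMap", function(object) {
  g <- dim(object@sigma)
  cat(sprintf(
    "NoiseMap %d x %d x %d blocks of %d^3 voxels (%s estimator)\n",
    g[1], g[2], g[3], object@blockSize, object@method
  ))
  cat(sprintf("  sigma-hat: min %.4g, median %.4g, max %.4g\n",
              min(object@sigma), stats::median(object@sigma),
              max(object@sigma)))
})

# classed errors so the CLI can map them onto exit codes:
# usage -> 1, io -> 2, contract -> 3
stop2 <- function(msg, class = "contract", call. = FALSE) {
  cls <- paste0("nlm3d_", class, "_error")
  stop(structure(
    class = c(cls, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# fold an out-of-range 0-based index back into [0, n) by mirror reflection
# (edge-inclusive symmetric padding); used by the pure-R oracle paths.
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep.int(0L, length(i)))
  period <- 2L * n
  i <- i %% period
  i[i < 0L] <- i[i < 0L] + period
  over <- i >= n
  i[over] <- period - 1L - i[over]
  i
}
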