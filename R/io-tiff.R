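#' Read a multi-page grayscale TIFF stack
#'
#' Page i becomes slice i along the z axis. The gsv level count is taken
#' from the sample bit depth (256 for 8-bit, 65536 for 16-bit). TIFF
#' carries no spacing metadata in this reader; spacing defaults to 1.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param spacing voxel spacing (micrometres) to stamp on the volume.
#' @return a [Volume-class].
#' @export
readTiffStack <- function(path, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop2("no input", "io")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop2("unsupported photometric interpretation", "io")
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  nz <- length(pages)
  d2 <- dim(pages[[1]])
  u <- array(0, c(nz, d2[1], d2[2]))
  for (i in seq_len(nz)) u[i, , ] <- pages[[i]]
  Volume(u, spacing = spacing, gsvLevels = 2^bits, provenance = path)
}

#' Write a volume as a multi-page grayscale TIFF stack
#'
#' The bit depth follows the volume's gsv level count (8-bit when
#' `gsvLevels <= 256`, else 16-bit). Intensities outside the storable
#' range, or non-integer intensities, are linearly rescaled to the full
#' range with a warning; otherwise stored values round-trip exactly.
#'
#' @param volume a [Volume-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTiffStack <- function(volume, path) {
  u <- volData(volume)
  bits <- if (gsvLevels(volume) <= 256) 8L else 16L
  vmax <- 2^bits - 1
  if (any(u < 0 | u > vmax) || any(u != round(u))) {
    warning("intensities not representable at ", bits,
            "-bit; rescaling to [0, ", vmax, "]")
    rng <- range(u)
    span <- if (diff(rng) > 0) diff(rng) else 1
    u <- round((u - rng[1]) / span * vmax)
  }
  nz <- dim(u)[1]
  pages <- lapply(seq_len(nz), function(i) u[i, , ] / vmax)
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = bits),
    error = function(e) stop2(conditionMessage(e), "io")
  )
  invisible(path)
}
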