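#' Read or write a volume with format auto-detection
#'
#' The format is inferred from the path: a directory or `.dcm` means a
#' DICOM series, `.nc`/`.cdf`/`.netcdf` netCDF, `.tif`/`.tiff` a TIFF
#' stack. Pass `format` to override.
#'
#' @param path file (or directory, for DICOM) path.
#' @param format "dicom", "netcdf", "tiff" or "auto".
#' @param variable netCDF variable name, passed to [readNetcdf()].
#' @return [readVolume()]: a [Volume-class]; [writeVolume()]: the path,
#'   invisibly.
#' @export
readVolume <- function(path, format = c("auto", "dicom", "netcdf", "tiff"),
                       variable = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  switch(format,
    dicom = readDicomSeries(path),
    netcdf = readNetcdf(path, variable),
    tiff = readTiffStack(path)
  )
}

#' @rdname readVolume
#' @param volume a [Volume-class] to write.
#' @export
writeVolume <- function(volume, path,
                        format = c("auto", "dicom", "netcdf", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  switch(format,
    dicom = writeDicomSeries(volume, path),
    netcdf = writeNetcdf(volume, path),
    tiff = writeTiffStack(volume, path)
  )
}

.guessFormat <- function(path) {
  if (dir.exists(path)) return("dicom")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    dcm = "dicom",
    nc = "netcdf",
    cdf = "netcdf",
    netcdf = "netcdf",
    tif = "tiff",
    tiff = "tiff",
    if (!nzchar(ext)) "dicom" else
      stop2(paste0("cannot infer volume format from '", path,
                   "'; pass format explicitly"), "usage")
  )
}
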