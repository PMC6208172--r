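#' Read a 3D volume from a netCDF file
#'
#' Accepts any netCDF (classic or netCDF-4) containing a 3D variable — the
#' layout produced by tomographic reconstruction pipelines varies, so no
#' particular schema is assumed. If `variable` is not given, the file must
#' contain exactly one 3D variable. Voxel spacing is recovered from the
#' variable's coordinate (dimension) variables when they are evenly
#' spaced; otherwise it defaults to 1 with a warning.
#'
#' @param path path to a netCDF file.
#' @param variable name of the 3D variable to read, or `NULL` to use the
#'   unique one.
#' @return a [Volume-class]; the array is dimensioned (nz, ny, nx) in the
#'   order the variable's dimensions are defined, fastest first.
#' @export
readNetcdf <- function(path, variable = NULL) {
  if (!file.exists(path)) stop2("no input", "io")
  nc <- tryCatch(ncdf4::nc_open(path),
                 error = function(e) stop2(conditionMessage(e), "io"))
  on.exit(ncdf4::nc_close(nc))
  vars3d <- Filter(function(v) v$ndims == 3L, nc$var)
  if (length(vars3d) == 0L) stop2("no volume found", "io")
  if (is.null(variable)) {
    if (length(vars3d) > 1L) stop2("ambiguous variable", "io")
    v <- vars3d[[1]]
  } else {
    if (!variable %in% names(vars3d)) stop2("no volume found", "io")
    v <- vars3d[[variable]]
  }
  u <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
  spacing <- vapply(v$dim, function(dd) {
    vals <- dd$vals
    if (length(vals) < 2L) return(1)
    st <- diff(vals)
    if (all(abs(st - st[1]) < 1e-9 * max(abs(st[1]), 1)) && st[1] > 0) {
      st[1]
    } else {
      warning("uneven coordinate spacing for dimension ", dd$name,
              "; using 1")
      1
    }
  }, numeric(1))
  gatt <- ncdf4::ncatt_get(nc, 0, "gsv_levels")
  gsv <- if (gatt$hasatt) gatt$value else 65536
  Volume(u, spacing = spacing, gsvLevels = gsv, provenance = path)
}

#' Write a volume as netCDF
#'
#' Stores the intensities as a double variable named `volume` dimensioned
#' (z, y, x) with z fastest, coordinate variables carrying the voxel
#' spacing in micrometres, and the gsv level count as a global attribute.
#'
#' @param volume a [Volume-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetcdf <- function(volume, path) {
  d <- dim(volume)
  sp <- volSpacing(volume)
  dims <- list(
    ncdf4::ncdim_def("z", "um", (seq_len(d[1]) - 1) * sp[1]),
    ncdf4::ncdim_def("y", "um", (seq_len(d[2]) - 1) * sp[2]),
    ncdf4::ncdim_def("x", "um", (seq_len(d[3]) - 1) * sp[3])
  )
  var <- ncdf4::ncvar_def("volume", "intensity", dims, prec = "double")
  nc <- tryCatch(ncdf4::nc_create(path, var),
                 error = function(e) stop2(conditionMessage(e), "io"))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, volData(volume))
  ncdf4::ncatt_put(nc, 0, "gsv_levels", gsvLevels(volume))
  ncdf4::ncatt_put(nc, 0, "provenance", provenance(volume))
  invisible(path)
}
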