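# Volume container and the three volume formats: every format must
# round-trip data (within its quantization), shape and spacing.

test_that("Volume validity catches malformed inputs", {
  expect_error(Volume(array(0, c(2, 2)), 1, 256), "3D")
  expect_error(Volume(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(Volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  expect_error(Volume(array(0, c(2, 2, 2)), gsvLevels = 1), "gsvLevels")
  v <- Volume(array(1:8, c(2, 2, 2)), spacing = 10.7, gsvLevels = 256,
              provenance = "test")
  expect_identical(dim(v), c(2L, 2L, 2L))
  expect_equal(volSpacing(v), rep(10.7, 3))
  expect_equal(gsvLevels(v), 256)
  expect_output(show(v), "2 x 2 x 2")
})

test_that("TIFF stacks round-trip with bit depth driving gsv levels", {
  set.seed(1)
  u8 <- array(sample(0:255, 5 * 16 * 16, replace = TRUE), c(5, 16, 16))
  v8 <- Volume(u8, gsvLevels = 256)
  p <- tempfile(fileext = ".tif")
  writeTiffStack(v8, p)
  r8 <- readTiffStack(p)
  expect_identical(dim(r8), c(5L, 16L, 16L))
  expect_equal(gsvLevels(r8), 256)
  expect_equal(volData(r8), volData(v8))

  u16 <- array(sample(0:65535, 3 * 8 * 8, replace = TRUE), c(3, 8, 8))
  v16 <- Volume(u16, gsvLevels = 65536)
  writeTiffStack(v16, p)
  r16 <- readTiffStack(p)
  expect_equal(gsvLevels(r16), 65536)
  expect_equal(volData(r16), volData(v16))
})

test_that("TIFF writer rescales out-of-range data with a warning", {
  v <- Volume(array(seq(-5, 300.2, length.out = 12), c(3, 2, 2)),
              gsvLevels = 256)
  p <- tempfile(fileext = ".tif")
  expect_warning(writeTiffStack(v, p), "rescal")
  r <- readTiffStack(p)
  # round trip equal after inverting the documented linear rescale
  back <- volData(r) / 255 * (300.2 - (-5)) + (-5)
  expect_equal(back, volData(v), tolerance = 1e-2)
})

test_that("TIFF reader rejects RGB pages", {
  p <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), p)
  expect_error(readTiffStack(p), "photometric")
})

test_that("netCDF round-trips data, shape, spacing and gsv levels", {
  set.seed(2)
  v <- Volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
              spacing = c(10.7, 10.7, 10.7), gsvLevels = 65536)
  p <- tempfile(fileext = ".nc")
  writeNetcdf(v, p)
  r <- readNetcdf(p)
  expect_identical(dim(r), c(4L, 5L, 6L))
  expect_equal(volData(r), volData(v))
  expect_equal(volSpacing(r), c(10.7, 10.7, 10.7))
  expect_equal(gsvLevels(r), 65536)
  # second write/read cycle is bitwise stable
  p2 <- tempfile(fileext = ".nc")
  writeNetcdf(r, p2)
  expect_identical(volData(readNetcdf(p2)), volData(r))
})

test_that("netCDF reader enforces the single-3D-variable contract", {
  p <- tempfile(fileext = ".nc")
  d <- list(ncdf4::ncdim_def("z", "", 1:3), ncdf4::ncdim_def("y", "", 1:3),
            ncdf4::ncdim_def("x", "", 1:3))
  v1 <- ncdf4::ncvar_def("a", "", d, prec = "double")
  v2 <- ncdf4::ncvar_def("b", "", d, prec = "double")
  nc <- ncdf4::nc_create(p, list(v1, v2))
  ncdf4::ncvar_put(nc, v1, array(1, c(3, 3, 3)))
  ncdf4::ncvar_put(nc, v2, array(2, c(3, 3, 3)))
  ncdf4::nc_close(nc)
  expect_error(readNetcdf(p), "ambiguous variable")
  expect_equal(volData(readNetcdf(p, "b"))[1], 2)

  # only scalar/1D variables -> no volume
  p2 <- tempfile(fileext = ".nc")
  s <- ncdf4::ncvar_def("s", "", d[1], prec = "double")
  nc2 <- ncdf4::nc_create(p2, s)
  ncdf4::ncvar_put(nc2, s, 1:3)
  ncdf4::nc_close(nc2)
  expect_error(readNetcdf(p2), "no volume found")
})

test_that("DICOM series round-trips integer volumes exactly", {
  set.seed(3)
  u <- array(sample(0:4000, 4 * 12 * 10, replace = TRUE), c(4, 12, 10))
  v <- Volume(u, spacing = c(10.7, 10.7, 10.7), gsvLevels = 65536)
  d <- file.path(tempdir(), "dcm-rt")
  unlink(d, recursive = TRUE)
  writeDicomSeries(v, d)
  r <- readDicomSeries(d)
  expect_identical(dim(r), dim(v))
  expect_equal(volData(r), volData(v))
  expect_equal(volSpacing(r), volSpacing(v), tolerance = 1e-9)
  expect_equal(gsvLevels(r), 65536)
  # rewriting the read-back volume is bitwise stable
  d2 <- file.path(tempdir(), "dcm-rt2")
  unlink(d2, recursive = TRUE)
  writeDicomSeries(r, d2)
  f1 <- list.files(d, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(lapply(f1, readBin, what = raw(), n = 1e6),
                   lapply(f2, readBin, what = raw(), n = 1e6))
})

test_that("DICOM reader applies rescale slope and intercept", {
  # stored value 100 with slope 2, intercept -1000 must read as -800
  v <- Volume(array(-800, c(3, 4, 4)), gsvLevels = 65536)
  d <- file.path(tempdir(), "dcm-rescale")
  unlink(d, recursive = TRUE)
  writeDicomSeries(v, d, slope = 2, intercept = -1000)
  r <- readDicomSeries(d)
  expect_true(all(volData(r) == -800))
})

test_that("DICOM slices are sorted by position, not file name", {
  u <- array(0, c(3, 2, 2))
  u[1, , ] <- 10
  u[2, , ] <- 20
  u[3, , ] <- 30
  v <- Volume(u, gsvLevels = 256)
  d <- file.path(tempdir(), "dcm-sort")
  unlink(d, recursive = TRUE)
  writeDicomSeries(v, d)
  # shuffle: rename files so lexical order disagrees with position
  f <- list.files(d, full.names = TRUE)
  tmp <- file.path(d, "zz_0001.dcm")
  file.rename(f[1], tmp) # slice at position 0 now sorts last by name
  r <- readDicomSeries(d)
  expect_equal(volData(r)[, 1, 1], c(10, 20, 30))
})

test_that("DICOM reader rejects empty directories and mixed series", {
  d <- file.path(tempdir(), "dcm-empty")
  unlink(d, recursive = TRUE)
  dir.create(d)
  expect_error(readDicomSeries(d), "no input")

  d2 <- file.path(tempdir(), "dcm-mixed")
  unlink(d2, recursive = TRUE)
  writeDicomSeries(Volume(array(1, c(2, 4, 4))), d2)
  other <- file.path(tempdir(), "dcm-other")
  unlink(other, recursive = TRUE)
  writeDicomSeries(Volume(array(2, c(2, 4, 4))), other)
  file.copy(list.files(other, full.names = TRUE)[1],
            file.path(d2, "intruder.dcm"))
  expect_error(readDicomSeries(d2), "inconsistent series")
})

test_that("non-integer intensities survive DICOM quantization", {
  set.seed(5)
  v <- Volume(array(rnorm(2 * 6 * 6, 100, 30), c(2, 6, 6)),
              gsvLevels = 65536)
  d <- file.path(tempdir(), "dcm-float")
  unlink(d, recursive = TRUE)
  expect_warning(writeDicomSeries(v, d), "rescale")
  r <- readDicomSeries(d)
  span <- diff(range(volData(v)))
  expect_equal(volData(r), volData(v), tolerance = span / 65535)
})

test_that("readVolume/writeVolume dispatch on extension", {
  v <- stepPhantom(8)
  p <- tempfile(fileext = ".nc")
  writeVolume(v, p)
  expect_equal(volData(readVolume(p)), volData(v))
  expect_error(readVolume(tempfile(fileext = ".xyz")), "format")
})

test_that("written DICOM and netCDF parse identically in python", {
  # independent readers (pydicom, scipy.io) confirm the byte formats
  py <- Sys.which("python")
  expect_true(nzchar(py))
  u <- array(sample(0:255, 3 * 5 * 4, replace = TRUE), c(3, 5, 4))
  v <- Volume(u, spacing = c(2, 3, 4), gsvLevels = 256)
  d <- file.path(tempdir(), "dcm-py")
  unlink(d, recursive = TRUE)
  writeDicomSeries(v, d)
  nc <- tempfile(fileext = ".nc")
  writeNetcdf(v, nc)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, glob, numpy as np",
    "import pydicom",
    "from scipy.io import netcdf_file",
    "d, nc = sys.argv[1], sys.argv[2]",
    "sl = [pydicom.dcmread(f) for f in sorted(glob.glob(d + '/*.dcm'))]",
    "sl.sort(key=lambda s: float(s.ImagePositionPatient[2]))",
    "vol = np.stack([s.pixel_array for s in sl])",
    "print('dcm', vol.shape[0], vol.shape[1], vol.shape[2],",
    "      int(vol.sum()), float(sl[0].PixelSpacing[0]))",
    "f = netcdf_file(nc, 'r', mmap=False)",
    "arr = f.variables['volume'][:]",
    "print('nc', int(np.asarray(arr).sum()))"
  ), script)
  out <- system2(py, c(script, d, nc), stdout = TRUE)
  dcm <- strsplit(out[1], " ")[[1]]
  # pydicom stacks slices as (z, rows, cols) = (nz, ny, nx)
  expect_equal(as.integer(dcm[2:4]), dim(v))
  expect_equal(as.numeric(dcm[5]), sum(u))
  expect_equal(as.numeric(dcm[6]), 3 / 1000) # PixelSpacing row (y), mm
  expect_equal(as.numeric(strsplit(out[2], " ")[[1]][2]), sum(u))
})
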