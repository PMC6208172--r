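# Minimal single-frame DICOM series I/O, Explicit VR Little Endian only.
# Covers what axial CT exports need: rescale slope/intercept, pixel and
# slice spacing, slice ordering by ImagePositionPatient with InstanceNumber
# fallback, and 8/16-bit unsigned pixel data. Not a general DICOM
# implementation (no sequences, no compressed transfer syntaxes).

.dcmUIDRoot <- "1.2.826.0.1.3680043.9999"
.dcmTS_ExplicitLE <- "1.2.840.10008.1.2.1"
.dcmLongVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# manual little-endian packing: unsigned 16-bit values up to 65535 do not
# fit R's signed writeBin(size = 2) without warnings
.rawU16 <- function(x) {
  x <- as.integer(x)
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}
.rawU32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")

# one data element in Explicit VR LE encoding
.dcmElement <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(paste(value, collapse = "\\"))
  }
  if (length(value) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value <- c(value, pad)
  }
  head <- c(.rawU16(group), .rawU16(element), charToRaw(vr))
  if (vr %in% .dcmLongVRs) {
    c(head, as.raw(c(0L, 0L)), .rawU32(length(value)), value)
  } else {
    if (length(value) > 65535L) stop2("element too long", "io")
    c(head, .rawU16(length(value)), value)
  }
}

.dcmNum <- function(x) sprintf("%.10g", x)

#' Write a volume as a single-frame DICOM series
#'
#' One Explicit-VR-little-endian file per z slice
#' (`slice_0001.dcm`, ...), 16-bit unsigned pixels with rescale
#' slope/intercept so that `slope * stored + intercept` reproduces the
#' intensities. Integer intensities already in \[0, 65535\] are stored
#' verbatim (slope 1, intercept 0); anything else is affinely quantized to
#' the 16-bit range with a warning. Spacing is written in millimetres as
#' DICOM requires (PixelSpacing, SpacingBetweenSlices) and converted back
#' to micrometres on read. UIDs are derived deterministically from the
#' content so rewriting the same volume is bitwise stable.
#'
#' @param volume a [Volume-class].
#' @param directory output directory (created if needed).
#' @param slope,intercept optionally force the rescale pair; stored values
#'   are then `round((v - intercept) / slope)`.
#' @return the directory, invisibly.
#' @export
writeDicomSeries <- function(volume, directory, slope = NULL,
                             intercept = NULL) {
  u <- volData(volume)
  d <- dim(u)
  sp_mm <- volSpacing(volume) / 1000
  if (is.null(slope) || is.null(intercept)) {
    if (all(u == round(u)) && min(u) >= 0 && max(u) <= 65535) {
      slope <- 1
      intercept <- 0
    } else {
      warning("intensities not representable as 16-bit integers; ",
              "storing with affine rescale")
      intercept <- min(u)
      slope <- if (max(u) > min(u)) (max(u) - min(u)) / 65535 else 1
    }
  }
  stored <- round((u - intercept) / slope)
  if (min(stored) < 0 || max(stored) > 65535) {
    stop2("stored values exceed 16-bit range under given rescale", "io")
  }
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop2("cannot create output directory", "io")
  }
  seriesUID <- sprintf("%s.%d.%d.%d.%.0f", .dcmUIDRoot, d[1], d[2], d[3],
                       sum(as.numeric(stored)) %% 1e7)
  sopClass <- "1.2.840.10008.5.1.4.1.1.7" # secondary capture
  for (i in seq_len(d[1])) {
    sopUID <- sprintf("%s.%d", seriesUID, i)
    pix <- .rawU16(as.vector(t(stored[i, , ])))
    meta <- c(
      .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      .dcmElement(0x0002, 0x0002, "UI", sopClass),
      .dcmElement(0x0002, 0x0003, "UI", sopUID),
      .dcmElement(0x0002, 0x0010, "UI", .dcmTS_ExplicitLE),
      .dcmElement(0x0002, 0x0012, "UI", paste0(.dcmUIDRoot, ".1"))
    )
    body <- c(
      .dcmElement(0x0008, 0x0016, "UI", sopClass),
      .dcmElement(0x0008, 0x0018, "UI", sopUID),
      .dcmElement(0x0008, 0x0060, "CS", "CT"),
      .dcmElement(0x0018, 0x0088, "DS", .dcmNum(sp_mm[1])),
      .dcmElement(0x0020, 0x000E, "UI", seriesUID),
      .dcmElement(0x0020, 0x0013, "IS", as.character(i)),
      .dcmElement(0x0020, 0x0032, "DS",
                  c("0", "0", .dcmNum((i - 1) * sp_mm[1]))),
      .dcmElement(0x0020, 0x0037, "DS", c("1", "0", "0", "0", "1", "0")),
      .dcmElement(0x0028, 0x0002, "US", .rawU16(1L)),
      .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcmElement(0x0028, 0x0010, "US", .rawU16(d[2])),
      .dcmElement(0x0028, 0x0011, "US", .rawU16(d[3])),
      .dcmElement(0x0028, 0x0030, "DS",
                  c(.dcmNum(sp_mm[2]), .dcmNum(sp_mm[3]))),
      .dcmElement(0x0028, 0x0100, "US", .rawU16(16L)),
      .dcmElement(0x0028, 0x0101, "US", .rawU16(16L)),
      .dcmElement(0x0028, 0x0102, "US", .rawU16(15L)),
      .dcmElement(0x0028, 0x0103, "US", .rawU16(0L)),
      .dcmElement(0x0028, 0x1052, "DS", .dcmNum(intercept)),
      .dcmElement(0x0028, 0x1053, "DS", .dcmNum(slope)),
      .dcmElement(0x7FE0, 0x0010, "OW", pix)
    )
    metaLen <- .dcmElement(0x0002, 0x0000, "UL", .rawU32(length(meta)))
    out <- c(raw(128L), charToRaw("DICM"), metaLen, meta, body)
    ok <- tryCatch(
      writeBin(out, file.path(directory, sprintf("slice_%04d.dcm", i))),
      error = function(e) stop2(conditionMessage(e), "io")
    )
  }
  invisible(directory)
}

# parse one Explicit-VR-LE DICOM file into a tag -> raw-value list
.dcmParseFile <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop2(paste0("not a DICOM file: ", path), "io")
  }
  u16 <- function(at) readBin(bytes[at + 0:1], integer(), size = 2L,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(bytes[at + 0:3], integer(), size = 4L,
                              endian = "little")
  pos <- 133L
  tags <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- u16(pos)
    element <- u16(pos + 2L)
    vr <- rawToChar(bytes[pos + 4:5])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop2("unsupported transfer syntax (implicit VR?)", "io")
    }
    if (vr %in% .dcmLongVRs) {
      len <- u32(pos + 8L)
      valAt <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      valAt <- pos + 8L
    }
    if (len < 0 || valAt + len - 1L > n) stop2("truncated DICOM file", "io")
    key <- sprintf("%04X%04X", group, element)
    tags[[key]] <- list(vr = vr,
                        value = bytes[seq.int(valAt, length.out = len)])
    pos <- valAt + len
  }
  tags
}

.dcmString <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v$value[v$value != as.raw(0L)]))
}

.dcmNumbers <- function(tags, key) {
  s <- .dcmString(tags, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcmU16 <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  readBin(v$value, integer(), size = 2L, signed = FALSE, endian = "little")
}

#' Read a single-frame DICOM series as a volume
#'
#' All parseable DICOM files in the directory must share one series
#' instance UID. Slices are ordered by the slice-normal projection of
#' ImagePositionPatient (ascending), falling back to InstanceNumber when
#' positions are absent or tied. Rescale slope/intercept are applied, so
#' returned intensities are in output units; voxel spacing comes from
#' PixelSpacing and SpacingBetweenSlices (or inter-slice position
#' differences), converted from millimetres to micrometres. Missing
#' spacing attributes default to 1 micrometre with a warning. The gsv
#' level count is 2^BitsStored.
#'
#' @param directory directory containing the series.
#' @return a [Volume-class].
#' @export
readDicomSeries <- function(directory) {
  if (!dir.exists(directory)) stop2("no input", "io")
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop2("no input", "io")
  slices <- lapply(sort(files), .dcmParseFile)

  series <- vapply(slices, function(t) {
    s <- .dcmString(t, "0020000E")
    if (is.null(s)) "" else s
  }, character(1))
  if (length(unique(series)) > 1L) stop2("inconsistent series", "io")

  orient <- .dcmNumbers(slices[[1]], "00200037")
  normal <- if (!is.null(orient) && length(orient) == 6L) {
    r <- orient[1:3]
    cvec <- orient[4:6]
    c(r[2] * cvec[3] - r[3] * cvec[2],
      r[3] * cvec[1] - r[1] * cvec[3],
      r[1] * cvec[2] - r[2] * cvec[1])
  } else {
    c(0, 0, 1)
  }
  pos <- vapply(slices, function(t) {
    p <- .dcmNumbers(t, "00200032")
    if (is.null(p) || length(p) != 3L) NA_real_ else sum(p * normal)
  }, numeric(1))
  inst <- vapply(slices, function(t) {
    v <- .dcmNumbers(t, "00200013")
    if (is.null(v)) NA_real_ else v[1]
  }, numeric(1))
  ord <- if (anyNA(pos)) order(inst) else order(pos, inst)
  slices <- slices[ord]
  pos <- pos[ord]

  first <- slices[[1]]
  rows <- .dcmU16(first, "00280010")
  cols <- .dcmU16(first, "00280011")
  bitsAlloc <- .dcmU16(first, "00280100")
  bitsStored <- .dcmU16(first, "00280101")
  if (is.null(rows) || is.null(cols) || is.null(bitsAlloc)) {
    stop2("missing image dimensions", "io")
  }
  if (is.null(bitsStored)) bitsStored <- bitsAlloc
  if (!bitsAlloc %in% c(8L, 16L)) {
    stop2("unsupported bits allocated", "io")
  }

  pxSp <- .dcmNumbers(first, "00280030")
  zSp <- .dcmNumbers(first, "00180088")
  if (is.null(zSp) && !anyNA(pos) && length(pos) > 1L) {
    dz <- diff(pos)
    if (all(abs(dz - dz[1]) < 1e-9) && dz[1] > 0) zSp <- dz[1]
  }
  if (is.null(pxSp) || length(pxSp) != 2L) {
    warning("missing PixelSpacing; defaulting to 1")
    pxSp <- c(1e-3, 1e-3)
  }
  if (is.null(zSp)) {
    if (length(slices) > 1L) warning("missing slice spacing; defaulting to 1")
    zSp <- 1e-3
  }

  u <- array(0, c(length(slices), rows, cols))
  for (i in seq_along(slices)) {
    t <- slices[[i]]
    pix <- t[["7FE00010"]]
    if (is.null(pix)) stop2("missing pixel data", "io")
    vals <- readBin(pix$value, integer(), n = rows * cols,
                    size = bitsAlloc %/% 8L, signed = FALSE,
                    endian = "little")
    slope <- .dcmNumbers(t, "00281053")
    icpt <- .dcmNumbers(t, "00281052")
    if (is.null(slope)) slope <- 1
    if (is.null(icpt)) icpt <- 0
    u[i, , ] <- matrix(slope * vals + icpt, nrow = rows, byrow = TRUE)
  }
  Volume(u, spacing = c(zSp, pxSp[1], pxSp[2]) * 1000,
         gsvLevels = 2^bitsStored, provenance = directory)
}
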