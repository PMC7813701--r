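# Minimal DICOM support: file-based ingest of one classic single-frame 3D
# T1 series and a matching writer used to exercise the ingest path.
# Scope: explicit-VR little-endian transfer syntax only, monochrome 16-bit
# pixels, no sequences or compressed syntaxes.

.dcmTransferSyntax <- "1.2.840.10008.1.2.1"    # explicit VR little endian
.dcmSOPClassMR <- "1.2.840.10008.5.1.4.1.1.4"  # MR Image Storage

#' @noRd
.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

#' @noRd
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# encode one explicit-VR element; value must be raw
#' @noRd
.dcmElement <- function(group, elem, vr, value) {
  if (length(value) %% 2 == 1)
    value <- c(value, as.raw(if (vr == "UI") 0L else 0x20))
  hdr <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(hdr, as.raw(c(0, 0)), .u32(length(value)), value)
  else c(hdr, .u16(length(value)), value)
}

#' @noRd
.dcmStr <- function(group, elem, vr, s) .dcmElement(group, elem, vr, charToRaw(s))

#' @noRd
.dcmUS <- function(group, elem, v) .dcmElement(group, elem, "US", .u16(v))

#' @noRd
.dcmDS <- function(group, elem, v)
  .dcmStr(group, elem, "DS", paste(sprintf("%.10g", v), collapse = "\\"))

#' Write a volume as a synthetic DICOM series
#'
#' Writes one explicit-VR little-endian single-frame DICOM file per axial
#' slice (16-bit monochrome with rescale slope/intercept, position and
#' orientation tags derived from the volume's affine). This is a minimal,
#' synthetic series intended for testing the ingest path and lightweight
#' interchange, not a full DICOM implementation.
#'
#' @param vol a [BrainVolume-class].
#' @param dir output directory (created if needed).
#' @param seriesUID Series Instance UID; a fixed default keeps output
#'   deterministic.
#' @return Character vector of file paths, invisibly.
#' @export
writeDicomSeries <- function(vol, dir,
                             seriesUID = "1.2.826.0.1.3680043.9999.1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- gridDim(vol)
  if (d[3] < 2) argumentError("a series needs at least 2 slices")
  Alps <- diag(c(-1, -1, 1, 1)) %*% vol@affine  # RAS -> LPS
  dc <- sqrt(sum(Alps[1:3, 1]^2))  # column spacing (index 1 = column)
  dr <- sqrt(sum(Alps[1:3, 2]^2))  # row spacing    (index 2 = row)
  F1 <- Alps[1:3, 1] / dc
  F2 <- Alps[1:3, 2] / dr

  rngv <- range(vol@data)
  slope <- if (diff(rngv) > 0) diff(rngv) / 65535 else 1
  intercept <- rngv[1]
  stored <- round((vol@data - intercept) / slope)

  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- Alps[1:3, 4] + (k - 1) * Alps[1:3, 3]
    # DICOM pixel order is row-major (columns fastest) == column-major
    # flattening of our (column, row) slice
    pixRaw <- writeBin(as.integer(stored[, , k]), raw(), size = 2,
                       endian = "little")
    sopUID <- sprintf("%s.%d", seriesUID, k)
    ds <- c(.dcmStr(0x0008, 0x0016, "UI", .dcmSOPClassMR),
            .dcmStr(0x0008, 0x0018, "UI", sopUID),
            .dcmStr(0x0008, 0x0060, "CS", "MR"),
            .dcmStr(0x0020, 0x000D, "UI", paste0(seriesUID, ".0")),
            .dcmStr(0x0020, 0x000E, "UI", seriesUID),
            .dcmStr(0x0020, 0x0013, "IS", as.character(k)),
            .dcmDS(0x0020, 0x0032, ipp),
            .dcmDS(0x0020, 0x0037, c(F1, F2)),
            .dcmUS(0x0028, 0x0002, 1),
            .dcmStr(0x0028, 0x0004, "CS", "MONOCHROME2"),
            .dcmUS(0x0028, 0x0010, d[2]),  # Rows
            .dcmUS(0x0028, 0x0011, d[1]),  # Columns
            .dcmDS(0x0028, 0x0030, c(dr, dc)),
            .dcmUS(0x0028, 0x0100, 16),
            .dcmUS(0x0028, 0x0101, 16),
            .dcmUS(0x0028, 0x0102, 15),
            .dcmUS(0x0028, 0x0103, 0),
            .dcmDS(0x0028, 0x1052, intercept),
            .dcmDS(0x0028, 0x1053, slope),
            .dcmElement(0x7FE0, 0x0010, "OW", pixRaw))
    metaBody <- c(.dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
                  .dcmStr(0x0002, 0x0002, "UI", .dcmSOPClassMR),
                  .dcmStr(0x0002, 0x0003, "UI", sopUID),
                  .dcmStr(0x0002, 0x0010, "UI", .dcmTransferSyntax))
    meta <- c(.dcmElement(0x0002, 0x0000, "UL", .u32(length(metaBody))),
              metaBody)
    paths[k] <- file.path(dir, sprintf("slice%04d.dcm", k))
    con <- file(paths[k], "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, ds), con)
    close(con)
  }
  invisible(paths)
}

# parse one explicit-VR little-endian DICOM file into a tag list
#' @noRd
.dcmParse <- function(path) {
  buf <- readBin(path, raw(), file.size(path))
  if (length(buf) < 160 || rawToChar(buf[129:132]) != "DICM")
    voxnormStop("voxnorm_dicom_error", "%s: not a DICOM file (no DICM magic)",
                path)
  pos <- 133L
  tags <- list()
  n <- length(buf)
  rdU16 <- function(at) readBin(buf[at:(at + 1)], "integer", size = 2,
                                endian = "little", signed = FALSE)
  rdU32 <- function(at) readBin(buf[at:(at + 3)], "integer", size = 4,
                                endian = "little")
  while (pos + 7 <= n) {
    group <- rdU16(pos); elem <- rdU16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      voxnormStop("voxnorm_dicom_error",
                  "%s: implicit VR or unsupported transfer syntax", path)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- rdU32(pos + 8L); body <- pos + 12L
    } else {
      len <- rdU16(pos + 6L); body <- pos + 8L
    }
    if (len < 0 || body + len - 1 > n)
      voxnormStop("voxnorm_dicom_error", "%s: truncated element (%04x,%04x)",
                  path, group, elem)
    key <- sprintf("%04X%04X", group, elem)
    tags[[key]] <- list(vr = vr,
                        raw = if (len > 0) buf[body:(body + len - 1)] else raw(0))
    pos <- body + len
  }
  tags
}

#' @noRd
.dcmGet <- function(tags, key, path, numeric = TRUE) {
  el <- tags[[key]]
  if (is.null(el))
    voxnormStop("voxnorm_dicom_error", "%s: missing required tag (%s,%s)",
                path, substr(key, 1, 4), substr(key, 5, 8))
  if (el$vr == "US")
    return(readBin(el$raw, "integer", n = length(el$raw) / 2, size = 2,
                   endian = "little", signed = FALSE))
  s <- trimws(rawToChar(el$raw[el$raw != as.raw(0)]))
  if (numeric) as.numeric(strsplit(s, "\\\\")[[1]]) else s
}

#' Ingest a DICOM series as a volume
#'
#' Reads a directory holding one classic single-frame 3D T1 series
#' (explicit-VR little endian): slices are sorted by the projection of
#' their Image Position (Patient) onto the slice normal, the affine is
#' assembled from position/orientation/spacing tags (converted from DICOM
#' LPS to RAS+ world coordinates), and stored values are rescaled with the
#' slope/intercept tags.
#'
#' @param dir directory containing the `.dcm` files of exactly one series.
#' @return A [BrainVolume-class].
#' @export
readDicomSeries <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0)
    voxnormStop("voxnorm_dicom_error", "no .dcm files under %s", dir)
  if (length(files) == 1)
    voxnormStop("voxnorm_dicom_error",
                "single-slice input is not volumetric: %s", dir)
  parsed <- lapply(files, .dcmParse)
  uids <- vapply(seq_along(files), function(i)
    .dcmGet(parsed[[i]], "0020000E", files[i], numeric = FALSE), "")
  if (length(unique(uids)) > 1)
    voxnormStop("voxnorm_dicom_error",
                "multiple series mixed in one directory: %s",
                paste(unique(uids), collapse = ", "))

  first <- parsed[[1]]
  orient <- .dcmGet(first, "00200037", files[1])
  if (length(orient) != 6)
    voxnormStop("voxnorm_dicom_error", "%s: bad orientation tag", files[1])
  F1 <- orient[1:3]; F2 <- orient[4:6]
  normal <- c(F1[2] * F2[3] - F1[3] * F2[2],
              F1[3] * F2[1] - F1[1] * F2[3],
              F1[1] * F2[2] - F1[2] * F2[1])
  ipps <- t(vapply(seq_along(files), function(i)
    .dcmGet(parsed[[i]], "00200032", files[i]), numeric(3)))
  ord <- order(ipps %*% normal)
  parsed <- parsed[ord]; files <- files[ord]; ipps <- ipps[ord, , drop = FALSE]

  rows <- .dcmGet(first, "00280010", files[1])
  cols <- .dcmGet(first, "00280011", files[1])
  spacing <- .dcmGet(first, "00280030", files[1])  # (row, col)
  nz <- length(files)
  arr <- array(0, c(cols, rows, nz))
  for (i in seq_len(nz)) {
    tg <- parsed[[i]]
    slope <- tryCatch(.dcmGet(tg, "00281053", files[i]), error = function(e) 1)
    inter <- tryCatch(.dcmGet(tg, "00281052", files[i]), error = function(e) 0)
    el <- tg[["7FE00010"]]
    if (is.null(el))
      voxnormStop("voxnorm_dicom_error", "%s: no pixel data", files[i])
    signed <- isTRUE(.dcmGet(tg, "00280103", files[i]) == 1)
    v <- readBin(el$raw, "integer", n = rows * cols, size = 2,
                 endian = "little", signed = signed)
    arr[, , i] <- matrix(v, nrow = cols) * slope + inter
  }

  dz <- ipps[2, ] - ipps[1, ]
  Alps <- cbind(c(F1 * spacing[2], 0), c(F2 * spacing[1], 0), c(dz, 0),
                c(ipps[1, ], 1))
  A <- diag(c(-1, -1, 1, 1)) %*% Alps
  brainVolume(arr, A)
}
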