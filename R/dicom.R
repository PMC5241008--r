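## Minimal DICOM series codec: explicit-VR little-endian, uncompressed,
## one single-frame 16-bit monochrome image per file.  Covers the subset of
## the standard needed to exchange secondary-capture CT/MR volumes with
## their grid geometry; no private tags, no compressed transfer syntaxes.

.dcmUIDroot <- "1.2.826.0.1.3680043.9.7435"   # generic org root for UIDs

.dcmCounter <- new.env(parent = emptyenv())
.dcmCounter$n <- 0L

.dcmNewUID <- function(suffix) {
  .dcmCounter$n <- .dcmCounter$n + 1L
  paste(.dcmUIDroot, format(as.integer(Sys.time())), Sys.getpid(),
        .dcmCounter$n, suffix, sep = ".")
}

.dcmNum <- function(x) {
  # DS (decimal string) formatting, <= 16 chars per value
  vapply(x, function(v) formatC(v, digits = 10, format = "g"), "")
}

## ---- writer ---------------------------------------------------------------

.dcmElement <- function(group, element, vr, value) {
  # value: raw vector (already encoded) or character/numeric to encode
  payload <- if (is.raw(value)) value else {
    if (vr %in% c("DS", "IS", "CS", "LO", "SH", "UI"))
      charToRaw(paste(as.character(value), collapse = "\\"))
    else if (vr == "US")
      writeBin(as.integer(value), raw(), size = 2, endian = "little")
    else stop("unhandled VR in writer: ", vr)
  }
  if (length(payload) %% 2 == 1)
    payload <- c(payload, if (vr == "UI") as.raw(0) else charToRaw(" "))
  head <- c(writeBin(as.integer(c(group, element)), raw(), size = 2,
                     endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    head <- c(head, as.raw(c(0, 0)),
              writeBin(length(payload), raw(), size = 4, endian = "little"))
  } else {
    head <- c(head, writeBin(length(payload), raw(), size = 2,
                             endian = "little"))
  }
  c(head, payload)
}

#' Write a volume as a DICOM series (one file per slice)
#'
#' Explicit-VR little-endian secondary-capture objects with 16-bit signed
#' pixels; voxel values must be integers representable in 16 bits (scanner
#' data are).  Geometry is carried by ImagePositionPatient,
#' ImageOrientationPatient, PixelSpacing and the slice positions.
#'
#' @param vol an [ImageVolume-class] with integer-valued voxels in
#'   `[-32768, 32767]`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDicomSeries <- function(vol, dir) {
  stopifnot(is(vol, "ImageVolume"))
  vox <- vol@voxels
  if (max(abs(vox - round(vox))) > 0)
    stop("DICOM output requires integer-valued voxels")
  if (min(vox) < -32768 || max(vox) > 32767)
    stop("voxel values outside the signed 16-bit range")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vox)
  studyUID <- .dcmNewUID("1")
  seriesUID <- .dcmNewUID("2")
  iop <- c(vol@direction[, 1], vol@direction[, 2])
  for (k in seq_len(d[3])) {
    ipp <- vol@origin + vol@direction[, 3] * vol@spacing[3] * (k - 1)
    pix <- writeBin(as.integer(vox[, , k]), raw(), size = 2,
                    endian = "little")
    tsuid <- .dcmElement(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1")
    # file meta group length element (0002,0000), UL
    gl <- c(writeBin(as.integer(c(0x0002L, 0x0000L)), raw(), size = 2,
                     endian = "little"),
            charToRaw("UL"),
            writeBin(4L, raw(), size = 2, endian = "little"),
            writeBin(length(tsuid), raw(), size = 4, endian = "little"))
    body <- c(
      .dcmElement(0x0008L, 0x0016L, "UI",
                  "1.2.840.10008.5.1.4.1.1.7"),          # secondary capture
      .dcmElement(0x0008L, 0x0018L, "UI",
                  paste(seriesUID, k, sep = ".")),
      .dcmElement(0x0008L, 0x0060L, "CS", vol@modality),
      .dcmElement(0x0018L, 0x0050L, "DS", .dcmNum(vol@spacing[3])),
      .dcmElement(0x0020L, 0x000DL, "UI", studyUID),
      .dcmElement(0x0020L, 0x000EL, "UI", seriesUID),
      .dcmElement(0x0020L, 0x0013L, "IS", as.character(k)),
      .dcmElement(0x0020L, 0x0032L, "DS", .dcmNum(ipp)),
      .dcmElement(0x0020L, 0x0037L, "DS", .dcmNum(iop)),
      .dcmElement(0x0028L, 0x0002L, "US", 1L),
      .dcmElement(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
      .dcmElement(0x0028L, 0x0010L, "US", d[2]),          # Rows
      .dcmElement(0x0028L, 0x0011L, "US", d[1]),          # Columns
      .dcmElement(0x0028L, 0x0030L, "DS",
                  .dcmNum(vol@spacing[c(2, 1)])),         # row\col spacing
      .dcmElement(0x0028L, 0x0100L, "US", 16L),
      .dcmElement(0x0028L, 0x0101L, "US", 16L),
      .dcmElement(0x0028L, 0x0102L, "US", 15L),
      .dcmElement(0x0028L, 0x0103L, "US", 1L),            # signed
      .dcmElement(0x7FE0L, 0x0010L, "OW", pix))
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(gl, con)
    writeBin(tsuid, con)
    writeBin(body, con)
    close(con)
  }
  invisible(dir)
}

## ---- reader ---------------------------------------------------------------

.dcmReadFile <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  buf <- readBin(con, "raw", sz)
  if (length(buf) < 132 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  tags <- list()
  u16 <- function(at) readBin(buf[at:(at + 1)], "integer", 1, size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(buf[at:(at + 3)], "integer", 1, size = 4,
                              endian = "little")
  while (pos + 7 <= length(buf)) {
    group <- u16(pos); element <- u16(pos + 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8)
      dataAt <- pos + 12L
    } else {
      len <- u16(pos + 6)
      dataAt <- pos + 8L
    }
    if (len < 0 || dataAt + len - 1 > length(buf))
      stop("corrupt DICOM element at byte ", pos, " in ", path)
    key <- sprintf("%04X,%04X", group, element)
    payload <- if (len > 0) buf[dataAt:(dataAt + len - 1)] else raw(0)
    tags[[key]] <- list(vr = vr, data = payload)
    pos <- dataAt + len
  }
  tags
}

.dcmString <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$data))
}

.dcmNumeric <- function(tags, key) {
  s <- .dcmString(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}

.dcmUS <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$data, "integer", length(el$data) / 2, size = 2, signed = FALSE,
          endian = "little")
}

#' Read a DICOM series directory as a volume
#'
#' All `.dcm` files in `dir` must belong to a single series (one
#' SeriesInstanceUID) with uniform in-plane spacing and uniform slice
#' spacing; otherwise an error names the offending attribute.
#'
#' @param dir directory containing one DICOM series.
#' @return an [ImageVolume-class].
#' @export
readDicomSeries <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) stop("no DICOM files found in ", dir)
  slices <- lapply(files, .dcmReadFile)
  uid <- vapply(slices, function(t) .dcmString(t, "0020,000E"), "")
  if (length(unique(uid)) != 1)
    stop("mixed-series directory: multiple SeriesInstanceUID values (",
         paste(unique(uid), collapse = ", "), ")")
  ps <- t(vapply(slices, function(t) .dcmNumeric(t, "0028,0030"), numeric(2)))
  if (max(apply(ps, 2, function(x) diff(range(x)))) > 1e-6)
    stop("non-uniform in-plane spacing: PixelSpacing varies across slices")
  iop <- t(vapply(slices, function(t) .dcmNumeric(t, "0020,0037"),
                  numeric(6)))
  if (max(apply(iop, 2, function(x) diff(range(x)))) > 1e-6)
    stop("inconsistent ImageOrientationPatient across slices")
  rows <- vapply(slices, function(t) .dcmUS(t, "0028,0010"), 0L)
  cols <- vapply(slices, function(t) .dcmUS(t, "0028,0011"), 0L)
  if (length(unique(rows)) != 1 || length(unique(cols)) != 1)
    stop("inconsistent Rows/Columns across slices")
  rdir <- iop[1, 1:3]; cdir <- iop[1, 4:6]
  ndir <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
            rdir[3] * cdir[1] - rdir[1] * cdir[3],
            rdir[1] * cdir[2] - rdir[2] * cdir[1])
  ipp <- t(vapply(slices, function(t) .dcmNumeric(t, "0020,0032"),
                  numeric(3)))
  proj <- as.numeric(ipp %*% ndir)
  ord <- order(proj)
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]
  proj <- proj[ord]
  if (length(proj) > 1) {
    steps <- diff(proj)
    if (diff(range(steps)) > 1e-4)
      stop("non-uniform slice spacing: ImagePositionPatient steps vary (",
           paste(format(range(steps)), collapse = " to "), " mm)")
    dz <- steps[1]
  } else {
    dz <- .dcmNumeric(slices[[1]], "0018,0050")
    if (is.null(dz)) dz <- 1
  }
  nx <- cols[1]; ny <- rows[1]; nz <- length(slices)
  vox <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    el <- slices[[k]][["7FE0,0010"]]
    if (is.null(el)) stop("missing PixelData in slice ", k)
    signed <- identical(.dcmUS(slices[[k]], "0028,0103"), 1L)
    v <- readBin(el$data, "integer", nx * ny, size = 2, signed = signed,
                 endian = "little")
    vox[, , k] <- v
  }
  modality <- .dcmString(slices[[1]], "0008,0060")
  if (is.null(modality) || !modality %in% c("CT", "MR")) modality <- "CT"
  imageVolume(vox,
              spacing = c(ps[1, 2], ps[1, 1], dz),
              origin = ipp[1, ],
              direction = cbind(rdir, cdir, ndir),
              modality = modality)
}
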