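## Volume file I/O: NIfTI-1 (via RNifti), MetaImage (.mha/.mhd) and
## single-series DICOM directories (minimal codec in dicom.R).
##
## Internal world coordinates are LPS (the DICOM patient frame); NIfTI
## stores RAS, so sforms are converted by negating the first two world axes.

.LPS2RAS <- diag(c(-1, -1, 1))

.guessFormat <- function(path) {
  if (dir.exists(path)) return("dicom_series")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) return("metaimage")
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) return("dicom_series")
  stop("cannot guess volume format from path: ", path)
}

#' Read a volume from disk
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`), MetaImage
#' (`.mha`, `.mhd`) and a directory holding one uncompressed
#' explicit-VR-little-endian DICOM series.
#'
#' @param path file (NIfTI/MetaImage) or directory (DICOM series).
#' @param format `"auto"` (from the extension), `"nifti"`, `"metaimage"` or
#'   `"dicom_series"`.
#' @param modality fallback modality when the file does not record one.
#' @return an [ImageVolume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path,
                       format = c("auto", "nifti", "metaimage",
                                  "dicom_series"),
                       modality = "CT") {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  if (!file.exists(path))
    stop("no such file or directory: ", path)
  switch(format,
         nifti = .readNiftiVolume(path, modality),
         metaimage = .readMetaImage(path, modality),
         dicom_series = readDicomSeries(path))
}

#' Write a volume to disk
#'
#' @param vol an [ImageVolume-class].
#' @param path output file (`.nii`, `.nii.gz`, `.mha`, `.mhd`) or directory
#'   (DICOM series).
#' @param format as in [readVolume()].
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path,
                        format = c("auto", "nifti", "metaimage",
                                   "dicom_series")) {
  stopifnot(is(vol, "ImageVolume"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else if (grepl("\\.(mha|mhd)$", path)) "metaimage"
      else if (!grepl("\\.", basename(path))) "dicom_series"
      else stop("unsupported output format for path: ", path)
  }
  parent <- dirname(path)
  if (!dir.exists(parent)) stop("parent directory does not exist: ", parent)
  switch(format,
         nifti = .writeNiftiVolume(vol, path),
         metaimage = .writeMetaImage(vol, path),
         dicom_series = writeDicomSeries(vol, path))
  invisible(path)
}

.writeNiftiVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@voxels)
  m <- diag(4)
  m[1:3, 1:3] <- .LPS2RAS %*% vol@direction %*% diag(vol@spacing)
  m[1:3, 4] <- .LPS2RAS %*% vol@origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
}

.readNiftiVolume <- function(path, modality) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim(img))
  if (length(dim(vox)) != 3L)
    stop("expected a 3-D NIfTI volume, got ", length(dim(vox)), " dims")
  m <- RNifti::xform(img)
  lin <- .LPS2RAS %*% m[1:3, 1:3]
  sp <- sqrt(colSums(lin^2))
  dir <- lin %*% diag(1 / sp)
  if (det(dir) < 0)
    stop("left-handed NIfTI orientation not supported")
  imageVolume(vox, spacing = sp,
              origin = as.numeric(.LPS2RAS %*% m[1:3, 4]),
              direction = dir, modality = modality)
}

.metaTypeMap <- c(MET_DOUBLE = "double", MET_FLOAT = "float",
                  MET_SHORT = "short", MET_UCHAR = "uchar")

.writeMetaImage <- function(vol, path) {
  mhd <- grepl("\\.mhd$", path)
  dataFile <- if (mhd) sub("\\.mhd$", ".raw", path) else path
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =",
          paste(format(as.vector(vol@direction), digits = 17),
                collapse = " ")),
    paste("Offset =", paste(format(vol@origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =",
          paste(format(vol@spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(vol@voxels), collapse = " ")),
    paste("Modality =", vol@modality),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", if (mhd) basename(dataFile) else "LOCAL"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (mhd) {
    rcon <- file(dataFile, "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(vol@voxels), rcon, size = 8, endian = "little")
  } else {
    writeBin(as.numeric(vol@voxels), con, size = 8, endian = "little")
  }
}

## read one newline-terminated header line from a binary connection without
## read-ahead (the payload follows immediately for LOCAL storage)
.readLineRaw <- function(con) {
  bytes <- raw()
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) return(NULL)
    if (b == as.raw(10)) break
    bytes <- c(bytes, b)
  }
  sub("\r$", "", rawToChar(bytes))
}

.readMetaImage <- function(path, modality) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- .readLineRaw(con)
    if (is.null(line)) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  n <- prod(dims)
  type <- hdr$ElementType
  if (!type %in% names(.metaTypeMap))
    stop("unsupported MetaImage ElementType: ", type)
  readPayload <- function(c2) {
    switch(type,
           MET_DOUBLE = readBin(c2, "double", n, size = 8, endian = "little"),
           MET_FLOAT = readBin(c2, "double", n, size = 4, endian = "little"),
           MET_SHORT = as.numeric(readBin(c2, "integer", n, size = 2,
                                          signed = TRUE, endian = "little")),
           MET_UCHAR = as.numeric(readBin(c2, "integer", n, size = 1,
                                          signed = FALSE, endian = "little")))
  }
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readPayload(con)
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    rcon <- file(rawPath, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readPayload(rcon)
  }
  if (length(vals) != n) stop("truncated MetaImage payload: ", path)
  dir <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3, 3)
  else diag(3)
  if (!is.null(hdr$Modality) && hdr$Modality %in% c("CT", "MR"))
    modality <- hdr$Modality
  imageVolume(array(vals, dim = dims),
              spacing = as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]),
              origin = as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]),
              direction = dir, modality = modality)
}

#' Read or write a label mask as NIfTI with 8-bit payload
#'
#' @param mask a [LabelMask-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path` invisibly for the writer; a [LabelMask-class] for the
#'   reader.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  img <- RNifti::asNifti(array(as.integer(mask@voxels), dim(mask@voxels)),
                         datatype = "uint8")
  m <- diag(4)
  m[1:3, 1:3] <- .LPS2RAS %*% mask@direction %*% diag(mask@spacing)
  m[1:3, 4] <- .LPS2RAS %*% mask@origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeMask
#' @param label,provenance metadata for the mask read back.
#' @export
readMask <- function(path, label = "bone", provenance = "manual") {
  if (!file.exists(path)) stop("no such file: ", path)
  vol <- .readNiftiVolume(path, "CT")
  labelMask(vol@voxels != 0, vol, label = label, provenance = provenance)
}
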