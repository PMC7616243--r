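#' @include AllClasses.R
NULL

# Minimal single-frame CT DICOM support: explicit-VR little-endian only,
# covering the geometry and pixel tags the slicing pipeline needs. Written
# in-package because no R DICOM reader is available here; the matching
# writer exists so synthetic series can be built in code for round-trip
# testing.

.VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcmU16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.dcmU32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcmElement <- function(group, element, vr, value) {
  if (vr %in% c("DS", "IS", "CS", "LO", "UI", "SH")) {
    v <- charToRaw(as.character(value))
    if (length(v) %% 2 == 1) v <- c(v, charToRaw(" "))
  } else if (vr == "US") {
    v <- .dcmU16(value)
  } else if (vr == "OW") {
    v <- value  # raw already
  } else stop("unsupported VR ", vr)
  hdr <- c(.dcmU16(group), .dcmU16(element), charToRaw(vr))
  if (vr %in% .VR_LONG) c(hdr, as.raw(c(0, 0)), .dcmU32(length(v)), v)
  else c(hdr, .dcmU16(length(v)), v)
}

#' Write one slice of a CTA volume as a minimal DICOM file
#'
#' Explicit-VR little-endian single-frame CT with the geometry tags
#' (rows/columns, pixel spacing, image position and orientation, slice
#' and instance indexing) and 16-bit signed pixel data. Intended for
#' building synthetic series that [readDicomVolume()] can load back.
#'
#' @param pixels numeric matrix (rows x cols) of HU-like intensities in
#'   `[-32768, 32767]`.
#' @param path output file.
#' @param position length-3 image position (patient, mm) of the first
#'   pixel centre.
#' @param rowDir,colDir patient-space direction cosines along increasing
#'   column / increasing row.
#' @param spacing `(rowSpacing, colSpacing)` in mm.
#' @param instance instance number (slice order).
#' @return `path`, invisibly
#' @export
writeDicomSlice <- function(pixels, path, position = c(0, 0, 0),
                            rowDir = c(1, 0, 0), colDir = c(0, 1, 0),
                            spacing = c(1, 1), instance = 1L) {
  ds <- function(x) paste(formatC(x, format = "f", digits = 6), collapse = "\\")
  pix <- as.integer(round(t(pixels)))  # DICOM is row-major
  pv <- writeBin(pix, raw(), size = 2, endian = "little")
  body <- c(
    .dcmElement(0x0008, 0x0060, "CS", "CT"),
    .dcmElement(0x0020, 0x0013, "IS", as.character(instance)),
    .dcmElement(0x0020, 0x0032, "DS", ds(position)),
    .dcmElement(0x0020, 0x0037, "DS", ds(c(rowDir, colDir))),
    .dcmElement(0x0028, 0x0010, "US", nrow(pixels)),
    .dcmElement(0x0028, 0x0011, "US", ncol(pixels)),
    .dcmElement(0x0028, 0x0030, "DS", ds(spacing)),
    .dcmElement(0x0028, 0x0100, "US", 16L),
    .dcmElement(0x0028, 0x0103, "US", 1L),
    .dcmElement(0x0028, 0x1052, "DS", "0"),
    .dcmElement(0x0028, 0x1053, "DS", "1"),
    .dcmElement(0x7FE0, 0x0010, "OW", pv))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}

.parseDicomFile <- function(path) {
  b <- readBin(path, raw(), file.size(path))
  if (length(b) < 140 || rawToChar(b[129:132]) != "DICM")
    stop("readDicomVolume: not a DICOM file: ", path)
  pos <- 133L
  u16 <- function(at) sum(as.integer(b[at:(at + 1)]) * c(1, 256))
  u32 <- function(at) sum(as.integer(b[at:(at + 3)]) * c(1, 256, 65536, 16777216))
  tags <- list()
  while (pos + 8 <= length(b)) {
    grp <- u16(pos); ele <- u16(pos + 2)
    vr <- rawToChar(b[(pos + 4):(pos + 5)])
    if (vr %in% .VR_LONG) {
      len <- u32(pos + 8); dstart <- pos + 12
    } else {
      len <- u16(pos + 6); dstart <- pos + 8
    }
    val <- if (len > 0) b[dstart:(dstart + len - 1)] else raw()
    tags[[sprintf("%04X%04X", grp, ele)]] <- list(vr = vr, value = val)
    pos <- dstart + len
  }
  tags
}

.tagNum <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  as.numeric(strsplit(trimws(rawToChar(t$value)), "\\\\")[[1]])
}

.tagU16 <- function(tags, key) {
  t <- tags[[key]]
  sum(as.integer(t$value[1:2]) * c(1, 256))
}

#' Read a DICOM series into a CTA volume
#'
#' Loads all `.dcm` files in a directory (explicit-VR little-endian,
#' single-frame CT), sorts the slices along the stack normal, applies the
#' rescale slope/intercept and assembles a [CTAVolume-class] whose array
#' axes are (row, column, slice) with matching direction cosines.
#'
#' @param path directory containing the series.
#' @return a [CTAVolume-class]
#' @export
readDicomVolume <- function(path) {
  files <- sort(list.files(path, pattern = "\\.dcm$", full.names = TRUE))
  if (length(files) == 0) stop("readDicomVolume: no .dcm files in ", path)
  slices <- lapply(files, function(f) {
    tags <- .parseDicomFile(f)
    rows <- .tagU16(tags, "00280010"); cols <- .tagU16(tags, "00280011")
    iop <- .tagNum(tags, "00200037")
    ipp <- .tagNum(tags, "00200032")
    sp <- .tagNum(tags, "00280030")
    slope <- .tagNum(tags, "00281053") %||% 1
    inter <- .tagNum(tags, "00281052") %||% 0
    pixrep <- .tagU16(tags, "00280103")
    pv <- tags[["7FE00010"]]$value
    pix <- readBin(pv, "integer", n = rows * cols, size = 2,
                   endian = "little", signed = pixrep == 1)
    list(img = t(matrix(pix, cols, rows)) * slope + inter,
         ipp = ipp, iop = iop, spacing = sp)
  })
  iop <- slices[[1]]$iop
  rowDir <- iop[1:3]; colDir <- iop[4:6]
  normal <- c(rowDir[2] * colDir[3] - rowDir[3] * colDir[2],
              rowDir[3] * colDir[1] - rowDir[1] * colDir[3],
              rowDir[1] * colDir[2] - rowDir[2] * colDir[1])
  zpos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  dz <- if (length(slices) > 1) mean(diff(zpos)) else 1
  vox <- array(0, c(dim(slices[[1]]$img), length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$img
  sp <- slices[[1]]$spacing
  ctaVolume(vox, spacing = c(sp[1], sp[2], dz),
            origin = slices[[1]]$ipp,
            orientation = cbind(colDir, rowDir, normal))
}
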