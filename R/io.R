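#' Read a 3D volume from NIfTI, NRRD or a DICOM series directory
#'
#' Intensities are interpreted as Hounsfield units with no rescaling beyond
#' the header's slope/intercept (DICOM) or stored values (NIfTI/NRRD).
#' Voxel spacing is taken from the file header.
#'
#' @param path file path (NIfTI/NRRD) or directory (DICOM series).
#' @param format one of "auto", "nifti", "nrrd", "dicom_dir". With "auto"
#'   the format is inferred from the path (directory -> DICOM series,
#'   .nii/.nii.gz -> NIfTI, .nrrd -> NRRD).
#' @return A \linkS4class{ScanVolume}.
#' @export
readVolume <- function(path, format = c("auto", "nifti", "nrrd", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  switch(format,
    nifti = .readNiftiVolume(path),
    nrrd = .readNrrdVolume(path),
    dicom_dir = .readDicomSeries(path))
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @param path output path; .nii/.nii.gz writes NIfTI, .nrrd writes NRRD.
#' @param format "auto", "nifti" or "nrrd".
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path, format = c("auto", "nifti", "nrrd")) {
  stopifnot(is(vol, "ScanVolume"))
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path, writing = TRUE)
  switch(format,
    nifti = .writeNiftiGrid(vol@data, vol@spacing, path),
    nrrd = .writeNrrdGrid(vol@data, vol@spacing, path, type = "double"))
  invisible(path)
}

#' Read a binary mask from NIfTI or NRRD
#'
#' The payload must be restricted to \{0, 1\}.
#'
#' @inheritParams readVolume
#' @return A \linkS4class{BinaryMask}.
#' @export
readMask <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  v <- switch(format,
    nifti = .readNiftiVolume(path),
    nrrd = .readNrrdVolume(path))
  BinaryMask(v@data, v@spacing)
}

#' Write a binary mask to NIfTI or NRRD with 0/1 payload
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @inheritParams writeVolume
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path, format = c("auto", "nifti", "nrrd")) {
  stopifnot(is(mask, "BinaryMask"))
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path, writing = TRUE)
  payload <- array(as.integer(mask@data), dim(mask@data))
  switch(format,
    nifti = .writeNiftiGrid(payload, mask@spacing, path),
    nrrd = .writeNrrdGrid(payload, mask@spacing, path, type = "uint8"))
  invisible(path)
}

.guessFormat <- function(path, writing = FALSE) {
  if (!writing && dir.exists(path)) return("dicom_dir")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop("cannot infer format from path: ", path)
}

.readNiftiVolume <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) != 3L)
    stop("dimensionality error: expected a 3D payload, got ",
         length(dim(a)), "D")
  ScanVolume(a, spacing = RNifti::pixdim(img)[1:3])
}

.writeNiftiGrid <- function(data, spacing, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
}

# --- NRRD: raw-encoded little-endian, header per the NRRD0004 format ---

.nrrdTypes <- list(
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "double",  size = 4L, signed = TRUE),
  double = list(what = "double",  size = 8L, signed = TRUE))

.nrrdTypeAliases <- c(
  "unsigned char" = "uint8", uchar = "uint8", "uint8_t" = "uint8",
  short = "int16", "signed short" = "int16", "int16_t" = "int16",
  int = "int32", "signed int" = "int32", "int32_t" = "int32")

.readNrrdVolume <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  nl <- which(raw == as.raw(10L))
  hdrEnd <- NA_integer_
  prev <- 0L
  for (p in nl) {
    line <- if (p - prev > 1L) rawToChar(raw[(prev + 1L):(p - 1L)]) else ""
    if (line == "" && prev > 0L) { hdrEnd <- p; break }
    prev <- p
  }
  if (is.na(hdrEnd)) stop("format error: no NRRD header terminator found")
  hdr <- strsplit(rawToChar(raw[1:(hdrEnd - 1L)]), "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("format error: not an NRRD file")
  fields <- list()
  for (line in hdr[-1]) {
    if (grepl("^#", line) || !grepl(":", line, fixed = TRUE)) next
    sep <- regexpr(":", line, fixed = TRUE)
    key <- tolower(trimws(substr(line, 1L, sep - 1L)))
    val <- trimws(sub("^=", "", trimws(substr(line, sep + 1L, nchar(line)))))
    fields[[key]] <- val
  }
  if (as.integer(fields$dimension) != 3L)
    stop("dimensionality error: expected a 3D payload, got ",
         fields$dimension, "D")
  if (!identical(tolower(fields$encoding), "raw"))
    stop("format error: only raw encoding is supported")
  type <- tolower(fields$type)
  if (type %in% names(.nrrdTypeAliases)) type <- .nrrdTypeAliases[[type]]
  spec <- .nrrdTypes[[type]]
  if (is.null(spec)) stop("format error: unsupported NRRD type ", fields$type)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  spacing <- rep(1, 3)
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  n <- prod(sizes)
  vals <- readBin(raw[(hdrEnd + 1L):length(raw)], spec$what, n = n,
                  size = spec$size, signed = spec$signed, endian = "little")
  if (length(vals) != n) stop("format error: truncated NRRD payload")
  ScanVolume(array(as.double(vals), sizes), spacing)
}

.writeNrrdGrid <- function(data, spacing, path, type = "double") {
  spec <- .nrrdTypes[[type]]
  hdr <- paste0(
    "NRRD0004\n",
    "# Complete NRRD file format specification at http://teem.sourceforge.net/nrrd/format.html\n",
    "type: ", type, "\n",
    "dimension: 3\n",
    "sizes: ", paste(dim(data), collapse = " "), "\n",
    "spacings: ", paste(format(spacing, digits = 10), collapse = " "), "\n",
    "encoding: raw\n",
    "endian: little\n\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  vals <- as.vector(data)
  if (spec$what == "integer") vals <- as.integer(vals)
  writeBin(vals, con, size = spec$size, endian = "little")
  invisible(path)
}
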