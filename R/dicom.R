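# Minimal DICOM support: uncompressed little-endian (explicit or implicit
# VR) single-frame image slices, no undefined-length sequences. Sufficient
# for CT/CBCT series export; anything fancier should be converted to NIfTI
# upstream.

.u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

.u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

.longVRs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

# Parse one DICOM file into a list of raw element values keyed by
# "gggg,eeee" (lower-case hex), plus decoded convenience fields.
.parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("format error: ", path, " is not a DICOM part-10 file")
  pos <- 133L
  n <- length(raw)
  tags <- list()
  explicit <- TRUE
  syntax <- "1.2.840.10008.1.2.1"
  metaDone <- FALSE
  while (pos + 7L <= n) {
    group <- .u16(raw, pos)
    if (!metaDone && group != 2L) {
      metaDone <- TRUE
      uid <- tags[["0002,0010"]]
      if (!is.null(uid)) syntax <- .dcmString(uid)
      if (syntax == "1.2.840.10008.1.2") explicit <- FALSE
      else if (!syntax %in% c("1.2.840.10008.1.2.1"))
        stop("format error: unsupported transfer syntax ", syntax)
    }
    elem <- .u16(raw, pos + 2L)
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .longVRs) {
        len <- .u32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- .u16(raw, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, pos + 4L)
      hdr <- 8L
    }
    if (len == 4294967295) stop("format error: undefined-length element")
    key <- sprintf("%04x,%04x", group, elem)
    val <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    tags[[key]] <- val
    pos <- pos + hdr + len
    if (key == "7fe0,0010") break
  }
  tags
}

.dcmString <- function(val) {
  if (is.null(val) || length(val) == 0L) return(NULL)
  gsub("[\\x00 ]+$", "", rawToChar(val), perl = TRUE)
}

.dcmNumeric <- function(tags, key) {
  s <- .dcmString(tags[[key]])
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}

.dcmU16 <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  .u16(v, 1L)
}

.readDicomSlice <- function(path) {
  tags <- .parseDicomFile(path)
  rows <- .dcmU16(tags, "0028,0010")
  cols <- .dcmU16(tags, "0028,0011")
  bits <- .dcmU16(tags, "0028,0100")
  signed <- identical(.dcmU16(tags, "0028,0103"), 1L)
  px <- tags[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop("format error: missing image elements in ", path)
  if (!bits %in% c(8L, 16L))
    stop("format error: unsupported BitsAllocated ", bits)
  vals <- readBin(px, "integer", n = rows * cols, size = bits / 8L,
                  signed = if (bits == 8L) FALSE else signed,
                  endian = "little")
  if (bits == 16L && !signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  slope <- .dcmNumeric(tags, "0028,1053")
  inter <- .dcmNumeric(tags, "0028,1052")
  if (is.null(slope)) slope <- 1
  if (is.null(inter)) inter <- 0
  # PixelData is row-major: columns vary fastest -> matrix[x = col, y = row]
  m <- matrix(vals * slope + inter, nrow = cols, ncol = rows)
  ps <- .dcmNumeric(tags, "0028,0030")  # (row spacing, column spacing)
  ipp <- .dcmNumeric(tags, "0020,0032")
  list(pixels = m,
       spacingXY = if (is.null(ps)) c(1, 1) else c(ps[2], ps[1]),
       z = if (is.null(ipp)) NA_real_ else ipp[3],
       instance = {
         s <- .dcmString(tags[["0020,0013"]])
         if (is.null(s)) NA_real_ else as.numeric(s)
       },
       thickness = {
         t <- .dcmNumeric(tags, "0018,0050")
         if (is.null(t)) NA_real_ else t
       })
}

.readDicomSeries <- function(dir) {
  if (!dir.exists(dir)) stop("unreadable path: ", dir)
  files <- list.files(dir, pattern = "\\.(dcm|DCM|ima|IMA)$", full.names = TRUE)
  if (length(files) == 0L) files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("format error: no files in ", dir)
  slices <- lapply(files, .readDicomSlice)
  zs <- vapply(slices, `[[`, numeric(1), "z")
  ord <- if (!anyNA(zs)) order(zs) else
    order(vapply(slices, `[[`, numeric(1), "instance"))
  slices <- slices[ord]
  sh <- dim(slices[[1]]$pixels)
  ok <- vapply(slices, function(s) identical(dim(s$pixels), sh), logical(1))
  if (!all(ok)) stop("format error: inconsistent slice shapes in series")
  data <- array(0, c(sh[1], sh[2], length(slices)))
  for (i in seq_along(slices)) data[, , i] <- slices[[i]]$pixels
  zs <- vapply(slices, `[[`, numeric(1), "z")
  dz <- if (length(zs) > 1L && !anyNA(zs)) stats::median(diff(zs))
        else slices[[1]]$thickness
  if (is.na(dz) || dz <= 0) dz <- 1
  ScanVolume(data, spacing = c(slices[[1]]$spacingXY, dz))
}

.dcmEncode <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  head <- writeBin(c(group, elem), raw(), size = 2, endian = "little")
  if (vr %in% .longVRs) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4, endian = "little"), value)
  } else {
    c(head, charToRaw(vr),
      writeBin(length(value), raw(), size = 2, endian = "little"), value)
  }
}

.dcmUS <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

#' Write a volume as a synthetic DICOM series
#'
#' One explicit-VR little-endian CT-style file per axial slice, with pixel
#' values stored as signed 16-bit integers under RescaleSlope 1 and
#' RescaleIntercept -1024 (stored = HU + 1024). Intended for testing the
#' series reader and for interoperability checks; clinical metadata beyond
#' the geometry/rescale elements is not written.
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeDicomSeries <- function(vol, dir) {
  stopifnot(is(vol, "ScanVolume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol@data)
  sp <- vol@spacing
  uidRoot <- "1.2.826.0.1.3680043.9999"
  for (z in seq_len(d[3])) {
    stored <- as.integer(round(vol@data[, , z]) + 1024)
    if (any(stored < -32768 | stored > 32767))
      stop("HU values out of range for 16-bit storage")
    meta <- c(
      .dcmEncode(2L, 1L, "OB", as.raw(c(0, 1))),
      .dcmEncode(2L, 2L, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcmEncode(2L, 3L, "UI", sprintf("%s.1.%d", uidRoot, z)),
      .dcmEncode(2L, 16L, "UI", "1.2.840.10008.1.2.1"),
      .dcmEncode(2L, 18L, "UI", paste0(uidRoot, ".0.1")))
    metaLen <- .dcmEncode(2L, 0L, "UL",
      writeBin(length(meta), raw(), size = 4, endian = "little"))
    body <- c(
      .dcmEncode(8L, 22L, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcmEncode(8L, 24L, "UI", sprintf("%s.1.%d", uidRoot, z)),
      .dcmEncode(24L, 80L, "DS", format(sp[3])),
      .dcmEncode(32L, 19L, "IS", as.character(z)),
      .dcmEncode(32L, 50L, "DS",
                 paste(c(0, 0, (z - 1) * sp[3]), collapse = "\\")),
      .dcmEncode(40L, 2L, "US", .dcmUS(1L)),
      .dcmEncode(40L, 4L, "CS", "MONOCHROME2"),
      .dcmEncode(40L, 16L, "US", .dcmUS(d[2])),   # Rows = y extent
      .dcmEncode(40L, 17L, "US", .dcmUS(d[1])),   # Columns = x extent
      .dcmEncode(40L, 48L, "DS", paste(c(sp[2], sp[1]), collapse = "\\")),
      .dcmEncode(40L, 256L, "US", .dcmUS(16L)),
      .dcmEncode(40L, 257L, "US", .dcmUS(16L)),
      .dcmEncode(40L, 258L, "US", .dcmUS(15L)),
      .dcmEncode(40L, 259L, "US", .dcmUS(1L)),
      .dcmEncode(40L, 4178L, "DS", "-1024"),
      .dcmEncode(40L, 4179L, "DS", "1"),
      .dcmEncode(32736L, 16L, "OW",
                 writeBin(stored, raw(), size = 2, endian = "little")))
    con <- file(file.path(dir, sprintf("slice_%03d.dcm", z)), "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), metaLen, meta, body), con)
    close(con)
  }
  invisible(dir)
}
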