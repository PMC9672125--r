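#' Extract the raw voxel array
#'
#' @param x a \linkS4class{ScanVolume} or \linkS4class{BinaryMask}.
#' @return The underlying 3D array (numeric for volumes, logical for masks).
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setMethod("voxels", "ScanVolume", function(x) x@data)

#' @rdname voxels
#' @export
setMethod("voxels", "BinaryMask", function(x) x@data)

#' Voxel spacing in millimetres
#'
#' @param x a \linkS4class{ScanVolume} or \linkS4class{BinaryMask}.
#' @return Numeric length-3 voxel size per axis.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ScanVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)

#' @export
setMethod("dim", "ScanVolume", function(x) dim(x@data))

#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@data))

setMethod("show", "ScanVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScanVolume %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  n <- sum(object@data)
  cat(sprintf("BinaryMask %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], n, 100 * n / prod(d)))
})

setMethod("show", "MdbReport", function(object) {
  cat(sprintf(
    "MDB screening: %d voxels > %g HU, %d voxels > %g HU\n  MDBR = %.4f (TH3 = %g) -> %s\n",
    object@countAboveTh1, object@th1, object@countAboveTh2, object@th2,
    object@mdbr, object@th3,
    if (object@heavy) "heavy metallic dental burden" else "not heavy"))
})

setMethod("show", "ViewStack", function(object) {
  sh <- dim(object@frames[[1]])
  cat(sprintf("ViewStack (%s, %s): %d frames of %d x %d\n", object@view,
              object@kind, length(object@frames), sh[1], sh[2]))
})

setMethod("show", "SlabStack", function(object) {
  cat(sprintf("SlabStack: %d three-channel axial slabs of %d x %d\n",
              length(object@frames), object@sourceDim[1], object@sourceDim[2]))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid (%s): %d patches of %s, pad (%s) on source %s\n",
              object@kind, length(object@patches),
              paste(object@patchShape, collapse = " x "),
              paste(object@pad, collapse = ", "),
              paste(object@sourceDim, collapse = " x ")))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d voters (%s), shape %s\n",
              length(object@masks), paste(names(object@masks), collapse = ", "),
              paste(dim(object@masks[[1]]@data), collapse = " x ")))
})

.schemeLabel <- function(s) {
  parts <- vapply(s@voters, function(v)
    if (is.character(v)) v else .schemeLabel(v), character(1))
  k <- if (is.na(s@k)) (length(s@voters) %/% 2L) + 1L else s@k
  sprintf("%s[k=%d](%s)", s@name, k, paste(parts, collapse = ", "))
}

setMethod("show", "VotingScheme", function(object) {
  cat("VotingScheme:", .schemeLabel(object), "\n")
})

setMethod("show", "StructuringElement", function(object) {
  cat(sprintf("StructuringElement: %s ball, radius %g, %d voxels\n",
              object@metric, object@radius, nrow(object@offsets)))
})
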