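#' @import methods
NULL

#' 3D scan volume in Hounsfield units
#'
#' A 3D scalar grid with per-axis voxel spacing in millimetres. The axis
#' convention is fixed package-wide: axis 1 is left-right (sagittal, x),
#' axis 2 is front-back (coronal, y), axis 3 is inferior-superior (axial, z).
#' An axial slice is a fixed-z plane, a coronal slice a fixed-y plane and a
#' sagittal slice a fixed-x plane.
#'
#' @slot data 3D numeric array of intensities in HU.
#' @slot spacing numeric length-3, voxel size in mm per axis (all > 0).
#'   Cone-beam CT is typically isotropic; the package default is 0.19 mm.
#' @export
setClass("ScanVolume", representation(data = "array", spacing = "numeric"))

setValidity("ScanVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must have exactly 3 dimensions")
  if (any(d < 1L)) return("every dimension must have extent >= 1")
  if (length(object@spacing) != 3L) return("spacing must have length 3")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("all spacing values must be finite and > 0")
  if (!is.numeric(object@data)) return("data must be numeric")
  TRUE
})

#' Binary segmentation mask aligned to a ScanVolume
#'
#' A 3D logical grid sharing the geometry (shape, spacing, axis convention)
#' of the volume it annotates: ground truth, a model prediction, or a fused
#' voting result.
#'
#' @slot data 3D logical array.
#' @slot spacing numeric length-3 voxel size in mm.
#' @export
setClass("BinaryMask", representation(data = "array", spacing = "numeric"))

setValidity("BinaryMask", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must have exactly 3 dimensions")
  if (any(d < 1L)) return("every dimension must have extent >= 1")
  if (!is.logical(object@data)) return("mask payload must be logical")
  if (anyNA(object@data)) return("mask payload must not contain NA")
  if (length(object@spacing) != 3L) return("spacing must have length 3")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("all spacing values must be finite and > 0")
  TRUE
})

#' Construct a ScanVolume
#'
#' @param data 3D numeric array of HU intensities.
#' @param spacing voxel size in mm (length 1 or 3); default 0.19 isotropic.
#' @return A \linkS4class{ScanVolume}.
#' @export
ScanVolume <- function(data, spacing = 0.19) {
  if (is.logical(data)) data <- data * 1
  storage.mode(data) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ScanVolume", data = data, spacing = as.numeric(spacing))
}

#' Construct a BinaryMask
#'
#' @param data 3D array coercible to logical with values in \{0, 1\}.
#' @param spacing voxel size in mm (length 1 or 3); default 0.19 isotropic.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(data, spacing = 0.19) {
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be restricted to {0, 1}")
    data <- array(as.logical(data), dim(data))
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("BinaryMask", data = data, spacing = as.numeric(spacing))
}

#' Metallic dental burden screening report
#'
#' Result of screening a CBCT volume for heavy metallic dental burden (MDB):
#' voxels above TH1 (metal-like density) are counted against voxels above
#' TH2 (enamel-like density); the ratio MDBR above TH3 flags the scan as
#' heavy-MDB.
#'
#' @slot th1,th2 HU thresholds for metal-like and enamel-like density.
#' @slot th3 MDBR cutoff defining "heavy".
#' @slot countAboveTh1,countAboveTh2 voxel counts above each threshold.
#' @slot mdbr the screening ratio (0 when no voxel exceeds th2).
#' @slot heavy logical, mdbr > th3.
#' @export
setClass("MdbReport", representation(
  th1 = "numeric", th2 = "numeric", th3 = "numeric",
  countAboveTh1 = "numeric", countAboveTh2 = "numeric",
  mdbr = "numeric", heavy = "logical"))

setValidity("MdbReport", function(object) {
  if (object@countAboveTh1 < 0 || object@countAboveTh2 < 0)
    return("voxel counts must be non-negative")
  if (object@mdbr < 0) return("mdbr must be non-negative")
  if (!identical(object@heavy, object@mdbr > object@th3))
    return("heavy flag inconsistent with mdbr > th3")
  if (object@th1 >= object@th2 && object@countAboveTh1 > object@countAboveTh2)
    return("count above th1 cannot exceed count above th2 when th1 >= th2")
  TRUE
})

#' Stack of 2D frames extracted from a volume along one anatomical view
#'
#' @slot view one of "axial", "coronal", "sagittal".
#' @slot frames list of 2D matrices, one per plane, in increasing coordinate
#'   order unless reordered (placement is governed by \code{indexMap}).
#' @slot indexMap integer vector: frame i sits at plane \code{indexMap[i]}
#'   of the source volume along the view axis.
#' @slot sourceDim integer length-3, shape of the source grid.
#' @slot kind "volume" or "mask" (controls reassembly type).
#' @slot spacing voxel spacing of the source.
#' @export
setClass("ViewStack", representation(
  view = "character", frames = "list", indexMap = "integer",
  sourceDim = "integer", kind = "character", spacing = "numeric"))

setValidity("ViewStack", function(object) {
  if (!object@view %in% c("axial", "coronal", "sagittal"))
    return("view must be axial, coronal or sagittal")
  ax <- c(sagittal = 1L, coronal = 2L, axial = 3L)[[object@view]]
  if (length(object@frames) != object@sourceDim[ax])
    return("frame count must equal the source extent along the view axis")
  if (length(object@indexMap) != length(object@frames))
    return("indexMap length must match frame count")
  if (anyDuplicated(object@indexMap) ||
      any(object@indexMap < 1L) || any(object@indexMap > object@sourceDim[ax]))
    return("indexMap must be a permutation of plane coordinates")
  sh <- dim(object@frames[[1]])
  ok <- vapply(object@frames, function(f) identical(dim(f), sh), logical(1))
  if (!all(ok)) return("every frame must have identical shape")
  TRUE
})

#' Stack of three-channel 2.5D axial slabs
#'
#' Frame i holds axial slices (i-1, i, i+1) in its three channels, with edge
#' slices replicating their nearest existing neighbour.
#'
#' @slot frames list of 3D arrays (nx x ny x 3).
#' @slot indexMap integer vector of centre-slice coordinates.
#' @slot sourceDim integer length-3 source shape.
#' @slot spacing voxel spacing of the source.
#' @export
setClass("SlabStack", representation(
  frames = "list", indexMap = "integer", sourceDim = "integer",
  spacing = "numeric"))

setValidity("SlabStack", function(object) {
  if (length(object@frames) != object@sourceDim[3])
    return("frame count must equal the axial extent")
  ok <- vapply(object@frames, function(f)
    length(dim(f)) == 3L && dim(f)[3] == 3L &&
      all(dim(f)[1:2] == object@sourceDim[1:2]), logical(1))
  if (!all(ok)) return("every frame must be nx x ny x 3")
  TRUE
})

#' Non-overlapping 3D patch decomposition of a volume
#'
#' The source grid is zero-padded at the trailing end of each axis to the
#' next multiple of the patch shape, then cut into disjoint, exhaustive
#' blocks in raster order (z fastest).
#'
#' @slot patchShape integer length-3 block shape (default 64 x 64 x 128).
#' @slot patches list of 3D blocks.
#' @slot offsets integer matrix (n x 3) of 0-based corner coordinates in
#'   padded space.
#' @slot pad integer length-3 trailing padding applied per axis.
#' @slot sourceDim integer length-3 original shape.
#' @slot kind "volume" or "mask".
#' @slot spacing voxel spacing of the source.
#' @export
setClass("PatchGrid", representation(
  patchShape = "integer", patches = "list", offsets = "matrix",
  pad = "integer", sourceDim = "integer", kind = "character",
  spacing = "numeric"))

setValidity("PatchGrid", function(object) {
  if (any(object@patchShape < 1L)) return("patch dimensions must be positive")
  if (nrow(object@offsets) != length(object@patches))
    return("one offset row per patch required")
  padded <- object@sourceDim + object@pad
  if (any(padded %% object@patchShape != 0L))
    return("padded shape must be a multiple of the patch shape")
  TRUE
})

#' Named collection of aligned prediction masks (the voters)
#'
#' @slot masks named list of \linkS4class{BinaryMask}, all congruent.
#' @export
setClass("PredictionSet", representation(masks = "list"))

setValidity("PredictionSet", function(object) {
  if (length(object@masks) < 1L) return("at least one mask required")
  nm <- names(object@masks)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    return("masks must have unique non-empty names")
  ok <- vapply(object@masks, function(m) is(m, "BinaryMask"), logical(1))
  if (!all(ok)) return("every element must be a BinaryMask")
  d <- dim(object@masks[[1]]@data)
  sh <- vapply(object@masks, function(m) identical(dim(m@data), d), logical(1))
  if (!all(sh)) return("all masks must share one shape")
  TRUE
})

#' Construct a PredictionSet
#'
#' @param masks named list of congruent \linkS4class{BinaryMask} objects,
#'   one per model.
#' @return A \linkS4class{PredictionSet}.
#' @export
PredictionSet <- function(masks) new("PredictionSet", masks = masks)

#' Declarative majority-voting recipe
#'
#' Voters are model names (leaves, looked up in a
#' \linkS4class{PredictionSet}) or nested \linkS4class{VotingScheme}
#' objects, evaluated depth-first. The rule is the minimum number of
#' affirmative votes k; \code{NA} means strict majority
#' \code{floor(n/2) + 1}.
#'
#' @slot name scheme identifier.
#' @slot voters list of character names and/or nested schemes.
#' @slot k integer minimum affirmative votes, or NA for strict majority.
#' @export
setClass("VotingScheme", representation(
  name = "character", voters = "list", k = "integer"))

setValidity("VotingScheme", function(object) {
  n <- length(object@voters)
  if (n < 1L) return("voters must be non-empty")
  ok <- vapply(object@voters, function(v)
    (is.character(v) && length(v) == 1L) || is(v, "VotingScheme"), logical(1))
  if (!all(ok)) return("each voter must be a model name or a VotingScheme")
  if (!is.na(object@k) && (object@k < 1L || object@k > n))
    return("k must lie in [1, number of voters]")
  TRUE
})

#' Construct a VotingScheme
#'
#' @param name scheme identifier.
#' @param voters list of model names and/or nested schemes.
#' @param k minimum affirmative votes; default NA = strict majority
#'   \code{floor(n/2) + 1}.
#' @return A \linkS4class{VotingScheme}.
#' @seealso \code{\link{builtinScheme}} for the stock 2.5Dv/3.5Dv recipes.
#' @export
VotingScheme <- function(name, voters, k = NA_integer_) {
  if (is.character(voters)) voters <- as.list(voters)
  new("VotingScheme", name = name, voters = voters, k = as.integer(k))
}

#' Spherical structuring element on the voxel lattice
#'
#' The discrete ball of integer offsets z with ||z|| <= radius. Contains the
#' origin and is symmetric (z in B implies -z in B), so it equals its own
#' reflection. With the default Euclidean metric and radius 2 the support
#' has 33 voxels.
#'
#' @slot radius ball radius in voxels.
#' @slot offsets integer matrix (n x 3) of member offsets.
#' @slot metric "euclidean", "cityblock" or "chessboard".
#' @export
setClass("StructuringElement", representation(
  radius = "numeric", offsets = "matrix", metric = "character"))

setValidity("StructuringElement", function(object) {
  off <- object@offsets
  if (ncol(off) != 3L) return("offsets must have 3 columns")
  if (!any(rowSums(abs(off)) == 0)) return("element must contain the origin")
  key <- function(m) sort(apply(m, 1L, paste, collapse = ","))
  if (!identical(key(off), key(-off))) return("element must be symmetric")
  TRUE
})
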