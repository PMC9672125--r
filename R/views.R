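.viewAxis <- c(sagittal = 1L, coronal = 2L, axial = 3L)

#' Decompose a volume or mask into 2D frames along one anatomical view
#'
#' Frames are the fixed-coordinate planes along the view axis in increasing
#' coordinate order: axial frames are (x, y) planes at fixed z, coronal
#' frames (x, z) planes at fixed y, sagittal frames (y, z) planes at fixed
#' x. The decomposition is lossless; \code{\link{stackToVolume}} inverts it.
#'
#' @param x a \linkS4class{ScanVolume} or \linkS4class{BinaryMask}.
#' @param view "axial", "coronal" or "sagittal".
#' @return A \linkS4class{ViewStack}.
#' @export
extractSlices <- function(x, view = c("axial", "coronal", "sagittal")) {
  stopifnot(is(x, "ScanVolume") || is(x, "BinaryMask"))
  if (length(view) == 1L && !view %in% names(.viewAxis))
    stop("parameter error: unknown view '", view, "'")
  view <- match.arg(view)
  a <- x@data
  d <- dim(a)
  ax <- .viewAxis[[view]]
  planeDim <- switch(ax, d[2:3], d[c(1, 3)], d[1:2])
  frames <- lapply(seq_len(d[ax]), function(k) {
    f <- switch(ax,
      a[k, , , drop = FALSE], a[, k, , drop = FALSE], a[, , k, drop = FALSE])
    dim(f) <- planeDim
    f
  })
  new("ViewStack", view = view, frames = frames,
      indexMap = seq_len(d[ax]), sourceDim = d,
      kind = if (is(x, "BinaryMask")) "mask" else "volume",
      spacing = x@spacing)
}

#' Reassemble a ViewStack into a full volume or mask
#'
#' Frames are placed at the plane coordinates given by the stack's
#' \code{indexMap} (not by list order), so permuted stacks reconstruct
#' correctly. Inverse of \code{\link{extractSlices}} for every view.
#'
#' @param stack a \linkS4class{ViewStack}.
#' @return A \linkS4class{ScanVolume} or \linkS4class{BinaryMask},
#'   matching the stack's source kind.
#' @export
stackToVolume <- function(stack) {
  stopifnot(is(stack, "ViewStack"))
  validObject(stack)
  d <- stack@sourceDim
  ax <- .viewAxis[[stack@view]]
  expected <- switch(ax, d[2:3], d[c(1, 3)], d[1:2])
  ok <- vapply(stack@frames, function(f) identical(dim(f), expected),
               logical(1))
  if (!all(ok)) stop("consistency error: misshapen frame in stack")
  a <- array(0, d)
  for (i in seq_along(stack@frames)) {
    k <- stack@indexMap[i]
    switch(ax,
      a[k, , ] <- stack@frames[[i]],
      a[, k, ] <- stack@frames[[i]],
      a[, , k] <- stack@frames[[i]])
  }
  if (stack@kind == "mask") BinaryMask(a > 0, stack@spacing)
  else ScanVolume(a, stack@spacing)
}

#' Build three-channel 2.5D axial slabs
#'
#' Frame i stacks axial slices (i-1, i, i+1) in its three channels. At the
#' volume edges the missing neighbour is replaced by the nearest existing
#' slice, so channel semantics are kept without inventing intensities; a
#' single-slice volume yields one frame with three identical channels.
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @return A \linkS4class{SlabStack}.
#' @export
makeSlabs <- function(vol) {
  stopifnot(is(vol, "ScanVolume"))
  a <- vol@data
  d <- dim(a)
  frames <- lapply(seq_len(d[3]), function(i) {
    lo <- max(i - 1L, 1L)
    hi <- min(i + 1L, d[3])
    slab <- array(0, c(d[1], d[2], 3L))
    slab[, , 1] <- a[, , lo]
    slab[, , 2] <- a[, , i]
    slab[, , 3] <- a[, , hi]
    slab
  })
  new("SlabStack", frames = frames, indexMap = seq_len(d[3]),
      sourceDim = d, spacing = vol@spacing)
}

#' Tile a volume or mask into non-overlapping 3D patches
#'
#' The grid is zero-padded at the trailing end of each axis up to the next
#' multiple of the patch dimension, then cut into disjoint, exhaustive
#' blocks enumerated in raster order with z fastest. The default patch
#' shape is the 64 x 64 x 128 cuboid used as 3D network input (64 x 64
#' in-plane, 128 along z).
#'
#' @param x a \linkS4class{ScanVolume} or \linkS4class{BinaryMask}.
#' @param patchShape integer length-3 block shape.
#' @return A \linkS4class{PatchGrid}.
#' @export
tilePatches <- function(x, patchShape = c(64L, 64L, 128L)) {
  stopifnot(is(x, "ScanVolume") || is(x, "BinaryMask"))
  patchShape <- as.integer(patchShape)
  if (length(patchShape) != 3L || any(patchShape < 1L))
    stop("parameter error: patch dimensions must be positive")
  d <- dim(x@data)
  isMask <- is(x, "BinaryMask")
  pad <- as.integer((patchShape - d %% patchShape) %% patchShape)
  padded <- array(if (isMask) FALSE else 0, d + pad)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x@data
  nBlocks <- (d + pad) %/% patchShape
  # raster order, z fastest
  offs <- as.matrix(expand.grid(
    z = seq_len(nBlocks[3]) - 1L,
    y = seq_len(nBlocks[2]) - 1L,
    x = seq_len(nBlocks[1]) - 1L))[, c("x", "y", "z"), drop = FALSE]
  offs <- offs * rep(patchShape, each = nrow(offs))
  patches <- lapply(seq_len(nrow(offs)), function(i) {
    o <- offs[i, ]
    padded[o[1] + seq_len(patchShape[1]),
           o[2] + seq_len(patchShape[2]),
           o[3] + seq_len(patchShape[3])]
  })
  storage.mode(offs) <- "integer"
  dimnames(offs) <- NULL
  new("PatchGrid", patchShape = patchShape, patches = patches,
      offsets = offs, pad = pad, sourceDim = d,
      kind = if (isMask) "mask" else "volume", spacing = x@spacing)
}

#' Reassemble a PatchGrid into a full volume or mask
#'
#' Patches are placed at their stored offsets; the decomposition must be
#' disjoint and exhaustive (every padded voxel covered exactly once), then
#' the trailing padding is cropped so the original shape is restored.
#' Inverse of \code{\link{tilePatches}}.
#'
#' @param grid a \linkS4class{PatchGrid}.
#' @return A \linkS4class{ScanVolume} or \linkS4class{BinaryMask}.
#' @export
assemblePatches <- function(grid) {
  stopifnot(is(grid, "PatchGrid"))
  d <- grid@sourceDim
  ps <- grid@patchShape
  padded <- d + grid@pad
  need <- prod(padded %/% ps)
  if (length(grid@patches) != need)
    stop("consistency error: expected ", need, " patches, got ",
         length(grid@patches))
  if (anyDuplicated(grid@offsets))
    stop("consistency error: overlapping patch offsets")
  if (any(grid@offsets < 0L) || any(grid@offsets %% rep(ps, each = nrow(grid@offsets)) != 0L) ||
      any(t(t(grid@offsets) + ps) > rep(padded, each = nrow(grid@offsets))))
    stop("consistency error: patch offsets off the tiling lattice")
  a <- array(0, padded)
  for (i in seq_along(grid@patches)) {
    p <- grid@patches[[i]]
    if (!identical(as.integer(dim(p)), ps))
      stop("consistency error: misshapen patch ", i)
    o <- grid@offsets[i, ]
    a[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]), o[3] + seq_len(ps[3])] <- p
  }
  a <- a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  if (grid@kind == "mask") BinaryMask(a > 0, grid@spacing)
  else ScanVolume(a, grid@spacing)
}
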