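#' Discrete spherical structuring element
#'
#' Builds the set of integer voxel offsets z with ||z|| <= radius under the
#' chosen metric. The default Euclidean ball of radius 2 contains 33 voxels
#' (1 + 6 + 12 + 8 + 6 by squared norm 0, 1, 2, 3, 4). The element always
#' contains the origin and is symmetric, so it equals its own reflection
#' and erosion/dilation form an adjoint pair.
#'
#' @param radius ball radius in voxels (default 2).
#' @param metric "euclidean" (default), "cityblock" or "chessboard".
#' @return A \linkS4class{StructuringElement}.
#' @export
structuringBall <- function(radius = 2,
                            metric = c("euclidean", "cityblock", "chessboard")) {
  metric <- match.arg(metric)
  if (!is.finite(radius) || radius < 0) stop("radius must be >= 0")
  r <- floor(radius)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  keep <- switch(metric,
    euclidean = rowSums(g^2) <= radius^2,
    cityblock = rowSums(abs(g)) <= radius,
    chessboard = apply(abs(g), 1L, max) <= radius)
  off <- g[keep, , drop = FALSE]
  dimnames(off) <- NULL
  storage.mode(off) <- "integer"
  new("StructuringElement", radius = radius, offsets = off, metric = metric)
}

#' Binary erosion by a structuring element
#'
#' A voxel stays foreground iff the element translated to it lies entirely
#' within the foreground. Voxels outside the grid count as background, so
#' objects touching the border erode (the standard convention).
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param B a \linkS4class{StructuringElement}; default Euclidean ball of
#'   radius 2.
#' @return The eroded \linkS4class{BinaryMask}.
#' @export
erodeMask <- function(mask, B = structuringBall(2)) {
  stopifnot(is(mask, "BinaryMask"), is(B, "StructuringElement"))
  out <- NULL
  for (i in seq_len(nrow(B@offsets))) {
    # out[z] requires mask[z + b] for every b: shift by -b and AND
    s <- .shift3(mask@data, -B@offsets[i, ], FALSE)
    out <- if (is.null(out)) s else out & s
  }
  BinaryMask(out, mask@spacing)
}

#' Binary dilation by a structuring element
#'
#' A voxel becomes foreground iff the reflected element translated to it
#' intersects the foreground; for the symmetric ball this is the union of
#' balls planted on every foreground voxel, clipped to the grid.
#'
#' @inheritParams erodeMask
#' @return The dilated \linkS4class{BinaryMask}.
#' @export
dilateMask <- function(mask, B = structuringBall(2)) {
  stopifnot(is(mask, "BinaryMask"), is(B, "StructuringElement"))
  out <- NULL
  for (i in seq_len(nrow(B@offsets))) {
    s <- .shift3(mask@data, B@offsets[i, ], FALSE)
    out <- if (is.null(out)) s else out | s
  }
  BinaryMask(out, mask@spacing)
}

#' Erosion-dilation (E&D) post-processing: morphological opening
#'
#' Erodes then dilates with the same element, i.e. a 3D morphological
#' opening. Removes foreground components too small to contain a translate
#' of the element - in particular the diminutive false-positive speckles a
#' single segmentation model tends to produce - while larger structures
#' survive with their boundary smoothed. Opening is anti-extensive (never
#' adds foreground) and idempotent, so per-slice TP and FP counts can only
#' decrease: specificity and PPV are non-decreasing while sensitivity and
#' NPV are non-increasing.
#'
#' @inheritParams erodeMask
#' @return The opened \linkS4class{BinaryMask}.
#' @export
openED <- function(mask, B = structuringBall(2)) {
  dilateMask(erodeMask(mask, B), B)
}
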