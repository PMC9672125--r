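#' Smooth a volume with a separable 3D Gaussian filter
#'
#' Standard deviation is given in voxels (the grid is assumed close to
#' isotropic, as in CBCT). The kernel is truncated at 4 sigma and
#' renormalised, so the volume sum is preserved for interior-supported
#' inputs. Boundaries are handled by reflective (symmetric) padding, which
#' avoids the edge darkening a zero-padded filter would introduce into
#' threshold-based ground-truth contouring.
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @param sigma standard deviation in voxels, >= 0; default 1. Zero returns
#'   the input unchanged.
#' @return The smoothed \linkS4class{ScanVolume}, same shape and spacing.
#' @export
gaussianSmooth <- function(vol, sigma = 1) {
  stopifnot(is(vol, "ScanVolume"))
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma == 0) return(vol)
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  a <- vol@data
  for (axis in 1:3) a <- .convolveAxis(a, w, r, axis)
  ScanVolume(a, vol@spacing)
}

# 1D correlation along `axis` with reflective (symmetric) padding:
# index pattern c(r:1, 1:n, n:(n-r+1)), i.e. the edge sample is repeated.
.convolveAxis <- function(a, w, r, axis) {
  n <- dim(a)[axis]
  reflect <- c(pmin(pmax(r:1, 1L), n), 1:n, pmin(pmax(n:(n - r + 1L), 1L), n))
  out <- array(0, dim(a))
  for (k in seq_along(w)) {
    idx <- reflect[(k - 1L) + seq_len(n)]
    shifted <- switch(axis,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE])
    out <- out + w[k] * shifted
  }
  out
}

#' Screen a volume for heavy metallic dental burden (MDB)
#'
#' Counts voxels above TH1 (metal-like density, default 3070 HU) and above
#' TH2 (enamel-like density, default 2500 HU) and forms the MDB ratio.
#' Under the default \code{definition = "count_ratio"}, MDBR is the ratio
#' of the two voxel counts, defined as 0 when no voxel exceeds TH2 (no
#' enamel-density voxels means no metal-burden verdict, a conservative
#' non-exclusion). A scan with MDBR > TH3 (default 0.4) is flagged heavy.
#' \code{definition = "threshold_ratio"} instead returns the literal ratio
#' TH1/TH2 of the thresholds themselves, which is constant in the volume
#' and retained only for comparison.
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @param th1 HU threshold for metal-like density (default 3070).
#' @param th2 HU threshold for enamel-like density (default 2500);
#'   must not exceed \code{th1}.
#' @param th3 MDBR cutoff defining heavy burden (default 0.4).
#' @param definition "count_ratio" (default) or "threshold_ratio".
#' @return An \linkS4class{MdbReport}.
#' @export
computeMDBR <- function(vol, th1 = 3070, th2 = 2500, th3 = 0.4,
                        definition = c("count_ratio", "threshold_ratio")) {
  stopifnot(is(vol, "ScanVolume"))
  definition <- match.arg(definition)
  if (th1 < th2) stop("parameter error: th1 must be >= th2")
  n1 <- sum(vol@data > th1)
  n2 <- sum(vol@data > th2)
  mdbr <- if (definition == "threshold_ratio") th1 / th2
          else if (n2 == 0) 0 else n1 / n2
  new("MdbReport", th1 = th1, th2 = th2, th3 = th3,
      countAboveTh1 = as.numeric(n1), countAboveTh2 = as.numeric(n2),
      mdbr = mdbr, heavy = mdbr > th3)
}

#' Flip a volume or mask along the horizontal (left-right) direction
#'
#' Reverses the x axis of every axial slice. Shape and spacing are
#' unchanged; applying the flip twice restores the input. Together with the
#' originals this yields the standard augmentation factor of 2.
#'
#' @param x a \linkS4class{ScanVolume} or \linkS4class{BinaryMask}.
#' @return An object of the same class, horizontally flipped.
#' @export
hflip <- function(x) {
  stopifnot(is(x, "ScanVolume") || is(x, "BinaryMask"))
  d <- dim(x@data)
  flipped <- x@data[d[1]:1, , , drop = FALSE]
  if (is(x, "ScanVolume")) ScanVolume(flipped, x@spacing)
  else BinaryMask(flipped, x@spacing)
}

#' Semiautomatic threshold contouring of teeth
#'
#' Reproduces the slice-by-slice semiautomatic ground-truth workflow: a
#' polygonal region of interest drawn on axial slices, an HU threshold
#' applied inside it, and per-slice filling of interior holes. Voxels
#' outside the ROI are background.
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @param roi either a single n x 2 matrix of polygon vertices in (x, y)
#'   voxel coordinates applied to every axial slice, or a list with one
#'   polygon (or NULL to skip the slice) per axial slice.
#' @param threshold HU threshold; voxels >= threshold inside the ROI become
#'   foreground.
#' @return A \linkS4class{BinaryMask}.
#' @export
semiautoContour <- function(vol, roi, threshold) {
  stopifnot(is(vol, "ScanVolume"))
  d <- dim(vol@data)
  polys <- if (is.list(roi) && !is.matrix(roi)) roi
           else rep(list(roi), d[3])
  if (length(polys) != d[3])
    stop("roi list must have one polygon per axial slice")
  mask <- array(FALSE, d)
  grid <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2])))
  for (z in seq_len(d[3])) {
    poly <- polys[[z]]
    if (is.null(poly)) next
    poly <- as.matrix(poly)
    if (nrow(poly) < 3L)
      stop("parameter error: polygon needs at least 3 vertices")
    if (any(poly[, 1] < 1 | poly[, 1] > d[1] |
            poly[, 2] < 1 | poly[, 2] > d[2]))
      stop("polygon vertices must lie inside the slice extent")
    inside <- matrix(mgcv::in.out(rbind(poly, poly[1, ]), grid), d[1], d[2])
    sl <- inside & (vol@data[, , z] >= threshold)
    if (any(sl)) sl <- .fillHoles2D(sl)
    mask[, , z] <- sl
  }
  BinaryMask(mask, vol@spacing)
}

# Fill interior holes of a 2D binary slice (background not reachable from
# the slice border becomes foreground).
.fillHoles2D <- function(sl) {
  filled <- EBImage::fillHull(EBImage::Image(sl * 1))
  as.matrix(filled) > 0
}
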