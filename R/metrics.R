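#' Per-slice confusion counts and the six segmentation metrics
#'
#' Compares a prediction to ground truth slice by slice along the chosen
#' view (axial by default, the acquisition plane) and computes, per slice:
#' TP, TN, FP, FN voxel counts and the derived Dice similarity coefficient
#' DSC = 2TP/(FP + 2TP + FN), accuracy (TP+TN)/total, sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), positive predictive value
#' TP/(TP+FP) and negative predictive value TN/(TN+FN).
#'
#' Undefined ratios are reported as NA: sensitivity on slices with empty
#' ground truth, PPV on slices with empty prediction, specificity/NPV on
#' degenerate all-foreground slices. One rule is fixed: a slice whose
#' ground truth is empty but which contains predicted foreground has
#' DSC = 0 (the formula gives 0/FP), so stray false positives on
#' tooth-free slices are fully penalised. A slice where both prediction
#' and ground truth are empty leaves DSC = NA here; the aggregation policy
#' decides its score.
#'
#' @param pred predicted \linkS4class{BinaryMask}.
#' @param gt ground-truth \linkS4class{BinaryMask}, congruent with pred.
#' @param axis "axial", "coronal" or "sagittal" slicing direction.
#' @return A data.frame with one row per slice: slice, tp, tn, fp, fn,
#'   dsc, ac, sn, sp, ppv, npv.
#' @export
confusionPerSlice <- function(pred, gt,
                              axis = c("axial", "coronal", "sagittal")) {
  stopifnot(is(pred, "BinaryMask"), is(gt, "BinaryMask"))
  axis <- match.arg(axis)
  .checkCongruent(pred, gt)
  ax <- .viewAxis[[axis]]
  d <- dim(pred@data)
  perm <- c(setdiff(1:3, ax), ax)
  p <- matrix(aperm(pred@data, perm), ncol = d[ax])
  g <- matrix(aperm(gt@data, perm), ncol = d[ax])
  tp <- colSums(p & g)
  fp <- colSums(p & !g)
  fn <- colSums(!p & g)
  tn <- colSums(!p & !g)
  df <- data.frame(slice = seq_len(d[ax]), tp = tp, tn = tn, fp = fp, fn = fn)
  df$dsc <- .safeRatio(2 * tp, fp + 2 * tp + fn)
  df$ac <- (tp + tn) / (tp + tn + fp + fn)
  df$sn <- .safeRatio(tp, tp + fn)
  df$sp <- .safeRatio(tn, tn + fp)
  df$ppv <- .safeRatio(tp, tp + fp)
  df$npv <- .safeRatio(tn, tn + fn)
  df
}

.safeRatio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Aggregate per-slice metrics
#'
#' Pools slices (optionally from several volumes via rbind) into mean and
#' median summaries per metric. Undefined (NA) slice values are excluded
#' from that metric's aggregate, except DSC on slices where prediction and
#' ground truth are both empty: under the default policy
#' \code{dscEmpty = "one"} such slices score DSC 1 (no error counts as
#' perfect agreement); \code{dscEmpty = "exclude"} drops them instead.
#' Both policies are reported by the per-metric count of contributing
#' slices.
#'
#' @param slices data.frame from \code{\link{confusionPerSlice}} (or
#'   several, row-bound).
#' @param dscEmpty policy for empty-prediction/empty-truth slices: "one"
#'   (default) or "exclude".
#' @return A data.frame with one row per metric: metric, mean, median, n
#'   (number of slices contributing).
#' @export
aggregateSlices <- function(slices, dscEmpty = c("one", "exclude")) {
  dscEmpty <- match.arg(dscEmpty)
  if (!is.data.frame(slices) || nrow(slices) == 0L)
    stop("data error: empty slice list")
  dsc <- slices$dsc
  if (dscEmpty == "one") {
    emptyBoth <- is.na(dsc) & slices$tp + slices$fp + slices$fn == 0
    dsc[emptyBoth] <- 1
  }
  vals <- list(dsc = dsc, ac = slices$ac, sn = slices$sn, sp = slices$sp,
               ppv = slices$ppv, npv = slices$npv)
  out <- do.call(rbind, lapply(names(vals), function(m) {
    v <- vals[[m]][!is.na(vals[[m]])]
    data.frame(metric = m,
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Whole-volume confusion counts (secondary convenience)
#'
#' @param pred,gt congruent \linkS4class{BinaryMask} objects.
#' @return Named numeric vector tp, tn, fp, fn, dsc over all voxels.
#' @export
volumeConfusion <- function(pred, gt) {
  stopifnot(is(pred, "BinaryMask"), is(gt, "BinaryMask"))
  .checkCongruent(pred, gt)
  tp <- sum(pred@data & gt@data)
  fp <- sum(pred@data & !gt@data)
  fn <- sum(!pred@data & gt@data)
  tn <- sum(!pred@data & !gt@data)
  c(tp = tp, tn = tn, fp = fp, fn = fn,
    dsc = if (fp + 2 * tp + fn > 0) 2 * tp / (fp + 2 * tp + fn) else NA_real_)
}

#' Patient-level fourfold cross-validation plan
#'
#' Randomly partitions patients into \code{nFolds} subsets of (nearly)
#' equal size under a seed, then enumerates the folds: fold f tests on
#' subset f and trains on the rest, so every patient is tested exactly
#' once. With 24 patients and 4 folds each subset holds 6 patients.
#'
#' @param patientIds character or integer vector of patient identifiers.
#' @param nFolds number of folds (default 4).
#' @param seed RNG seed for the partition.
#' @return A list of class "FoldPlan" with elements \code{subsets} (named
#'   integer vector: patient -> subset) and \code{folds} (list of
#'   \code{list(test, train)} id vectors).
#' @export
makeFolds <- function(patientIds, nFolds = 4L, seed = 1L) {
  n <- length(patientIds)
  if (anyDuplicated(patientIds)) stop("data error: duplicate patient ids")
  if (n < nFolds) stop("data error: fewer patients than folds")
  shuffled <- .withSeed(seed, sample(patientIds))
  sizes <- rep(n %/% nFolds, nFolds) + (seq_len(nFolds) <= n %% nFolds)
  subset <- rep(seq_len(nFolds), times = sizes)
  subsets <- stats::setNames(subset[match(patientIds, shuffled)],
                             as.character(patientIds))
  folds <- lapply(seq_len(nFolds), function(f)
    list(test = patientIds[subsets == f], train = patientIds[subsets != f]))
  structure(list(subsets = subsets, folds = folds), class = "FoldPlan")
}

#' @export
print.FoldPlan <- function(x, ...) {
  sizes <- table(x$subsets)
  cat(sprintf("FoldPlan: %d patients in %d subsets (sizes %s)\n",
              length(x$subsets), length(x$folds),
              paste(sizes, collapse = ", ")))
  invisible(x)
}
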