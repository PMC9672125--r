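#' Per-voxel majority vote over aligned binary masks
#'
#' The fused voxel is foreground iff at least k of the input masks mark it
#' foreground. The default k is the strict majority floor(n/2) + 1.
#'
#' @param masks list of congruent \linkS4class{BinaryMask} objects (>= 1).
#' @param k minimum affirmative votes, in [1, n]; default strict majority.
#' @return The fused \linkS4class{BinaryMask}.
#' @export
majorityVote <- function(masks, k = NULL) {
  if (length(masks) < 1L) stop("at least one mask required")
  stopifnot(all(vapply(masks, function(m) is(m, "BinaryMask"), logical(1))))
  n <- length(masks)
  if (is.null(k)) k <- n %/% 2L + 1L
  if (length(k) != 1L || is.na(k) || k < 1L || k > n)
    stop("parameter error: k must lie in [1, ", n, "]")
  d <- dim(masks[[1]]@data)
  for (m in masks) .checkCongruent(masks[[1]], m)
  counts <- Reduce(`+`, lapply(masks, function(m) m@data * 1L))
  BinaryMask(counts >= k, masks[[1]]@spacing)
}

#' Built-in voting schemes
#'
#' The four stock recipes over the five trained models 2Da, 2Dc, 2Ds,
#' 2.5Da and 3D:
#' \itemize{
#'   \item \code{2.5Dv}: vote of \{2Da, 2Dc, 2Ds\} with k = 2.
#'   \item \code{3.5Dv3}: nested vote of \{2.5Dv, 2.5Da, 3D\} with k = 2 -
#'     its first voter is itself the 2.5Dv vote, which is not equivalent to
#'     flattening to five voters.
#'   \item \code{3.5Dv4}: vote of \{2Da, 2Dc, 2Ds, 3D\} with k = 3 (strict
#'     majority; a 2-2 tie is negative, the conservative choice for
#'     false-positive removal).
#'   \item \code{3.5Dv5}: vote of \{2Da, 2Dc, 2Ds, 2.5Da, 3D\} with k = 3.
#' }
#'
#' @param name one of "2.5Dv", "3.5Dv3", "3.5Dv4", "3.5Dv5".
#' @return A \linkS4class{VotingScheme}.
#' @export
builtinScheme <- function(name = c("2.5Dv", "3.5Dv3", "3.5Dv4", "3.5Dv5")) {
  name <- match.arg(name)
  v25 <- VotingScheme("2.5Dv", list("2Da", "2Dc", "2Ds"), k = 2L)
  switch(name,
    "2.5Dv" = v25,
    "3.5Dv3" = VotingScheme("3.5Dv3", list(v25, "2.5Da", "3D"), k = 2L),
    "3.5Dv4" = VotingScheme("3.5Dv4", list("2Da", "2Dc", "2Ds", "3D"), k = 3L),
    "3.5Dv5" = VotingScheme("3.5Dv5",
                            list("2Da", "2Dc", "2Ds", "2.5Da", "3D"), k = 3L))
}

#' Apply a (possibly nested) voting scheme to a prediction set
#'
#' Leaf voters are looked up by model name in \code{preds}; nested schemes
#' are evaluated depth-first, so e.g. 3.5Dv3 first fuses the three
#' orthogonal 2D predictions into the 2.5Dv vote and then votes that
#' result against the 2.5Da and 3D predictions with k = 2 of 3.
#'
#' @param preds a \linkS4class{PredictionSet}.
#' @param scheme a \linkS4class{VotingScheme} or the name of a built-in
#'   scheme (see \code{\link{builtinScheme}}).
#' @return The fused \linkS4class{BinaryMask}.
#' @export
applyScheme <- function(preds, scheme) {
  stopifnot(is(preds, "PredictionSet"))
  if (is.character(scheme)) scheme <- builtinScheme(scheme)
  stopifnot(is(scheme, "VotingScheme"))
  .evalScheme(preds, scheme, depth = 0L)
}

.evalScheme <- function(preds, scheme, depth) {
  if (depth > 32L)
    stop("scheme error: voting schemes nested deeper than 32 levels")
  validObject(scheme)
  voted <- lapply(scheme@voters, function(v) {
    if (is.character(v)) {
      m <- preds@masks[[v]]
      if (is.null(m))
        stop("lookup error: voter '", v, "' missing from prediction set")
      m
    } else {
      .evalScheme(preds, v, depth + 1L)
    }
  })
  k <- if (is.na(scheme@k)) NULL else scheme@k
  majorityVote(voted, k)
}

#' Analytic false-positive suppression of an independent-voter majority
#'
#' For n voters with independent per-voxel background false-positive
#' probability p, the fused false-positive rate at threshold k is the
#' binomial tail P(X >= k), X ~ Binomial(n, p). This is the idealised
#' companion to the empirical observation that majority voting removes
#' model false positives: at n = 5, p = 0.01, k = 3 the fused rate drops
#' to about 1e-5.
#'
#' @param nVoters number of voters n.
#' @param perVoterFp per-voxel false-positive probability p in [0, 1].
#' @param k vote threshold in [1, n].
#' @return The expected fused false-positive probability.
#' @export
fpSuppressionCurve <- function(nVoters, perVoterFp, k) {
  if (!is.finite(perVoterFp) || perVoterFp < 0 || perVoterFp > 1)
    stop("parameter error: p must lie in [0, 1]")
  if (!is.finite(k) || k < 1 || k > nVoters)
    stop("parameter error: k must lie in [1, n]")
  stats::pbinom(k - 1, size = nVoters, prob = perVoterFp, lower.tail = FALSE)
}
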