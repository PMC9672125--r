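# Nonparametric statistics used to compare segmentation performance:
# Lilliefors-corrected KS normality screen, paired Wilcoxon signed-rank
# (before/after E&D), and Kruskal-Wallis with Dunn's Bonferroni-adjusted
# post hoc over the nine models.

.statsResult <- function(test, statistic, p, posthoc = NULL,
                         degenerate = FALSE, note = NULL) {
  structure(list(test = test, statistic = statistic, p = p,
                 posthoc = posthoc, degenerate = degenerate, note = note),
            class = "StatsResult")
}

#' @export
print.StatsResult <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s: degenerate data (%s)\n", x$test, x$note))
  } else {
    cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic, x$p))
    if (!is.null(x$posthoc))
      cat(sprintf("  post hoc: %d pairwise comparisons (Bonferroni)\n",
                  nrow(x$posthoc)))
  }
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples, used to compare a metric
#' before and after E&D post-processing. Zero differences are dropped. For
#' n <= 25 remaining pairs the p value is computed from the exact
#' sign-flip permutation distribution of the signed-rank statistic
#' (midranks, so ties in the absolute differences are handled exactly);
#' larger samples use the tie-corrected normal approximation. If every
#' difference is zero the result is flagged degenerate rather than tested.
#'
#' @param x,y equal-length paired samples.
#' @return A "StatsResult" list: test, statistic (V, the positive-rank
#'   sum), p, degenerate flag.
#' @export
pairedWilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  diffs <- x - y
  nz <- diffs[diffs != 0]
  if (length(nz) == 0L)
    return(.statsResult("paired Wilcoxon signed-rank", NA_real_, NA_real_,
                        degenerate = TRUE, note = "all differences zero"))
  if (length(nz) < 5L)
    warning("fewer than 5 non-zero differences; test has little power")
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (length(nz) <= 25L) {
    p <- .exactSignedRankP(r, v)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    p <- ht$p.value
  }
  .statsResult("paired Wilcoxon signed-rank", v, p)
}

# Exact two-sided sign-flip permutation p for the positive-rank sum V.
# Works on doubled midranks (integers even under ties); the distribution
# of V over all 2^n sign assignments is built by subset-sum convolution.
.exactSignedRankP <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with 2V = s
  counts[1L] <- 1
  for (w in r2) {
    shifted <- c(numeric(w), counts[seq_len(total + 1L - w)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(r2)
  v2 <- as.integer(round(2 * v))
  pLow <- sum(counts[seq_len(v2 + 1L)])
  pHigh <- sum(counts[(v2 + 1L):(total + 1L)])
  min(1, 2 * min(pLow, pHigh))
}

#' Kruskal-Wallis test with Dunn's Bonferroni-adjusted post hoc
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p value across >= 3
#' groups, followed by Dunn's pairwise rank comparisons over all group
#' pairs with Bonferroni adjustment (adjusted p = min(1, m * raw p) for m
#' pairs; 9 groups give 36 comparisons).
#'
#' @param groups named (or unnamed) list of >= 3 numeric samples, each of
#'   size >= 2.
#' @return A "StatsResult" list with the H statistic, its p value and a
#'   \code{posthoc} data.frame (group1, group2, z, p, pAdjusted).
#' @export
kruskalWallisBonferroni <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("parameter error: need >= 3 groups (use pairedWilcoxon for 2)")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("parameter error: each group needs >= 2 observations")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  # Dunn's z tests on pooled ranks with tie correction
  pooled <- unlist(groups, use.names = FALSE)
  grp <- rep(names(groups), vapply(groups, length, integer(1)))
  rk <- rank(pooled)
  N <- length(pooled)
  ties <- table(pooled)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  meanRanks <- tapply(rk, grp, mean)
  ns <- tapply(rk, grp, length)
  pairs <- utils::combn(names(groups), 2L)
  ph <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tieTerm) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (meanRanks[[a]] - meanRanks[[b]]) / se
    data.frame(group1 = a, group2 = b, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }))
  ph$pAdjusted <- stats::p.adjust(ph$p, method = "bonferroni")
  rownames(ph) <- NULL
  .statsResult("Kruskal-Wallis", unname(kw$statistic), kw$p.value,
               posthoc = ph)
}

#' Kolmogorov-Smirnov normality screen (Lilliefors)
#'
#' KS test against a normal distribution with mean and SD estimated from
#' the sample (Lilliefors correction, since no fixed reference normal is
#' available). Constant samples are flagged degenerate.
#'
#' @param x numeric sample of size >= 5.
#' @return A "StatsResult" list: test, statistic (D), p.
#' @export
ksNormality <- function(x) {
  if (length(x) < 5L) stop("parameter error: need n >= 5")
  if (stats::sd(x) == 0)
    return(.statsResult("Lilliefors KS normality", NA_real_, NA_real_,
                        degenerate = TRUE, note = "constant sample"))
  ht <- nortest::lillie.test(x)
  .statsResult("Lilliefors KS normality", unname(ht$statistic), ht$p.value)
}
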