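# Shared fixtures and independent oracles used across the suite.

randMask <- function(d, p = 0.5, seed = 1) {
  withr::with_seed(seed, BinaryMask(array(runif(prod(d)) < p, d)))
}

randVolume <- function(d, seed = 1, mean = 0, sd = 1) {
  withr::with_seed(seed, ScanVolume(array(rnorm(prod(d), mean, sd), d)))
}

# Brute-force evaluation of erosion/dilation straight from the set
# definitions: for every voxel z, gather mask values at z + b over all
# element offsets b (out-of-grid reads count as background).
bruteMorph <- function(mask, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  d <- dim(mask)
  coords <- arrayInd(seq_len(prod(d)), d)
  acc <- if (op == "erode") rep(TRUE, nrow(coords)) else rep(FALSE, nrow(coords))
  for (i in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2L, offsets[i, ], "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
    val <- rep(FALSE, nrow(coords))
    val[inside] <- mask[nb[inside, , drop = FALSE]]
    acc <- if (op == "erode") acc & val else acc | val
  }
  array(acc, d)
}

# Hole filling oracle: flood-fill the background from the slice border
# (4-connectivity); anything unreached is an interior hole.
floodFillHoles <- function(sl) {
  d <- dim(sl)
  reach <- matrix(FALSE, d[1], d[2])
  queue <- which(!sl & (row(sl) %in% c(1, d[1]) | col(sl) %in% c(1, d[2])))
  reach[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    i <- (idx - 1) %% d[1] + 1; j <- (idx - 1) %/% d[1] + 1
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > d[1] || nb[2] < 1 || nb[2] > d[2]) next
      k <- nb[1] + d[1] * (nb[2] - 1)
      if (!sl[k] && !reach[k]) { reach[k] <- TRUE; queue <- c(queue, k) }
    }
  }
  sl | !reach
}

# Slice-average DSC with the empty-empty-scores-one policy.
meanSliceDsc <- function(pred, gt) {
  aggregateSlices(confusionPerSlice(pred, gt))$mean[1]
}

# Small phantom + degradation configs reused by the simulation tests.
smallPhantom <- function(seed = 1, noiseSd = 30) {
  makePhantom(phantomConfig(shape = c(32, 32, 32), nTeeth = 4,
                            crownSemiAxes = c(2.5, 2.5, 3), rootRadius = 1.5,
                            rootLength = 8, noiseSd = noiseSd, seed = seed))
}

speckleCfg <- function(seed = 1, rate = 2, fn = 0.2, jitter = 1) {
  degradationConfig(fpSpeckleRate = rate, speckleSize = 1, fnDropRate = fn,
                    boundaryJitter = jitter, seed = seed)
}

voterNames <- c("2Da", "2Dc", "2Ds", "2.5Da", "3D")
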