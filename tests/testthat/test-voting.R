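# Encode all 2^n voter patterns as an (2^n x 1 x 1) grid: voxel j carries
# bit i of j - 1 in voter i, so every pattern is checked at once.
patternMasks <- function(n) {
  lapply(seq_len(n), function(i)
    BinaryMask(array(bitwAnd(0:(2^n - 1), bitwShiftL(1L, i - 1L)) > 0,
                     c(2^n, 1, 1))))
}

test_that("majority vote equals exhaustive per-voxel counting for all voter patterns", {
  for (n in 3:5) {
    masks <- patternMasks(n)
    counts <- rowSums(sapply(masks, function(m) as.vector(voxels(m))))
    for (k in seq_len(n)) {
      got <- as.vector(voxels(majorityVote(masks, k)))
      expect_identical(got, counts >= k)
    }
  }
  # n = 5, k = 3: positive for exactly the 16 patterns with >= 3 ones
  masks <- patternMasks(5)
  expect_equal(sum(voxels(majorityVote(masks, 3))), 16)
})

test_that("majority vote matches counting on random masks and honours contracts", {
  for (s in 1:5) {
    n <- 3 + (s %% 3)
    masks <- lapply(seq_len(n), function(i)
      randMask(c(16, 16, 16), 0.5, seed = 1000 + 10 * s + i))
    counts <- Reduce(`+`, lapply(masks, function(m) voxels(m) * 1L))
    for (k in c(1L, (n %/% 2L) + 1L, n))
      expect_identical(voxels(majorityVote(masks, k)), counts >= k)
    # default k is the strict majority
    expect_identical(voxels(majorityVote(masks)), counts >= (n %/% 2L + 1L))
  }
  same <- randMask(c(4, 4, 4), 0.5, seed = 1)
  expect_identical(voxels(majorityVote(list(same, same, same), 2)),
                   voxels(same))
  expect_identical(voxels(majorityVote(list(same), 1)), voxels(same))
  expect_error(majorityVote(list(same, same), 3), "k must lie")
  expect_error(majorityVote(list(same, randMask(c(5, 4, 4), 0.5, 2)), 1),
               "congruent")
})

test_that("voting is permutation invariant, monotone in k and sandwiched", {
  masks <- lapply(1:5, function(i) randMask(c(8, 8, 8), 0.5, seed = 40 + i))
  perm <- withr::with_seed(1, sample(5))
  for (k in 1:5) {
    v1 <- voxels(majorityVote(masks, k))
    expect_identical(v1, voxels(majorityVote(masks[perm], k)))
    if (k > 1)
      expect_true(all(v1 <= voxels(majorityVote(masks, k - 1L))))
    inter <- Reduce(`&`, lapply(masks, voxels))
    uni <- Reduce(`|`, lapply(masks, voxels))
    expect_true(all(v1[inter]))
    expect_false(any(v1[!uni]))
  }
})

test_that("built-in schemes fuse as drawn, with 3.5Dv3 nesting the 2.5Dv vote", {
  d <- c(2, 2, 1)
  at <- function(on) BinaryMask(array(rep(on, prod(d)), d))
  # the three orthogonal 2D models vote yes; 2.5Da and 3D vote no
  preds <- PredictionSet(list(
    "2Da" = at(TRUE), "2Dc" = at(TRUE), "2Ds" = at(TRUE),
    "2.5Da" = at(FALSE), "3D" = at(FALSE)))
  expect_true(all(voxels(applyScheme(preds, "2.5Dv"))))     # 3 of 3
  expect_true(all(voxels(applyScheme(preds, "3.5Dv5"))))    # 3 of 5 >= 3
  expect_true(all(voxels(applyScheme(preds, "3.5Dv4"))))    # 3 of 4 >= 3
  # nested: 2.5Dv votes yes but 2.5Da and 3D vote no -> 1 of 3 < 2
  expect_false(any(voxels(applyScheme(preds, "3.5Dv3"))))
  # flip: only 2.5Da and 3D vote yes
  preds2 <- PredictionSet(list(
    "2Da" = at(FALSE), "2Dc" = at(FALSE), "2Ds" = at(FALSE),
    "2.5Da" = at(TRUE), "3D" = at(TRUE)))
  expect_true(all(voxels(applyScheme(preds2, "3.5Dv3"))))   # 2 of 3
  expect_false(any(voxels(applyScheme(preds2, "3.5Dv5")))) # 2 of 5 < 3
  # 3.5Dv4 tie rule: 2-2 is negative
  preds3 <- PredictionSet(list(
    "2Da" = at(TRUE), "2Dc" = at(TRUE), "2Ds" = at(FALSE), "3D" = at(FALSE)))
  expect_false(any(voxels(applyScheme(preds3, "3.5Dv4"))))
})

test_that("scheme application resolves leaves, identities and errors", {
  m <- randMask(c(6, 6, 6), 0.5, seed = 77)
  preds <- PredictionSet(list(solo = m, other = randMask(c(6, 6, 6), 0.5, 78)))
  single <- VotingScheme("just-solo", list("solo"), k = 1L)
  expect_identical(voxels(applyScheme(preds, single)), voxels(m))
  missing <- VotingScheme("bad", list("nonexistent"), k = 1L)
  expect_error(applyScheme(preds, missing), "lookup error")
  # random prediction sets: nested v3 differs from flat v5 somewhere
  ph <- smallPhantom(seed = 3)
  ps <- simulatePredictionSet(ph$mask, speckleCfg(rate = 4, fn = 0.4),
                              nVoters = 5, rho = 0, masterSeed = 5)
  names(ps@masks) <- voterNames
  v3 <- voxels(applyScheme(ps, "3.5Dv3"))
  v5 <- voxels(applyScheme(ps, "3.5Dv5"))
  expect_gt(sum(v3 != v5), 0)
})

test_that("the analytic FP suppression curve is the binomial tail", {
  p <- 0.01
  manual <- choose(5, 3) * p^3 * (1 - p)^2 + choose(5, 4) * p^4 * (1 - p) + p^5
  expect_equal(fpSuppressionCurve(5, p, 3), manual, tolerance = 1e-12)
  expect_equal(fpSuppressionCurve(7, 0.2, 1), 1 - (1 - 0.2)^7)
  expect_equal(fpSuppressionCurve(5, 0, 3), 0)
  expect_equal(fpSuppressionCurve(4, 1, 4), 1)
  expect_error(fpSuppressionCurve(5, 1.2, 3), "parameter")
  expect_error(fpSuppressionCurve(5, 0.5, 6), "parameter")
})
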