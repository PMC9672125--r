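test_that("per-slice metrics follow their defining formulas", {
  # constructed slice: tp = 2, fp = 1, fn = 1 -> DSC = 4/6
  p <- array(FALSE, c(4, 4, 1)); g <- array(FALSE, c(4, 4, 1))
  p[1, 1, 1] <- p[2, 1, 1] <- p[3, 1, 1] <- TRUE
  g[1, 1, 1] <- g[2, 1, 1] <- g[4, 1, 1] <- TRUE
  df <- confusionPerSlice(BinaryMask(p), BinaryMask(g))
  expect_equal(df$tp, 2); expect_equal(df$fp, 1); expect_equal(df$fn, 1)
  expect_equal(df$dsc, 2 * 2 / (1 + 4 + 1))
  expect_equal(df$ac, (2 + 12) / 16)
  expect_equal(df$sn, 2 / 3)
  expect_equal(df$sp, 12 / 13)
  expect_equal(df$ppv, 2 / 3)
  expect_equal(df$npv, 12 / 13)

  m <- randMask(c(8, 8, 4), 0.4, seed = 21)
  same <- confusionPerSlice(m, m)
  expect_true(all(same$dsc[!is.na(same$dsc)] == 1))
  expect_true(all(same$ac == 1))
})

test_that("false positives on tooth-free slices zero the slice DSC", {
  p <- array(FALSE, c(5, 5, 2)); p[3, 3, 1] <- TRUE
  g <- array(FALSE, c(5, 5, 2))
  df <- confusionPerSlice(BinaryMask(p), BinaryMask(g))
  expect_equal(df$dsc[1], 0)          # fp > 0, empty GT
  expect_true(is.na(df$dsc[2]))       # empty-empty left to policy
  expect_true(is.na(df$sn[1]))        # no GT positives
  agg1 <- aggregateSlices(df, dscEmpty = "one")
  expect_equal(agg1$mean[agg1$metric == "dsc"], 0.5)
  agg0 <- aggregateSlices(df, dscEmpty = "exclude")
  expect_equal(agg0$mean[agg0$metric == "dsc"], 0)
})

test_that("slice counts conserve the whole-volume confusion", {
  pr <- randMask(c(9, 10, 11), 0.3, seed = 31)
  gt <- randMask(c(9, 10, 11), 0.3, seed = 32)
  for (ax in c("axial", "coronal", "sagittal")) {
    df <- confusionPerSlice(pr, gt, axis = ax)
    expect_equal(sum(df$tp + df$tn + df$fp + df$fn), prod(c(9, 10, 11)))
    # brute-force whole-volume counts
    expect_equal(sum(df$tp), sum(voxels(pr) & voxels(gt)))
    expect_equal(sum(df$fp), sum(voxels(pr) & !voxels(gt)))
    expect_equal(sum(df$fn), sum(!voxels(pr) & voxels(gt)))
    expect_equal(sum(df$tn), sum(!voxels(pr) & !voxels(gt)))
  }
  vc <- volumeConfusion(pr, gt)
  df <- confusionPerSlice(pr, gt)
  expect_equal(unname(vc["tp"]), sum(df$tp))
})

test_that("DSC is the harmonic mean of PPV and sensitivity; swapping roles swaps them", {
  pr <- randMask(c(12, 12, 6), 0.4, seed = 41)
  gt <- randMask(c(12, 12, 6), 0.4, seed = 42)
  df <- confusionPerSlice(pr, gt)
  ok <- !is.na(df$ppv) & !is.na(df$sn) & (df$ppv + df$sn) > 0
  expect_true(any(ok))
  expect_equal(df$dsc[ok], 2 * df$ppv[ok] * df$sn[ok] / (df$ppv[ok] + df$sn[ok]))
  swapped <- confusionPerSlice(gt, pr)
  expect_equal(df$dsc, swapped$dsc)
  expect_equal(df$ac, swapped$ac)
  expect_equal(df$sn, swapped$ppv)
  expect_equal(df$sp, swapped$npv)
  # accuracy is a prevalence-weighted combination of sn and sp
  pos <- df$tp + df$fn
  expect_equal(df$ac, (df$sn * pos + df$sp * (144 - pos)) / 144)
})

test_that("aggregation averages slices and respects undefined-value policies", {
  df <- data.frame(slice = 1:2, tp = c(1, 2), tn = c(1, 1), fp = c(0, 0),
                   fn = c(0, 0), dsc = c(0.4, 0.8), ac = c(1, 1),
                   sn = c(0.9, NA), sp = c(1, 1), ppv = c(1, NA),
                   npv = c(1, 1))
  agg <- aggregateSlices(df)
  expect_equal(agg$mean[agg$metric == "dsc"], 0.6)
  expect_equal(agg$median[agg$metric == "dsc"], 0.6)
  expect_equal(agg$mean[agg$metric == "sn"], 0.9)
  expect_equal(agg$n[agg$metric == "sn"], 1)
  expect_error(aggregateSlices(df[0, ]), "empty")
  # order-statistic check: dsc = k/100 over 101 slices -> median 0.5
  df2 <- df[rep(1, 101), ]
  df2$dsc <- (0:100) / 100
  agg2 <- aggregateSlices(df2)
  expect_equal(agg2$median[agg2$metric == "dsc"], 0.5)
})

test_that("fourfold cross-validation partitions patients evenly and reproducibly", {
  ids <- sprintf("pat%02d", 1:24)
  fp <- makeFolds(ids, 4, seed = 7)
  expect_equal(unname(table(fp$subsets)), rep(6L, 4), ignore_attr = TRUE)
  tested <- unlist(lapply(fp$folds, `[[`, "test"))
  expect_setequal(tested, ids)
  expect_equal(length(tested), 24)
  for (f in fp$folds) {
    expect_length(f$train, 18)
    expect_length(intersect(f$test, f$train), 0)
  }
  expect_identical(makeFolds(ids, 4, seed = 7), fp)
  expect_false(identical(makeFolds(ids, 4, seed = 8)$subsets, fp$subsets))
  small <- makeFolds(letters[1:8], 4, seed = 1)
  expect_equal(unname(table(small$subsets)), rep(2L, 4), ignore_attr = TRUE)
  expect_error(makeFolds(letters[1:3], 4), "fewer patients")
})
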