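# independent layer-by-layer parameter tally for the U-Net topology
tallyParams <- function(nd, depth, ff, cin) {
  k <- 3^nd
  total <- 0
  cprev <- cin
  for (l in seq_len(depth)) {
    cl <- ff * 2^(l - 1)
    total <- total + (k * cprev + 1) * cl + (k * cl + 1) * cl
    cprev <- cl
  }
  for (l in seq_len(depth - 1)) {
    cl <- ff * 2^(l - 1)
    total <- total + (k * 2 * cl + 1) * cl +   # conv after upsampling
      (k * 2 * cl + 1) * cl +                  # post-concat conv
      (k * cl + 1) * cl
  }
  total + (ff + 1) * 2                         # 1x1 dual-class head
}

zeroedPredictor <- function(spec, fgLogit = log(9)) {
  pred <- buildPredictor(spec, seed = 1)
  for (L in asNamespace("VoteSeg")$.allLayers(pred$net)) {
    L$W[] <- 0
    L$b[] <- 0
  }
  pred$net$out$b <- c(0, fgLogit)   # softmax -> constant fg probability
  pred
}

test_that("parameter counts match an independent layer-by-layer tally", {
  cases <- list(
    list(spec = unetSpec("2d", depth = 2, firstFeatures = 8,
                         inputShape = c(32, 32)), nd = 2, cin = 1),
    list(spec = unetSpec("2.5d", depth = 3, firstFeatures = 4,
                         inputShape = c(16, 16)), nd = 2, cin = 3),
    list(spec = unetSpec("3d", depth = 2, firstFeatures = 4,
                         patchShape = c(8, 8, 8)), nd = 3, cin = 1))
  for (cs in cases) {
    pred <- buildPredictor(cs$spec, seed = 2)
    expect_equal(countParams(pred),
                 tallyParams(cs$nd, cs$spec$depth, cs$spec$firstFeatures,
                             cs$cin))
  }
})

test_that("builds are deterministic in the seed and reject bad geometry", {
  spec <- unetSpec("2d", depth = 2, firstFeatures = 4, inputShape = c(16, 16))
  x <- withr::with_seed(3, array(runif(16 * 16), c(16, 16, 1)))
  fwd <- function(p) asNamespace("VoteSeg")$.unetForward(p, x)$p
  expect_identical(fwd(buildPredictor(spec, seed = 9)),
                   fwd(buildPredictor(spec, seed = 9)))
  expect_false(identical(fwd(buildPredictor(spec, seed = 9)),
                         fwd(buildPredictor(spec, seed = 10))))
  expect_error(unetSpec("2d", depth = 4, inputShape = c(50, 50)),
               "not divisible")
})

test_that("the plateau scheduler follows x0.95 arithmetic and the early-stop window", {
  frozen <- rep(0.5, 60)
  sched <- plateauSchedule(frozen, lr0 = 1e-4)
  # two decays within 20 epochs of frozen loss
  expect_equal(sched$lrAfter[sched$epoch == 20], 1e-4 * 0.95^2,
               tolerance = 1e-12)
  expect_equal(attr(sched, "stopEpoch"), 50)   # halts before the cap
  expect_equal(nrow(sched), 50)
  # improving losses never decay
  improving <- 1 / (1:40)
  s2 <- plateauSchedule(improving, lr0 = 1e-3)
  expect_true(all(s2$lr == 1e-3))
  expect_true(is.na(attr(s2, "stopEpoch")))
  # recovery resets the window: stall 9 epochs, improve, stall again
  seq3 <- c(rep(0.5, 9), 0.4, rep(0.4, 9), 0.3)
  s3 <- plateauSchedule(seq3, lr0 = 1)
  expect_true(all(s3$lr == 1))
})

test_that("training history bookkeeping and data contracts hold", {
  ph <- smallPhantom(seed = 4)
  spec <- unetSpec("2d", depth = 2, firstFeatures = 4, inputShape = c(32, 32),
                   lr0 = 1e-3, batch = 2, epochs = 1)
  pairs <- makeTrainingPairs(ph$volume, ph$mask, spec)[15:18]
  pred <- buildPredictor(spec, seed = 5)
  res <- trainPredictor(pred, pairs, pairs[1:2], seed = 6)
  expect_equal(nrow(res$history), 1)
  expect_named(res$history, c("epoch", "loss", "valLoss", "lr"))
  expect_equal(res$history$lr, spec$lr0)
  expect_error(trainPredictor(pred, list(), pairs[1:2]), "empty")
  bad <- pairs
  bad[[1]]$y[1] <- 0.5
  expect_error(trainPredictor(pred, bad, pairs[1:2]), "binary")
  # identical seeds reproduce the history bit for bit
  r1 <- trainPredictor(buildPredictor(spec, seed = 5), pairs, pairs[1:2],
                       seed = 6)
  expect_identical(r1$history, res$history)
})

test_that("prediction decomposes, infers and reassembles at source shape", {
  ph <- smallPhantom(seed = 6)
  # constant-output stub: all-zero weights, fg bias log(9) -> p = 0.9
  stub2d <- zeroedPredictor(unetSpec("2d", depth = 2, firstFeatures = 4,
                                     inputShape = c(32, 32)))
  prob <- predictVolume(stub2d, ph$volume)
  expect_identical(dim(prob), dim(ph$volume))
  expect_equal(range(voxels(prob)), c(0.9, 0.9), tolerance = 1e-12)
  stub25 <- zeroedPredictor(unetSpec("2.5d", depth = 2, firstFeatures = 4,
                                     inputShape = c(32, 32)))
  expect_equal(range(voxels(predictVolume(stub25, ph$volume))), c(0.9, 0.9),
               tolerance = 1e-12)
  # 3d mode crops its padding back to the source shape
  v <- randVolume(c(20, 18, 10), seed = 61, mean = 500, sd = 300)
  stub3d <- zeroedPredictor(unetSpec("3d", depth = 2, firstFeatures = 2,
                                     patchShape = c(8, 8, 8)))
  p3 <- predictVolume(stub3d, v)
  expect_identical(dim(p3), c(20L, 18L, 10L))
  # binarisation: >= tau with foreground ties
  exact <- ScanVolume(array(0.5, c(3, 3, 3)))
  expect_true(all(voxels(binarize(exact, 0.5))))
  expect_false(any(voxels(binarize(ScanVolume(array(0.49, c(3, 3, 3)))))))
  pr <- withr::with_seed(8, ScanVolume(array(runif(4^3), c(4, 4, 4))))
  expect_identical(voxels(binarize(pr, 0.3)), voxels(pr) >= 0.3)
  expect_error(binarize(pr, 1.2), "tau")
  expect_error(binarize(ScanVolume(array(2, c(2, 2, 2)))), "outside")
})

test_that("2d axial inference is slice-local", {
  spec <- unetSpec("2d", depth = 2, firstFeatures = 4, inputShape = c(16, 16))
  pred <- buildPredictor(spec, seed = 12)
  v1 <- randVolume(c(16, 16, 5), seed = 13, mean = 800, sd = 400)
  v2 <- v1
  v2@data[, , 3] <- v2@data[, , 3] + 500
  p1 <- voxels(predictVolume(pred, v1))
  p2 <- voxels(predictVolume(pred, v2))
  expect_false(isTRUE(all.equal(p1[, , 3], p2[, , 3])))
  for (k in c(1, 2, 4, 5)) expect_identical(p1[, , k], p2[, , k])
})

test_that("a reduced U-Net learns the phantom segmentation within 30 epochs", {
  ph <- smallPhantom(seed = 2)
  spec <- unetSpec("2d", depth = 2, firstFeatures = 8, inputShape = c(32, 32),
                   lr0 = 3e-3, batch = 4, epochs = 30)
  pairs <- makeTrainingPairs(ph$volume, ph$mask, spec)
  tr <- pairs[vapply(pairs, function(p) sum(p$y) > 0, logical(1))]
  pred <- buildPredictor(spec, seed = 3)
  res <- trainPredictor(pred, tr, tr, seed = 4)
  dscs <- vapply(tr, function(p) {
    pm <- asNamespace("VoteSeg")$.unetForward(res$predictor, p$x)$p >= 0.5
    2 * sum(pm & p$y) / (sum(pm) + sum(p$y))
  }, numeric(1))
  expect_gt(mean(dscs), 0.8)
})
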