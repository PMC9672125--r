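test_that("phantoms are reproducible, intensity-faithful and geometry-checked", {
  cfg <- phantomConfig(seed = 21)
  p1 <- makePhantom(cfg)
  p2 <- makePhantom(cfg)
  expect_identical(voxels(p1$volume), voxels(p2$volume))
  expect_identical(voxels(p1$mask), voxels(p2$mask))
  expect_equal(voxelSpacing(p1$volume), rep(0.19, 3))

  clean <- makePhantom(phantomConfig(noiseSd = 0))
  hu <- voxels(clean$volume)
  mk <- voxels(clean$mask)
  expect_gt(sum(mk), 0)
  expect_true(all(hu[mk] %in% c(2000, 2800)))
  expect_lte(max(hu[!mk]), 1200)

  none <- makePhantom(phantomConfig(nTeeth = 0, noiseSd = 0))
  expect_equal(sum(voxels(none$mask)), 0)

  expect_error(makePhantom(phantomConfig(shape = c(64, 64, 16),
                                         rootLength = 30)), "overflow")
  expect_error(phantomConfig(noiseSd = -1), "noiseSd")
})

test_that("metal insertion enables exact MDB count arithmetic", {
  # constructed enamel block: exactly 100 voxels above TH2, none above TH1
  a <- array(0, c(20, 20, 20))
  a[6:10, 6:10, 6:9] <- 2800
  v <- ScanVolume(a)
  expect_identical(voxels(addMetal(v, 0)), voxels(v))

  v50 <- addMetal(v, 50, seed = 31)
  r50 <- computeMDBR(v50)
  expect_equal(r50@countAboveTh1, 50)
  expect_equal(r50@countAboveTh2, 150)
  expect_equal(r50@mdbr, 1 / 3)
  expect_false(r50@heavy)

  v80 <- addMetal(v, 80, seed = 32)
  r80 <- computeMDBR(v80)
  expect_equal(r80@mdbr, 80 / 180)
  expect_true(r80@heavy)
  # metal lands next to enamel, not on it
  expect_equal(sum(voxels(v80) == 2800), 100)
  expect_error(addMetal(v, 1e6), "insufficient|available")
})

test_that("degradation is the identity at zero rates and only adds outside the truth", {
  ph <- smallPhantom(seed = 41)
  idcfg <- degradationConfig(fpSpeckleRate = 0, fnDropRate = 0,
                             boundaryJitter = 0)
  expect_identical(voxels(degradePrediction(ph$mask, idcfg)),
                   voxels(ph$mask))
  fpcfg <- degradationConfig(fpSpeckleRate = 3, fnDropRate = 0,
                             boundaryJitter = 0, seed = 42)
  out <- degradePrediction(ph$mask, fpcfg)
  expect_true(all(voxels(out)[voxels(ph$mask)]))    # superset of the truth
  extra <- voxels(out) & !voxels(ph$mask)
  expect_gt(sum(extra), 0)
  # speckles keep clear of the truth by construction
  near <- voxels(dilateMask(ph$mask, structuringBall(1)))
  expect_equal(sum(extra & near), 0)
})

test_that("speckle planting follows the configured Poisson rate", {
  gt <- BinaryMask(array(FALSE, c(24, 24, 200)))
  lambda <- 0.5
  cfg <- degradationConfig(fpSpeckleRate = lambda, fnDropRate = 0,
                           boundaryJitter = 0, seed = 43)
  log <- degradePrediction(gt, cfg, withLog = TRUE)
  expected <- lambda * 200
  expect_lt(abs(log$nSpeckles - expected), 3 * sqrt(expected))
  expect_gt(sum(voxels(log$mask)), 0)
})

test_that("voter correlation spans identical (rho = 1) to independent (rho = 0)", {
  ph <- smallPhantom(seed = 51)
  cfg <- speckleCfg(rate = 2, fn = 0.2, jitter = 1)
  same <- simulatePredictionSet(ph$mask, cfg, nVoters = 4, rho = 1,
                                masterSeed = 5)
  for (m in same@masks[-1])
    expect_identical(voxels(m), voxels(same@masks[[1]]))

  # rho = 0: pairwise background FP overlap is near the independence product
  gt <- BinaryMask(array(FALSE, c(40, 40, 60)))
  fpcfg <- degradationConfig(fpSpeckleRate = 6, fnDropRate = 0,
                             boundaryJitter = 0)
  indep <- simulatePredictionSet(gt, fpcfg, nVoters = 5, rho = 0,
                                 masterSeed = 6)
  rates <- vapply(indep@masks, function(m) mean(voxels(m)), numeric(1))
  pairRates <- utils::combn(5, 2, function(ij)
    mean(voxels(indep@masks[[ij[1]]]) & voxels(indep@masks[[ij[2]]])))
  prods <- utils::combn(5, 2, function(ij) rates[ij[1]] * rates[ij[2]])
  expect_lt(mean(pairRates) / mean(prods), 3)
  # one voter degenerates to a single degradation draw
  solo <- simulatePredictionSet(ph$mask, cfg, nVoters = 1, rho = 0,
                                masterSeed = 7)
  expect_length(solo@masks, 1)
  expect_error(simulatePredictionSet(ph$mask, cfg, nVoters = 2, rho = 2),
               "rho")
})
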