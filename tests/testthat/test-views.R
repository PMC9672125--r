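test_that("slice extraction does the shape bookkeeping per view", {
  v <- randVolume(c(4, 5, 6), seed = 1)
  ax <- extractSlices(v, "axial")
  expect_length(ax@frames, 6)
  expect_identical(dim(ax@frames[[1]]), c(4L, 5L))
  co <- extractSlices(v, "coronal")
  expect_length(co@frames, 5)
  expect_identical(dim(co@frames[[1]]), c(4L, 6L))
  sa <- extractSlices(v, "sagittal")
  expect_length(sa@frames, 4)
  expect_identical(dim(sa@frames[[1]]), c(5L, 6L))
  # frame k equals the plane z = k element-wise
  for (k in c(1, 4, 6)) expect_equal(ax@frames[[k]], voxels(v)[, , k])
  expect_error(extractSlices(v, "oblique"), "view")
})

test_that("stack reassembly inverts extraction for every view and kind", {
  shapes <- list(c(7, 8, 9), c(1, 5, 3), c(6, 1, 2), c(4, 4, 1), c(2, 3, 40))
  for (s in seq_along(shapes)) {
    d <- shapes[[s]]
    v <- randVolume(d, seed = 100 + s)
    m <- randMask(d, 0.4, seed = 200 + s)
    for (w in c("axial", "coronal", "sagittal")) {
      expect_identical(voxels(stackToVolume(extractSlices(v, w))), voxels(v))
      expect_identical(voxels(stackToVolume(extractSlices(m, w))), voxels(m))
    }
  }
})

test_that("frames are placed by index map, not list order", {
  m <- randMask(c(5, 6, 7), 0.5, seed = 9)
  st <- extractSlices(m, "axial")
  perm <- c(3L, 1L, 7L, 2L, 6L, 4L, 5L)
  shuffled <- new("ViewStack", view = "axial", frames = st@frames[perm],
                  indexMap = st@indexMap[perm], sourceDim = st@sourceDim,
                  kind = "mask", spacing = st@spacing)
  expect_identical(voxels(stackToVolume(shuffled)), voxels(m))
  zero <- new("ViewStack", view = "axial",
              frames = rep(list(matrix(0, 5, 6)), 7),
              indexMap = 1:7, sourceDim = c(5L, 6L, 7L), kind = "volume",
              spacing = rep(1, 3))
  expect_true(all(voxels(stackToVolume(zero)) == 0))
})

test_that("2.5D slabs stack neighbouring axial slices with edge replication", {
  v <- randVolume(c(6, 7, 5), seed = 3)
  sl <- makeSlabs(v)
  expect_length(sl@frames, 5)
  for (i in 2:4) {
    expect_equal(sl@frames[[i]][, , 1], voxels(v)[, , i - 1])
    expect_equal(sl@frames[[i]][, , 2], voxels(v)[, , i])
    expect_equal(sl@frames[[i]][, , 3], voxels(v)[, , i + 1])
  }
  expect_equal(sl@frames[[1]][, , 1], sl@frames[[1]][, , 2])
  expect_equal(sl@frames[[5]][, , 3], sl@frames[[5]][, , 2])
  one <- makeSlabs(randVolume(c(4, 4, 1), seed = 5))
  expect_length(one@frames, 1)
  expect_equal(one@frames[[1]][, , 1], one@frames[[1]][, , 3])
  # centre channels reassemble to the axial stack
  ctr <- lapply(sl@frames, function(f) f[, , 2])
  expect_equal(ctr, extractSlices(v, "axial")@frames)
})

test_that("patch tiling pads, counts and reassembles exactly", {
  v1 <- randVolume(c(64, 64, 128), seed = 6)
  g1 <- tilePatches(v1)
  expect_length(g1@patches, 1)
  expect_identical(g1@pad, c(0L, 0L, 0L))

  v2 <- randVolume(c(65, 64, 128), seed = 7)
  g2 <- tilePatches(v2)
  expect_length(g2@patches, 2)
  expect_identical(g2@pad, c(63L, 0L, 0L))
  expect_identical(voxels(assemblePatches(g2)), voxels(v2))

  g3 <- tilePatches(randVolume(c(10, 10, 10), seed = 8), c(4, 4, 4))
  expect_length(g3@patches, 27)

  m <- randMask(c(70, 70, 130), 0.3, seed = 9)
  gm <- tilePatches(m)
  expect_identical(voxels(assemblePatches(gm)), voxels(m))
  # every padded voxel in exactly one patch: constant patches -> all ones
  ones <- gm
  ones@patches <- lapply(gm@patches, function(p) array(TRUE, dim(p)))
  expect_true(all(voxels(assemblePatches(ones))))
})

test_that("inconsistent patch grids are rejected", {
  g <- tilePatches(randMask(c(8, 8, 8), 0.5, seed = 10), c(4, 4, 4))
  broken <- g
  broken@patches <- g@patches[-1]
  broken@offsets <- g@offsets[-1, , drop = FALSE]
  expect_error(assemblePatches(broken), "consistency")
  overlap <- g
  overlap@offsets[2, ] <- overlap@offsets[1, ]
  expect_error(assemblePatches(overlap), "consistency")
})

test_that("patch decomposition round-trips random small shapes", {
  for (s in 1:5) {
    d <- withr::with_seed(300 + s, sample(1:40, 3, replace = TRUE))
    m <- randMask(d, 0.5, seed = 400 + s)
    g <- tilePatches(m, c(8, 8, 16))
    expect_identical(voxels(assemblePatches(g)), voxels(m))
  }
})
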