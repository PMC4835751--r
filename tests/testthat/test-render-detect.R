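test_that("a rendered soma peaks at its own voxel and empty input is empty", {
  cellTab <- makeCellTable(c(25, 25, 15), "iba1")
  st <- renderStack(cellTab, fieldUm = c(50, 50, 30),
                    voxelSizeUm = c(1, 1, 1))
  v <- st@data[1, , , ]
  peak <- arrayInd(which.max(v), dim(v))  # (z, y, x)
  expect_equal(as.integer(peak), c(15L, 25L, 25L), tolerance = 0)
  # gfap channel untouched
  expect_equal(max(st@data[2, , , ]), 0)

  empty <- renderStack(makeCellTable(matrix(0, 0, 3), character(0)),
                       fieldUm = c(20, 20, 10), voxelSizeUm = c(1, 1, 1))
  expect_equal(max(empty@data), 0)
})

test_that("a rendered dense-core sphere occupies the analytic voxel count", {
  pre <- makePreset("human-dense-core")
  pl <- samplePlaque(pre, 4188.790205, 1, fieldUm = c(40, 40, 40))  # R = 10
  st <- renderStack(makeCellTable(matrix(0, 0, 3), character(0)),
                    plaque = pl, fieldUm = c(40, 40, 40),
                    voxelSizeUm = c(1, 1, 1))
  n <- sum(st@data[3, , , ] > 0.5)
  expect_lt(abs(n - 4189) / 4189, 0.10)
})

test_that("Otsu lands between the modes of a bimodal histogram", {
  set.seed(5)
  v <- array(c(rnorm(4000, 10, 3), rnorm(1000, 200, 10)), c(10, 25, 20))
  th <- rgnet:::otsuThreshold(v)
  expect_gt(th, 10 + 3 * 3)   # above the low mode
  expect_lt(th, 200 - 3 * 10) # below the high mode
  # exhaustive-search oracle over the same 256-bin histogram
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), 256)
  best <- -Inf; bestK <- 1L
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mids <- (br[-1] + br[-257]) / 2
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):256] * mids[(k + 1):256]) / w1
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best) { best <- sb; bestK <- k }
  }
  expect_equal(th, br[bestK + 1], tolerance = 1e-9)
})

test_that("thresholding errors on constant channels, obeys fixed cutoffs", {
  st <- renderStack(makeCellTable(matrix(0, 0, 3), character(0)),
                    fieldUm = c(10, 10, 5), voxelSizeUm = c(1, 1, 1))
  expect_error(thresholdChannel(st, "iba1", method = "otsu"), "constant")
  expect_false(any(thresholdChannel(st, "iba1", method = "fixed",
                                    fixedValue = 1)))
  expect_error(thresholdChannel(st, "nope", method = "fixed",
                                fixedValue = 1), "channel")
})

test_that("labeling: 26-connectivity, size filter, descending renumber", {
  mask <- array(FALSE, c(6, 10, 10))
  mask[2:3, 2:3, 2:3] <- TRUE          # 8 voxels
  mask[2:5, 7:9, 7:9] <- TRUE          # 36 voxels
  lv <- labelComponents(mask, c(1, 1, 1), minVolumeUm3 = 0)
  expect_equal(lv@nComponents, 2L)
  # label 1 must be the larger component
  expect_equal(sum(lv@labels == 1L), 36L)

  # speck removal
  speck <- array(FALSE, c(4, 4, 4)); speck[1, 1, 1:2] <- TRUE
  expect_equal(labelComponents(speck, c(1, 1, 1),
                               minVolumeUm3 = 3)@nComponents, 0L)

  # corner-touching voxels are one component under 26-connectivity
  corner <- array(FALSE, c(3, 3, 3))
  corner[1, 1, 1] <- TRUE; corner[2, 2, 2] <- TRUE
  lvc <- labelComponents(corner, c(1, 1, 1), minVolumeUm3 = 0)
  expect_equal(lvc@nComponents, 1L)
})

test_that("labeling agrees with a brute-force flood fill on random masks", {
  set.seed(21)
  for (rep in 1:5) {
    mask <- array(runif(5 * 8 * 8) < 0.25, c(5, 8, 8))
    lv <- labelComponents(mask, c(1, 1, 1), minVolumeUm3 = 0)
    ref <- bruteFloodLabels(mask)
    expect_equal(lv@nComponents, max(ref))
    # same partition: labels must be a relabeling of the oracle's
    if (max(ref) > 0) {
      pairs <- unique(cbind(ref[mask], lv@labels[mask]))
      expect_equal(nrow(pairs), max(ref))
    }
  }
})

test_that("centroids use voxel centers and respect anisotropy", {
  # single voxel at 0-based (z,y,x) = (5,10,20), voxel 0.5/0.5/1.0
  m <- array(FALSE, c(10, 20, 30)); m[6, 11, 21] <- TRUE
  lv <- labelComponents(m, c(0.5, 0.5, 1.0), minVolumeUm3 = 0)
  ce <- extractCentroids(lv, "iba1")
  expect_equal(c(ce$x_um, ce$y_um, ce$z_um), c(10.25, 5.25, 5.5))

  # L-shaped 3-voxel component: centroid = mean of the voxel centers
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[1, 1, 2] <- TRUE; m2[1, 2, 1] <- TRUE
  lv2 <- labelComponents(m2, c(1, 1, 1), minVolumeUm3 = 0)
  ce2 <- extractCentroids(lv2, "gfap")
  expect_equal(c(ce2$x_um, ce2$y_um, ce2$z_um),
               c(mean(c(0.5, 1.5, 0.5)), mean(c(0.5, 0.5, 1.5)), 0.5))

  # symmetric sphere: centroid at the center
  pre <- makePreset("human-dense-core")
  pl <- samplePlaque(pre, 4188.79, 1, fieldUm = c(40, 40, 40))
  st <- renderStack(makeCellTable(matrix(0, 0, 3), character(0)),
                    plaque = pl, fieldUm = c(40, 40, 40),
                    voxelSizeUm = c(1, 1, 1))
  det <- detectStack(st)
  expect_equal(c(det$plaque$cx_um, det$plaque$cy_um, det$plaque$cz_um),
               c(20, 20, 20), tolerance = 0.2)
})

test_that("measurePlaque: volume arithmetic, largest-wins, empty errors", {
  m <- array(FALSE, c(14, 14, 14)); m[2:11, 2:11, 2:11] <- TRUE
  lv <- labelComponents(m, c(0.5, 0.5, 1.0), minVolumeUm3 = 0)
  expect_equal(measurePlaque(lv)$volume_um3, 1000 * 0.25)

  m[14, 14, 14] <- TRUE  # stray second component, separated by a gap
  lv2 <- labelComponents(m, c(0.5, 0.5, 1.0), minVolumeUm3 = 0)
  expect_warning(pm <- measurePlaque(lv2), "largest")
  expect_equal(pm$volume_um3, 1000 * 0.25)

  empty <- labelComponents(array(FALSE, c(2, 2, 2)), c(1, 1, 1))
  expect_error(measurePlaque(empty), "no plaque")
})

test_that("maximum projection is the per-pixel max over z", {
  cellTab <- makeCellTable(rbind(c(10, 10, 5), c(30, 30, 25)), "iba1")
  st <- renderStack(cellTab, fieldUm = c(40, 40, 30),
                    voxelSizeUm = c(1, 1, 1))
  proj <- maxProjection(st, "iba1")
  v <- st@data[1, , , ]
  expect_equal(proj, apply(v, c(2, 3), max))
  # single-slice stack: projection equals the slice
  st1 <- renderStack(makeCellTable(c(5, 5, 0.5), "iba1"),
                     fieldUm = c(10, 10, 1), voxelSizeUm = c(1, 1, 1))
  expect_equal(maxProjection(st1, "iba1"),
               matrix(st1@data[1, 1, , ], 10, 10))
  # coordinate mapping just drops z
  expect_equal(projectCentroids(cellTab),
               cbind(x_um = cellTab$x_um, y_um = cellTab$y_um))
})
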