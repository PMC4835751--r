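test_that("equivalent radius follows the sphere formula", {
  pre <- makePreset("human-dense-core")
  expect_equal(samplePlaque(pre, 4188.790205, 1)$equivalent_radius_um, 10,
               tolerance = 1e-6)
  expect_equal(samplePlaque(pre, 33510.32164, 1)$equivalent_radius_um, 20,
               tolerance = 1e-6)
  expect_error(samplePlaque(pre, -1, 1), "positive")
  expect_identical(samplePlaque(pre, 5e3, 7), samplePlaque(pre, 5e3, 7))
})

test_that("deterministic counts are exact when noise is switched off", {
  pre <- makePreset("human-dense-core",
                    microgliaBaseCount = 10, gfapBaseCount = 8,
                    microgliaSlopePerUm3 = 0, gfapSlopePerUm3 = 0,
                    backgroundDensityPerMm3 = 0)
  pl <- samplePlaque(pre, 5000, 1)
  cl <- sampleGlia(pl, pre, seed = 3, noiseSd = c(iba1 = 0, gfap = 0))
  expect_identical(sum(cl$marker == "iba1"), 10L)
  expect_identical(sum(cl$marker == "gfap"), 8L)
  expect_true(all(cl$origin == "shell"))
})

test_that("shell radial law matches its truncated normal (pooled draws)", {
  pre <- makePreset("human-dense-core", microgliaBaseCount = 10000,
                    microgliaSlopePerUm3 = 0, gfapBaseCount = 5000,
                    gfapSlopePerUm3 = 0, backgroundDensityPerMm3 = 0)
  pl <- samplePlaque(pre, 500, 1)  # small core: truncation negligible
  cl <- sampleGlia(pl, pre, seed = 11, noiseSd = c(iba1 = 0, gfap = 0))
  cen <- fieldCenter()
  d <- sqrt((cl$x_um - cen[1])^2 + (cl$y_um - cen[2])^2 +
            (cl$z_um - cen[3])^2)
  expect_lt(abs(mean(d[cl$marker == "iba1"]) - 25), 0.5)
  expect_lt(abs(mean(d[cl$marker == "gfap"]) - 40), 0.5)
  # truncation bounds: below at core radius, above at astroMax
  expect_true(all(d >= max(5, pl$equivalent_radius_um) - 1e-9))
  expect_true(all(d[cl$marker == "gfap"] <= 80 + 1e-9))
})

test_that("shell ordering holds over cohorts: astrocytes outside microglia", {
  for (nm in c("human-dense-core", "human-fibrillar", "mouse-mid",
               "mouse-late")) {
    co <- suppressWarnings(generateCohort(makePreset(nm), 30, seed = 4))
    cl <- cells(co)
    sh <- cl[cl$origin == "shell", ]
    cen <- fieldCenter(co@fieldUm)
    d <- sqrt((sh$x_um - cen[1])^2 + (sh$y_um - cen[2])^2 +
              (sh$z_um - cen[3])^2)
    expect_gt(mean(d[sh$marker == "gfap"]), mean(d[sh$marker == "iba1"]))
  }
})

test_that("cohorts are reproducible and validated", {
  pre <- makePreset("mouse-mid")
  a <- suppressWarnings(generateCohort(pre, 5, seed = 123))
  b <- suppressWarnings(generateCohort(pre, 5, seed = 123))
  expect_identical(plaques(a), plaques(b))
  expect_identical(cells(a), cells(b))
  expect_equal(nrow(plaques(suppressWarnings(
    generateCohort(pre, 39, seed = 1)))), 39)
  one <- suppressWarnings(generateCohort(pre, 1, seed = 1))
  expect_s4_class(one, "GliaCohort")
  expect_error(generateCohort(pre, 0, seed = 1), "nPlaques")
  expect_error(generateCohort(pre, 5, volumeRangeUm3 = c(10, 10), seed = 1),
               "interval")
})

test_that("count-volume correlation calibration hits its target", {
  # fibrillar preset is calibrated to r = 0.561; a zero-slope marker has ~0
  co <- suppressWarnings(
    generateCohort(makePreset("human-fibrillar"), 2000, seed = 31))
  cl <- cells(co)
  sh <- cl[cl$origin == "shell" & cl$marker == "iba1", ]
  counts <- table(factor(sh$plaque_id, levels = plaques(co)$plaque_id))
  r <- cor(as.numeric(counts), plaques(co)$volume_um3)
  expect_lt(abs(r - 0.561), 0.05)

  cop <- suppressWarnings(
    generateCohort(makePreset("human-phf-nft"), 2000, seed = 32))
  clp <- cells(cop)
  shp <- clp[clp$origin == "shell" & clp$marker == "iba1", ]
  cp <- table(factor(shp$plaque_id, levels = plaques(cop)$plaque_id))
  expect_lt(abs(cor(as.numeric(cp), plaques(cop)$volume_um3)), 0.05)
})

test_that("landscapes: containment, null perturbation, density contrast", {
  spec <- landscapeSpec(nMicroglia = 100)
  pts <- generateLandscape(spec, seed = 9)
  expect_equal(nrow(pts), 100)
  expect_true(all(pts[, 1] >= 0 & pts[, 1] <= 1000 &
                  pts[, 2] >= 0 & pts[, 2] <= 1000))

  centers <- rbind(c(300, 300), c(700, 700))
  null <- landscapeSpec(mode = "plaque_perturbed", nMicroglia = 100,
                        plaqueCenters = centers, aggregationFraction = 0)
  expect_identical(generateLandscape(null, seed = 9), pts)

  pert <- landscapeSpec(mode = "plaque_perturbed", nMicroglia = 2000,
                        plaqueCenters = centers, aggregationRadiusUm = 60,
                        depletionOuterUm = 180, aggregationFraction = 0.7)
  pp <- generateLandscape(pert, seed = 10)
  dmin <- pmin(sqrt((pp[, 1] - 300)^2 + (pp[, 2] - 300)^2),
               sqrt((pp[, 1] - 700)^2 + (pp[, 2] - 700)^2))
  discArea <- 2 * pi * 60^2
  annArea <- 2 * pi * (180^2 - 60^2)
  densDisc <- sum(dmin <= 60) / discArea
  densAnn <- sum(dmin > 60 & dmin <= 180) / annArea
  expect_gt(densDisc, densAnn)

  expect_error(landscapeSpec(nMicroglia = 2), "nMicroglia")
  expect_error(landscapeSpec(mode = "plaque_perturbed", nMicroglia = 10,
                             plaqueCenters = rbind(c(1, 1)),
                             aggregationRadiusUm = 100,
                             depletionOuterUm = 50),
               "depletionOuterUm")
})

test_that("negative computed counts clamp to zero with a warning", {
  pre <- makePreset("human-phf-nft", microgliaBaseCount = 0,
                    backgroundDensityPerMm3 = 0)
  pl <- samplePlaque(pre, 1000, 1)
  # huge noise forces negative draws for some seeds
  expect_warning(
    cl <- sampleGlia(pl, pre, seed = 2, noiseSd = c(iba1 = 50, gfap = 0)),
    "clamped")
})
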