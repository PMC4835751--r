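test_that("radial distances: exact cases and sorted output", {
  ct <- makeCellTable(rbind(c(0, 0, 0), c(3, 4, 0), c(90, 0, 0)), "iba1")
  d <- radialDistances(ct, c(0, 0, 0), "iba1", maxRadiusUm = 100)
  expect_equal(d, c(0, 5, 90))
  expect_equal(radialDistances(ct, c(0, 0, 0), "iba1", maxRadiusUm = 10),
               c(0, 5))
  expect_equal(radialDistances(ct, c(0, 0, 0), "gfap", 100), numeric(0))
  expect_error(radialDistances(ct, c(0, 0, 0), "iba1", maxRadiusUm = 0),
               "maxRadiusUm")
})

test_that("histogram follows the half-open convention and conserves counts", {
  h <- radialHistogram(list(iba1 = c(5, 15, 15), gfap = numeric(0)),
                       binWidthUm = 10, maxRadiusUm = 20)
  expect_equal(unname(h@counts[, "iba1"]), c(1L, 2L))
  # boundary value 10 falls in [10, 20)
  h2 <- radialHistogram(list(iba1 = 10, gfap = numeric(0)), 10, 20)
  expect_equal(unname(h2@counts[, "iba1"]), c(0L, 1L))
  # conservation incl. a distance equal to the maximum radius
  h3 <- radialHistogram(list(iba1 = c(0, 9.99, 10, 20), gfap = 1), 10, 20)
  expect_equal(sum(h3@counts[, "iba1"]), 4L)
  expect_error(radialHistogram(list(iba1 = 1, gfap = 1), binWidthUm = 0),
               "binWidthUm")
  expect_warning(radialHistogram(list(iba1 = 1, gfap = 1), 7, 20),
                 "truncated")
})

test_that("interval max GFAP: argmax bin, innermost tie-break, error on none", {
  h <- radialHistogram(list(iba1 = numeric(0),
                            gfap = c(rep(15, 3), rep(25, 7), rep(35, 2))),
                       10, 40)
  expect_equal(unname(intervalMaxGfap(h)), c(20, 30))
  # tie: bins (30,40) and (50,60) both hold 5 -> innermost wins
  ht <- radialHistogram(list(iba1 = numeric(0),
                             gfap = c(rep(35, 5), rep(55, 5))), 10, 60)
  expect_equal(unname(intervalMaxGfap(ht)), c(30, 40))
  h0 <- radialHistogram(list(iba1 = c(5, 10), gfap = numeric(0)), 10, 20)
  expect_error(intervalMaxGfap(h0), "RGN undefined")
})

test_that("intra-net counting is a direct threshold count and monotone", {
  d <- c(10, 25, 45, 90)
  expect_equal(countIntraRgn(d, 50), 3)
  expect_equal(countIntraRgn(d, 5), 0)
  expect_equal(countIntraRgn(d, 45), 3)  # boundary inclusive
  bs <- seq(5, 100, by = 5)
  cnts <- vapply(bs, function(b) countIntraRgn(d, b), 1)
  expect_true(all(diff(cnts) >= 0))
  expect_true(all(cnts <= length(d)))
})

test_that("profilePlaque composes the parts and propagates undefined nets", {
  pre <- makePreset("human-dense-core")
  pl <- samplePlaque(pre, 1000, 1, fieldUm = c(200, 200, 200))
  cen <- c(100, 100, 100)
  ct <- rbind(
    makeCellTable(cbind(cen[1] + c(10, 20, 38), cen[2], cen[3]), "iba1"),
    makeCellTable(cbind(cen[1] + 35, cen[2], cen[3]), "gfap"))
  pr <- profilePlaque(pl, ct)
  expect_equal(pr@intervalMaxGfapUm, c(30, 40))
  expect_equal(pr@rgnBoundaryUm, 40)
  expect_equal(pr@nIba1IntraRgn, 3L)  # all iba1 inside the limit
  expect_equal(pr@nGfap, 1L)

  noGfap <- profilePlaque(pl, ct[ct$marker == "iba1", ])
  expect_false(noGfap@gfapDefined)
  expect_true(is.na(noGfap@rgnBoundaryUm))
})

test_that("synthetic dense-core geometry keeps all microglia intra-net", {
  co <- suppressWarnings(
    generateCohort(makePreset("human-dense-core",
                              backgroundDensityPerMm3 = 0), 30, seed = 8))
  pr <- profileCohort(co)
  ok <- pr$gfap_defined
  # microglia at 20-30 um sit inside the astrocyte-defined limit (>= 30 um)
  expect_true(all(pr$n_iba1_intra_rgn[ok] == pr$n_iba1_total[ok]))
})

test_that("histogram/argmax/intra-net equal brute force on random inputs", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(3:200, 1)
    w <- sample(c(5, 10, 20), 1)
    maxR <- 100
    ct <- makeCellTable(matrix(runif(3 * n, 0, 150), n, 3),
                        sample(c("iba1", "gfap"), n, replace = TRUE))
    cen <- runif(3, 40, 110)
    di <- radialDistances(ct, cen, "iba1", maxR)
    dg <- radialDistances(ct, cen, "gfap", maxR)
    expect_equal(di, bruteRadialDistances(ct, cen, "iba1", maxR))
    expect_equal(dg, bruteRadialDistances(ct, cen, "gfap", maxR))
    h <- radialHistogram(list(iba1 = di, gfap = dg), w, maxR)
    expect_identical(unname(h@counts[, "iba1"]), bruteHistogram(di, w, maxR))
    expect_identical(unname(h@counts[, "gfap"]), bruteHistogram(dg, w, maxR))
    if (length(dg)) {
      expect_equal(unname(intervalMaxGfap(h)),
                   bruteArgmaxBin(h@counts[, "gfap"], w))
      b <- unname(intervalMaxGfap(h))[2]
      expect_equal(countIntraRgn(di, b), sum(di <= b))
    }
  }
})

test_that("cohort-mean interval midpoint recovers the astrocyte shell mean", {
  for (cfg in list(list(name = "mouse-mid", mean = 40),
                   list(name = "mouse-late", mean = 60))) {
    co <- suppressWarnings(generateCohort(makePreset(cfg$name), 50,
                                          seed = 13))
    pr <- profileCohort(co, binWidthUm = 10)
    ok <- pr$gfap_defined
    mid <- (pr$interval_lo_um[ok] + pr$interval_hi_um[ok]) / 2
    expect_lt(abs(mean(mid) - cfg$mean), 10)  # within one bin width
  }
})

test_that("recruitment correlations: exact linear case and degenerate flags", {
  prof <- data.frame(
    plaque_id = paste0("p", 1:5), plaque_class = "dense_core",
    volume_um3 = c(1000, 2000, 3000, 4000, 5000),
    interval_lo_um = 30, interval_hi_um = 40, rgn_boundary_um = 40,
    n_iba1_total = c(10, 20, 30, 40, 50),
    n_iba1_intra_rgn = c(5, 10, 15, 20, 25),
    n_gfap = c(50, 40, 30, 20, 10),
    gfap_defined = TRUE)
  rc <- recruitmentCorrelations(prof)
  expect_equal(rc$r_iba1_total, 1)
  expect_equal(rc$r_iba1_intra_rgn, 1)
  expect_equal(rc$r_gfap, -1)

  prof$n_gfap <- 7  # constant counts: undefined, not zero
  rc2 <- recruitmentCorrelations(prof)
  expect_true(is.na(rc2$r_gfap))
  expect_true("r_gfap" %in% rc2$undefined)

  expect_error(recruitmentCorrelations(prof[1:2, ]), "at least 3")
})
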