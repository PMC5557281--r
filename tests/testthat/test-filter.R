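mkDet <- function(area = 200, maxI = 40000, meanI = 30000) {
  d <- fakeDetection(c(50, 50), area = area, meanIntensity = meanI)
  d@features$area <- area
  d@features$maxIntensity <- maxI
  d
}

test_that("vacuous criteria keep everything; intervals are closed", {
  dets <- list(mkDet(50), mkDet(200), mkDet(800))
  out <- applyFilter(dets, filterCriteria())
  expect_length(out$kept, 3)
  expect_length(out$discarded, 0)

  out2 <- applyFilter(dets, filterCriteria(area = c(75, 450)))
  expect_length(out2$kept, 1)
  expect_equal(features(out2$kept[[1]])$area, 200)
  expect_length(out2$discarded, 2)

  # activation floor: closed at the boundary
  floorV <- 35000
  dets3 <- list(mkDet(maxI = floorV), mkDet(maxI = floorV - 1))
  out3 <- applyFilter(dets3, filterCriteria(requireActivity = TRUE,
                                            activationFloor = floorV))
  expect_length(out3$kept, 1)
  expect_equal(features(out3$kept[[1]])$maxIntensity, floorV)
})

test_that("filtering conserves records and tightening never grows the kept set", {
  set.seed(41)
  for (rep in 1:30) {
    dets <- lapply(1:12, function(i)
      mkDet(area = sample(10:900, 1), maxI = runif(1, 1000, 65000),
            meanI = runif(1, 500, 60000)))
    lo <- sample(10:300, 1); hi <- lo + sample(50:600, 1)
    crit <- filterCriteria(area = c(lo, hi))
    out <- applyFilter(dets, crit)
    expect_equal(length(out$kept) + length(out$discarded), length(dets))
    # order preserved within each part
    ids <- sapply(dets, function(d) features(d)$area)
    expect_equal(as.numeric(unlist(lapply(out$kept,
                                          function(d) features(d)$area))),
                 as.numeric(ids[ids >= lo & ids <= hi]))
    tight <- filterCriteria(area = c(lo + 20, hi - 20))
    expect_lte(length(applyFilter(dets, tight)$kept), length(out$kept))
  }
})

test_that("malformed criteria are rejected", {
  expect_error(filterCriteria(area = c(100, 10)), "lower <= upper")
  expect_error(filterCriteria(extent = c(0.5, NA)), "finite")
})

test_that("erasing cells resets exactly their pixels on a copy", {
  set.seed(42)
  m <- matrix(as.integer(sample(900:1100, 64 * 64, replace = TRUE)), 64, 64)
  f <- Frame(m)
  det <- fakeDetection(c(20, 20), area = 64)
  out <- eraseCells(f, list(det), backgroundValue = 1000L)
  expect_identical(pixels(f), m)  # input untouched
  px <- pixelSet(det)
  expect_true(all(pixels(out)[cbind(px[, 1] + 1, px[, 2] + 1)] == 1000L))
  untouched <- pixels(out)
  untouched[cbind(px[, 1] + 1, px[, 2] + 1)] <- m[cbind(px[, 1] + 1, px[, 2] + 1)]
  expect_identical(untouched, m)

  # no-op copy and idempotence
  same <- eraseCells(f, list())
  expect_identical(pixels(same), m)
  twice <- eraseCells(out, list(det), backgroundValue = 1000L)
  expect_identical(pixels(twice), pixels(out))

  bad <- fakeDetection(c(63, 63), area = 64)
  expect_error(eraseCells(f, list(bad)), "out-of-bounds")
})

test_that("erased cells are not re-detected", {
  f <- renderDiskFrame(c(96, 96), rbind(c(30, 30), c(70, 70)), c(7, 7),
                       1000, 30000)
  cfg <- segmentationConfig(minComponentArea = 50, maxComponentArea = 450,
                            autoThresholdBounds = FALSE,
                            thresholdBounds = c(0, 1))
  dets <- segmentFrame(f, cfg)
  expect_length(dets, 2)
  drop1 <- dets[1]
  cleaned <- eraseCells(f, drop1)  # background = modal value (1000)
  dets2 <- segmentFrame(cleaned, cfg)
  expect_length(dets2, 1)
  expect_equal(features(dets2[[1]])$centroid,
               features(dets[[2]])$centroid, tolerance = 1e-6)
})
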