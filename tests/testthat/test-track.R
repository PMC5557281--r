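test_that("the assignment solver matches brute-force enumeration", {
  set.seed(51)
  for (rep in 1:60) {
    n <- sample(1:5, 1); m <- sample(n:6, 1)
    cost <- matrix(runif(n * m, 0, 100), n, m)
    assign <- phasetrack:::.solveAssignment(cost)
    got <- sum(cost[cbind(seq_len(n), assign)])
    exp <- bruteAssignment(cost)$matchedCost
    expect_equal(got, exp, tolerance = 1e-9)
  }
})

test_that("linkFrames solves the gated assignment optimally", {
  cfg <- trackingConfig(gateRadius = 20, featureWeights = c(0, 0, 0))
  # identity matching at zero movement
  dets <- lapply(list(c(10, 10), c(40, 40), c(70, 20)), fakeDetection)
  res <- linkFrames(dets, dets, cfg)
  expect_equal(res$pairs[, 1], res$pairs[, 2])
  expect_equal(res$totalCost, 0)

  # uncrossed pairing beats the crossed one (4 vs 14)
  a <- list(fakeDetection(c(50, 0)), fakeDetection(c(50, 10)))
  b <- list(fakeDetection(c(50, 2)), fakeDetection(c(50, 8)))
  res2 <- linkFrames(a, b, cfg)
  expect_equal(res2$pairs, cbind(from = 1:2, to = 1:2), ignore_attr = TRUE)
  expect_equal(res2$totalCost, 4)

  # beyond the gate: both sides unmatched
  far <- linkFrames(list(fakeDetection(c(50, 10))),
                    list(fakeDetection(c(50, 31))), cfg)
  expect_equal(nrow(far$pairs), 0)
  expect_equal(far$unmatchedFrom, 1L)
  expect_equal(far$unmatchedTo, 1L)

  # empty inputs allowed
  none <- linkFrames(list(), list(fakeDetection(c(1, 1))), cfg)
  expect_equal(nrow(none$pairs), 0)
})

test_that("link totals equal brute force on random gated problems", {
  set.seed(52)
  cfg <- trackingConfig(gateRadius = 15, featureWeights = c(1, 1, 0.5))
  for (rep in 1:40) {
    nA <- sample(0:6, 1); nB <- sample(0:6, 1)
    a <- lapply(seq_len(nA), function(i)
      fakeDetection(runif(2, 0, 60), area = sample(60:300, 1),
                    meanIntensity = runif(1, 1e4, 5e4)))
    b <- lapply(seq_len(nB), function(i)
      fakeDetection(runif(2, 0, 60), area = sample(60:300, 1),
                    meanIntensity = runif(1, 1e4, 5e4)))
    res <- linkFrames(a, b, cfg)
    if (nA && nB) {
      cost <- phasetrack:::.linkCostMatrix(a, b, cfg, rep(15, nA))
      exp <- bruteAssignment(cost)
      expect_equal(res$totalCost, exp$matchedCost, tolerance = 1e-9)
      expect_equal(nrow(res$pairs), exp$nMatched)
    } else {
      expect_equal(nrow(res$pairs), 0)
    }
  }
})

test_that("a stationary cell yields one full-length track with zero steps", {
  det <- function(t) fakeDetection(c(30, 30), timeIndex = t)
  tracks <- buildTracks(lapply(0:4, function(t) list(det(t))))
  expect_length(tracks, 1)
  expect_length(tracks[[1]], 5)
  expect_equal(stepDistances(tracks[[1]]), rep(0, 4))
  expect_true(validObject(tracks[[1]]))
})

test_that("births, deaths and gap bridging work as configured", {
  cfg <- trackingConfig(gateRadius = 10, maxMissedFrames = 1)
  moving <- function(t) fakeDetection(c(20 + 2 * t, 20), timeIndex = t)
  late <- function(t) fakeDetection(c(80, 80), timeIndex = t)
  # cell A all frames; cell B appears from frame 2; A missing at frame 3
  byTime <- list(
    list(moving(0)),
    list(moving(1)),
    list(moving(2), late(2)),
    list(late(3)),
    list(moving(4), late(4)))
  tracks <- buildTracks(byTime, cfg)
  expect_length(tracks, 2)
  tA <- tracks[[1]]; tB <- tracks[[2]]
  expect_equal(tA@timeIndices, c(0L, 1L, 2L, 4L))  # bridged one-frame gap
  expect_equal(tB@timeIndices, 2:4)
  # every detection in exactly one track
  expect_equal(sum(sapply(tracks, length)), sum(lengths(byTime)))

  # with maxMissedFrames = 0 the gap kills the track: a new one is born
  tracks0 <- buildTracks(byTime, trackingConfig(gateRadius = 10,
                                                maxMissedFrames = 0))
  expect_length(tracks0, 3)

  # mismatched time indices are rejected
  bad <- list(list(moving(0)), list(moving(2)))
  expect_error(buildTracks(bad), "consecutive")
})

test_that("feature weights disambiguate a crossing with distinct intensities", {
  cfg <- trackingConfig(gateRadius = 30, featureWeights = c(0, 50, 0))
  bright <- function(p, t) fakeDetection(p, timeIndex = t,
                                         meanIntensity = 60000)
  dim_ <- function(p, t) fakeDetection(p, timeIndex = t,
                                       meanIntensity = 10000)
  # cells swap positions between frames; distance alone is symmetric, the
  # intensity term must keep identities
  byTime <- list(
    list(bright(c(30, 20), 0), dim_(c(30, 40), 0)),
    list(bright(c(30, 31), 1), dim_(c(30, 29), 1)))
  tracks <- buildTracks(byTime, cfg)
  expect_length(tracks, 2)
  for (tk in tracks) {
    ints <- sapply(tk@detections, function(d) features(d)$meanIntensity)
    expect_equal(length(unique(ints)), 1)
  }
})

test_that("tracking is deterministic", {
  set.seed(53)
  byTime <- lapply(0:5, function(t)
    lapply(1:6, function(i)
      fakeDetection(c(10 * i + rnorm(1), 20 + rnorm(1)), timeIndex = t)))
  a <- buildTracks(byTime)
  b <- buildTracks(byTime)
  expect_identical(lapply(a, function(t) t@timeIndices),
                   lapply(b, function(t) t@timeIndices))
  expect_identical(lapply(a, stepDistances), lapply(b, stepDistances))
})
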