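test_that("scene generation is deterministic and honours frozen dynamics", {
  cfg <- sceneConfig(nFrames = 4, nCells = 6, frameShape = c(128L, 128L),
                     seed = 9)
  expect_identical(sceneTruth(generateScene(cfg)),
                   sceneTruth(generateScene(cfg)))

  frozen <- sceneConfig(nFrames = 5, nCells = 4, frameShape = c(128L, 128L),
                        motionSd = 0, drift = c(0, 0), seed = 3)
  tr <- sceneTruth(generateScene(frozen))
  for (cell in unique(tr$cell)) {
    sub <- tr[tr$cell == cell, ]
    expect_equal(diff(range(sub$row)), 0)
    expect_equal(diff(range(sub$col)), 0)
  }

  # empty scene renders to pure background
  e <- sceneConfig(nFrames = 1, nCells = 0, frameShape = c(64L, 64L),
                   noiseSd = 0, seed = 1)
  rn <- renderTimeLapse(generateScene(e))
  expect_true(all(pixels(getFrame(rn$timelapse, 0)) == 6000L))
  expect_equal(nrow(rn$truth), 0)
})

test_that("drift moves all centers deterministically", {
  cfg <- sceneConfig(nFrames = 6, nCells = 3, frameShape = c(256L, 256L),
                     motionSd = 0, drift = c(1, 2), seed = 8)
  tr <- sceneTruth(generateScene(cfg))
  for (cell in unique(tr$cell)) {
    sub <- tr[tr$cell == cell, ][order(tr$frame[tr$cell == cell]), ]
    expect_equal(diff(sub$row), rep(1, 5))
    expect_equal(diff(sub$col), rep(2, 5))
  }
})

test_that("noiseless renders obey the additive disk model", {
  cfg <- sceneConfig(nFrames = 1, nCells = 1, frameShape = c(64L, 64L),
                     noiseSd = 0, illuminationGradient = 0,
                     flashProbability = 0, seed = 12)
  sc <- generateScene(cfg)
  rn <- renderTimeLapse(sc)
  px <- pixels(getFrame(rn$timelapse, 0))
  tr <- sceneTruth(sc)
  d <- sqrt(outer((0:63 - tr$row)^2, (0:63 - tr$col)^2, `+`))
  inside <- d <= tr$radius - 1   # clear of the smoothed rim
  outside <- d >= tr$radius + 1
  expect_true(all(px[inside] == 6000L + 4000L))
  expect_true(all(px[outside] == 6000L))

  # thresholding at background + contrast/2 recovers the label mask up to
  # the 1-px rim
  mask <- rn$masks[[1]] > 0
  got <- px > 6000 + 2000
  rim <- abs(d - tr$radius) <= 1
  expect_identical(got[!rim], mask[!rim])
})

test_that("flashes scale the disk height by the configured gain", {
  cfg <- sceneConfig(nFrames = 40, nCells = 1, frameShape = c(64L, 64L),
                     noiseSd = 0, motionSd = 0, flashProbability = 0.3,
                     flashGain = 1.8, seed = 21)
  sc <- generateScene(cfg)
  rn <- renderTimeLapse(sc)
  tr <- sceneTruth(sc)
  expect_gt(sum(tr$flashing), 0); expect_lt(sum(tr$flashing), 40)
  tOn <- tr$frame[tr$flashing][1]; tOff <- tr$frame[!tr$flashing][1]
  d <- sqrt(outer((0:63 - tr$row[1])^2, (0:63 - tr$col[1])^2, `+`))
  core <- d <= tr$radius[1] - 1
  hOn <- mean(pixels(getFrame(rn$timelapse, tOn))[core]) - 6000
  hOff <- mean(pixels(getFrame(rn$timelapse, tOff))[core]) - 6000
  expect_equal(hOn / hOff, 1.8, tolerance = 1e-3)
})

test_that("the empirical flash rate approaches the configured probability", {
  cfg <- sceneConfig(nFrames = 50, nCells = 20, frameShape = c(512L, 512L),
                     flashProbability = 0.1, seed = 31)
  tr <- sceneTruth(generateScene(cfg))
  p <- mean(tr$flashing)
  n <- nrow(tr)
  expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("scripted entries and exits cross the border mid-sequence", {
  cfg <- sceneConfig(nFrames = 40, nCells = 10, frameShape = c(256L, 256L),
                     entryExit = TRUE, nEnter = 2, nExit = 2, seed = 14)
  tr <- sceneTruth(generateScene(cfg))
  roles <- tapply(tr$role, tr$cell, `[`, 1)
  expect_equal(sum(roles == "enter"), 2)
  expect_equal(sum(roles == "exit"), 2)
  for (cell in names(roles)) {
    v <- tr$visible[tr$cell == as.integer(cell)]
    if (roles[[cell]] == "enter") expect_gt(which(v)[1], 1)
    if (roles[[cell]] == "exit") expect_lt(rev(which(v))[1], 40)
  }
  # invisible cells keep out-of-bounds centers, never dropped
  inv <- tr[!tr$visible, ]
  expect_true(all(inv$row < 0 | inv$row > 255 | inv$col < 0 | inv$col > 255))
  expect_equal(nrow(tr), 40 * 10)
})

test_that("overcrowded configurations fail with advice", {
  cfg <- sceneConfig(nFrames = 1, nCells = 60, frameShape = c(64L, 64L),
                     radiusRange = c(10, 12), seed = 2)
  expect_error(generateScene(cfg), "density")
})

test_that("rendering is deterministic for a fixed seed", {
  cfg <- sceneConfig(nFrames = 2, nCells = 5, frameShape = c(128L, 128L),
                     seed = 77)
  a <- renderTimeLapse(generateScene(cfg))
  b <- renderTimeLapse(generateScene(cfg))
  expect_identical(lapply(a$timelapse@frames, pixels),
                   lapply(b$timelapse@frames, pixels))
  expect_identical(a$masks, b$masks)
})
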