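test_that("tiles partition the frame exactly", {
  cfg <- segmentationConfig()
  f <- Frame(matrix(0L, 64, 64))
  tiles <- tileFrame(f, cfg)
  expect_equal(length(tiles), 4)
  expect_equal(lapply(tiles, `[[`, "origin"),
               list(c(0, 0), c(0, 32), c(32, 0), c(32, 32)))
  expect_length(tileFrame(Frame(matrix(0L, 32, 32)), cfg), 1)

  f2 <- Frame(matrix(0L, 70, 45))
  tiles2 <- tileFrame(f2, cfg)
  expect_equal(length(tiles2), 6)
  dims <- t(sapply(tiles2, function(t) dim(t$pixels)))
  origins <- t(sapply(tiles2, `[[`, "origin"))
  expect_true(all(origins %% 32 == 0))
  expect_equal(dims[origins[, 1] == 64, 1], c(6, 6))   # bottom band 6 rows
  expect_equal(dims[origins[, 2] == 32, 2], c(13, 13, 13)) # right band 13 cols
  # exact cover: every pixel in exactly one tile
  cover <- matrix(0L, 70, 45)
  for (tl in tiles2)
    cover[tl$origin[1] + seq_len(nrow(tl$pixels)),
          tl$origin[2] + seq_len(ncol(tl$pixels))] <-
      cover[tl$origin[1] + seq_len(nrow(tl$pixels)),
            tl$origin[2] + seq_len(ncol(tl$pixels))] + 1L
  expect_true(all(cover == 1L))
})

test_that("per-tile thresholds equal the exhaustive variance scan", {
  cfg <- segmentationConfig(thresholdBounds = c(0, 1),
                            autoThresholdBounds = FALSE)
  set.seed(31)
  for (rep in 1:60) {
    kind <- rep %% 3
    vals <- if (kind == 0) {
      as.integer(sample.int(65536L, 1024, replace = TRUE) - 1L)
    } else if (kind == 1) {
      as.integer(round(pmax(0, pmin(65535,
        c(rnorm(900, 6000, 500), rnorm(124, 10000, 500))))))
    } else {
      as.integer(sample(c(10L, 200L, 5000L), 1024, replace = TRUE,
                        prob = c(0.7, 0.2, 0.1)))
    }
    tile <- list(pixels = matrix(vals, 32, 32), origin = c(0L, 0L),
                 bitDepth = 16L)
    got <- thresholdTile(tile, cfg)
    expect_false(got$cellFree)
    expect_identical(got$threshold, bruteOtsu(vals))
  }
})

test_that("threshold bounds declare tiles cell-free", {
  cfg <- segmentationConfig(thresholdBounds = c(0, 1),
                            autoThresholdBounds = FALSE)
  zero <- list(pixels = matrix(0L, 32, 32), origin = c(0L, 0L),
               bitDepth = 16L)
  expect_true(thresholdTile(zero, cfg)$cellFree)

  px <- matrix(10L, 32, 32); px[10:17, 10:17] <- 200L
  tile <- list(pixels = px, origin = c(0L, 0L), bitDepth = 16L)
  got <- thresholdTile(tile, cfg)
  expect_false(got$cellFree)
  expect_gt(got$threshold, 10); expect_lt(got$threshold, 200)
  expect_identical(which(got$mask), which(px == 200L))

  high <- segmentationConfig(thresholdBounds = c(0.9, 1),
                             autoThresholdBounds = FALSE)
  expect_true(thresholdTile(tile, high)$cellFree)
})

test_that("component extraction is 8-connected and area-bounded", {
  cfg <- segmentationConfig(minComponentArea = 75, maxComponentArea = 450,
                            autoThresholdBounds = FALSE)
  f <- Frame(matrix(10L, 64, 64))
  tile <- tileFrame(f, cfg)[[1]]
  empty <- matrix(FALSE, 32, 32)
  expect_length(extractComponents(empty, tile, f, cfg), 0)

  # two diagonal-touching blobs are one 8-connected component
  m <- matrix(FALSE, 32, 32)
  m[2:11, 2:11] <- TRUE          # area 100
  m[12:14, 12:14] <- TRUE        # area 9, touching only diagonally
  small <- segmentationConfig(minComponentArea = 1, maxComponentArea = 450,
                              autoThresholdBounds = FALSE)
  comps <- extractComponents(m, tile, f, small)
  expect_length(comps, 1)
  expect_equal(features(comps[[1]])$area, 109)

  # areas {3, 120, 600}: only the 120 survives [75, 450]
  tile64 <- list(pixels = matrix(10L, 40, 40), origin = c(0L, 0L),
                 bitDepth = 16L)
  m3 <- matrix(FALSE, 40, 40)
  m3[1, 1:3] <- TRUE                       # 3
  m3[5:14, 5:16] <- TRUE                   # 120
  m3[17:40, 16:40] <- TRUE                 # 600
  f40 <- Frame(matrix(10L, 40, 40))
  comps3 <- extractComponents(m3, tile64, f40, cfg)
  expect_length(comps3, 1)
  expect_equal(features(comps3[[1]])$area, 120)

  expect_error(extractComponents(matrix(FALSE, 5, 5), tile, f, cfg),
               "dimensions")
})

test_that("circle seeding finds rendered disks and ignores blank frames", {
  cfg <- segmentationConfig(circleRadiusRange = c(4, 16))
  blank <- Frame(matrix(500L, 64, 64))
  expect_equal(nrow(detectCircles(blank, cfg)), 0)

  one <- renderDiskFrame(c(64, 64), matrix(c(16, 16), 1), 8, 1000, 30000)
  seeds <- detectCircles(one, cfg)
  expect_gte(nrow(seeds), 1)
  expect_lte(abs(seeds$row[1] - 16) , 1)
  expect_lte(abs(seeds$col[1] - 16), 1)
  expect_lte(abs(seeds$radius[1] - 8), 2)

  two <- renderDiskFrame(c(64, 64), rbind(c(20, 20), c(20, 44)), c(6, 6),
                         1000, 30000)
  seeds2 <- detectCircles(two, cfg)
  expect_gte(nrow(seeds2), 2)
  d1 <- sqrt((seeds2$row - 20)^2 + (seeds2$col - 20)^2)
  d2 <- sqrt((seeds2$row - 20)^2 + (seeds2$col - 44)^2)
  expect_true(min(d1) <= 1 && min(d2) <= 1)
  expect_error(detectCircles(one, segmentationConfig(circleRadiusRange = c(0.5, 4))),
               ">= 1")
})

test_that("a disk centered on a tile boundary yields one whole detection", {
  # disk of radius 6 straddling the column-32 boundary of a 64x64 frame
  f <- renderDiskFrame(c(64, 64), matrix(c(16, 31.5), 1), 6, 1000, 30000)
  cfg <- segmentationConfig(minComponentArea = 50, maxComponentArea = 450,
                            autoThresholdBounds = FALSE,
                            thresholdBounds = c(0, 1))
  dets <- segmentFrame(f, cfg)
  expect_length(dets, 1)
  truthPx <- diskPixels(16, 31.5, 6)
  got <- pixelSet(dets[[1]])
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(truthPx[, 1], truthPx[, 2]))
})

test_that("boundary re-processing leaves interior detections untouched", {
  f <- renderDiskFrame(c(96, 96), rbind(c(16, 15), c(50, 63.5)), c(6, 6),
                       1000, 30000)
  cfg <- segmentationConfig(minComponentArea = 50, maxComponentArea = 450,
                            autoThresholdBounds = FALSE,
                            thresholdBounds = c(0, 1))
  # first-pass (tiled) detections without boundary handling
  firstPass <- list()
  for (tl in tileFrame(f, cfg)) {
    th <- thresholdTile(tl, cfg)
    if (!th$cellFree)
      firstPass <- c(firstPass, extractComponents(th$mask, tl, f, cfg))
  }
  resolved <- resolveBoundaries(f, firstPass, cfg)
  expect_length(resolved, 2)
  cens <- t(sapply(resolved, function(d) features(d)$centroid))
  interior <- which.min((cens[, 1] - 16)^2 + (cens[, 2] - 15)^2)
  ip <- resolved[[interior]]
  match1 <- Filter(function(d) abs(features(d)$centroid[1] - 16) < 2,
                   firstPass)
  expect_identical(pixelSet(ip), pixelSet(match1[[1]]))
  # the boundary cell is whole
  bd <- resolved[[3 - interior]]
  expect_equal(features(bd)$area, nrow(diskPixels(50, 63.5, 6)),
               tolerance = 0.05)
})

test_that("interior-only detections are returned unchanged", {
  f <- renderDiskFrame(c(64, 64), matrix(c(16, 15), 1), 5, 1000, 30000)
  cfg <- segmentationConfig(minComponentArea = 20, maxComponentArea = 450,
                            autoThresholdBounds = FALSE,
                            thresholdBounds = c(0, 1))
  firstPass <- list()
  for (tl in tileFrame(f, cfg)) {
    th <- thresholdTile(tl, cfg)
    if (!th$cellFree)
      firstPass <- c(firstPass, extractComponents(th$mask, tl, f, cfg))
  }
  expect_identical(resolveBoundaries(f, firstPass, cfg), firstPass)
})

test_that("segmentation recovers well-separated disks with sub-pixel accuracy", {
  centers <- rbind(c(20, 20), c(20, 70), c(60, 40), c(90, 90), c(100, 20))
  radii <- c(5, 7, 9, 10, 6)
  f <- renderDiskFrame(c(128, 128), centers, radii, 1000, 30000)
  cfg <- segmentationConfig(minComponentArea = 50, maxComponentArea = 450,
                            autoThresholdBounds = FALSE,
                            thresholdBounds = c(0, 1))
  dets <- segmentFrame(f, cfg)
  expect_length(dets, 5)
  cens <- t(sapply(dets, function(d) features(d)$centroid))
  for (k in 1:5) {
    d <- sqrt((cens[, 1] - centers[k, 1])^2 + (cens[, 2] - centers[k, 2])^2)
    expect_lte(min(d), 1)
  }
  # blank frame: nothing
  expect_length(segmentFrame(Frame(matrix(900L, 64, 64)), cfg), 0)
})

test_that("segmentation is equivariant under a one-tile shift", {
  centers <- rbind(c(20, 18), c(50, 52))
  f <- renderDiskFrame(c(96, 96), centers, c(6, 7), 1000, 30000)
  shifted <- renderDiskFrame(c(128, 128), centers + 32, c(6, 7), 1000, 30000)
  cfg <- segmentationConfig(minComponentArea = 50, maxComponentArea = 450,
                            autoThresholdBounds = FALSE,
                            thresholdBounds = c(0, 1))
  a <- segmentFrame(f, cfg)
  b <- segmentFrame(shifted, cfg)
  expect_equal(length(a), length(b))
  ca <- t(sapply(a, function(d) features(d)$centroid))
  cb <- t(sapply(b, function(d) features(d)$centroid))
  expect_equal(cb[order(cb[, 1]), ], ca[order(ca[, 1]), ] + 32,
               tolerance = 1e-8)
})

test_that("detections never share pixels and carry tight boxes", {
  set.seed(33)
  cfg0 <- sceneConfig(nFrames = 1, nCells = 12, frameShape = c(256L, 256L),
                      seed = 77, flashProbability = 0)
  rn <- renderTimeLapse(generateScene(cfg0))
  ef <- stretchContrast(getFrame(rn$timelapse, 0))
  dets <- segmentFrame(ef, segmentationConfig(maxComponentArea = 600))
  keys <- unlist(lapply(dets, function(d)
    pixelSet(d)[, 1] * 256 + pixelSet(d)[, 2]))
  expect_identical(anyDuplicated(keys), 0L)
  for (d in dets) expect_true(validObject(d))
})
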