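test_that("gradient response is zero on constants and peaks at step edges", {
  expect_lt(max(axialGradientResponse(matrix(0.5, 60, 20), 6)), 1e-10)
  img <- rbind(matrix(0, 40, 15), matrix(1, 40, 15))
  resp <- axialGradientResponse(img, 6)
  peaks <- apply(resp, 2, which.max)
  expect_true(all(abs(peaks - 40.5) <= 1))
  expect_error(axialGradientResponse(1:10, 6), "2-D")
})

test_that("the strongest response bands sit at the true retinal interfaces", {
  # per column, the top two well-separated peaks must mark (a) the ILM and
  # (b) the EZ/RPE complex -- at sigma = 6 the ellipsoid and RPE bands blur
  # into one response band whose extent spans [ez, rpe]
  cfg <- deskPhantomConfig(seed = 31, speckle = 0)
  b <- generateBScan(cfg, sliceIndex = 12)
  resp <- axialGradientResponse(b$pixels, 6)
  cols <- seq(20, cfg$nCols - 20, by = 12)
  hits <- vapply(cols, function(cc) {
    ord <- order(resp[, cc], decreasing = TRUE)
    top1 <- ord[1]
    top2 <- ord[which(abs(ord - top1) > 12)[1]]
    peaks <- sort(c(top1, top2))
    ilmOk <- abs(peaks[1] - b$surfaces$ilm[cc]) <= 5
    # the complex's response peak can shift by ~sigma past the RPE band
    ezOk <- peaks[2] >= b$surfaces$ez[cc] - 6 &&
      peaks[2] <= b$surfaces$rpe[cc] + 9
    ilmOk && ezOk
  }, TRUE)
  expect_gt(mean(hits), 0.95)
})

test_that("Otsu threshold equals the exhaustive-search oracle", {
  withr::with_seed(42, {
    for (trial in 1:100) {
      v <- switch(1 + trial %% 3,
        runif(500),
        c(rnorm(300, 0.2, 0.05), rnorm(200, 0.8, 0.1)),
        rbeta(400, 0.5, 0.5))
      expect_equal(otsuThreshold(v), otsuOracle(v), tolerance = 1e-12)
    }
  })
})

test_that("Otsu separates a two-valued image and rejects constants", {
  v <- c(rep(0, 60), rep(1, 40))
  thr <- otsuThreshold(v)
  expect_gt(thr, 0)
  expect_lt(thr, 1)
  expect_error(otsuThreshold(rep(0.3, 100)), "degenerate")
})

test_that("largest components match the flood-fill oracle on random images", {
  withr::with_seed(7, {
    for (trial in 1:100) {
      bw <- matrix(runif(30 * 40) < 0.35, 30, 40)
      got <- largestComponents(bw, k = 2)$labels
      want <- floodFillOracle(bw)
      # same partition: label images agree up to renaming
      expect_equal(got > 0, want > 0)
      if (max(want) > 0) {
        tab <- table(got[got > 0], want[want > 0])
        expect_true(all(rowSums(tab > 0) == 1))
        expect_true(all(colSums(tab > 0) == 1))
      }
    }
  })
})

test_that("component ranking keeps the k largest, ties broken by top row", {
  bw <- matrix(FALSE, 40, 40)
  bw[2:6, 2:11] <- TRUE      # 50 px
  bw[20:22, 1:10] <- TRUE    # 30 px
  bw[35, 1:5] <- TRUE        # 5 px
  lc <- largestComponents(bw, k = 2)
  expect_equal(sort(lc$sizes), c(30, 50))
  expect_false(lc$short)
  kept <- matrix(lc$labels %in% lc$keep, nrow(bw))
  expect_true(all(kept[2:6, 2:11]))
  expect_true(all(kept[20:22, 1:10]))
  expect_false(any(kept[35, 1:5]))
  # equal sizes: the component starting higher in the image ranks first
  bw2 <- matrix(FALSE, 30, 30)
  bw2[3:4, 1:5] <- TRUE
  bw2[20:21, 1:5] <- TRUE
  lc2 <- largestComponents(bw2, k = 1)
  expect_true(3 %in% row(bw2)[lc2$labels == lc2$keep[1]])
  # degenerate: nothing above threshold
  lc0 <- largestComponents(matrix(FALSE, 5, 5))
  expect_true(lc0$short)
  expect_length(lc0$keep, 0)
})

test_that("bounding box expansion follows the symmetric-centre rule", {
  bw <- matrix(FALSE, 512, 40)
  bw[121:141, 1:18] <- TRUE
  bw[261:286, 1:22] <- TRUE
  box <- retinaBoundingBox(largestComponents(bw), 512, 300)
  expect_equal(box$top, 54)      # rows 54..353 = [53, 353) zero-based
  expect_equal(box$bottom, 353)
  expect_equal(box$height, 300)
  # span already tall enough is untouched
  bw2 <- matrix(FALSE, 512, 20)
  bw2[101:140, 1:10] <- TRUE
  bw2[421:460, 1:10] <- TRUE
  box2 <- retinaBoundingBox(largestComponents(bw2), 512, 300)
  expect_equal(c(box2$top, box2$bottom), c(101, 460))
  # span centred near the top edge clips to [1, 300]
  bw3 <- matrix(FALSE, 512, 20)
  bw3[25:35, 1:10] <- TRUE
  box3 <- retinaBoundingBox(largestComponents(bw3), 512, 300)
  expect_equal(c(box3$top, box3$bottom), c(1, 300))
  expect_error(retinaBoundingBox(list(keep = integer()), 512, 300),
               "no components")
})

test_that("retina boxes honour the height contract and contain the retina", {
  heights <- numeric(0)
  contained <- numeric(0)
  for (s in 1:200) {
    cfg <- microConfig(seed = s)
    slice <- 1 + (s %% cfg$nSlices)
    b <- generateBScan(cfg, sliceIndex = slice)
    box <- locateRetina(b$pixels)
    minH <- round(300 * cfg$nRows / 512)
    heights <- c(heights, box$height)
    contained <- c(contained,
                   mean(b$surfaces$ilm >= box$top & b$surfaces$rpe <= box$bottom))
  }
  expect_true(all(heights >= round(300 * 128 / 512)))
  expect_gte(mean(contained), 0.99)
})

test_that("preprocessing emits the exact standard shapes", {
  for (cfg in list(microConfig(seed = 1),
                   phantomConfig(nRows = 200, nCols = 300, nSlices = 8,
                                 seed = 2))) {
    b <- generateBScan(cfg, sliceIndex = 3)
    expect_equal(dim(preprocessBScan(b$pixels, path = "transfer")),
                 c(300L, 512L))
    den <- preprocessBScan(b$pixels, path = "denovo")
    expect_equal(dim(den), c(150L, 256L))
    expect_true(all(den >= 0 & den <= 1))
  }
})

test_that("preprocessVolume keeps labels and order", {
  vol <- generateVolume(microConfig(seed = 6),
                        list(lesionSpec("ped", c(3, 6), 128, 60, 18)))
  pre <- preprocessVolume(vol)
  expect_equal(dim(pre@pixels), c(150, 256, 12))
  expect_identical(sliceLabels(pre), sliceLabels(vol))
  expect_identical(volumeId(pre), volumeId(vol))
})

test_that("augmentation with zero ranges is the identity", {
  img <- tinyImage(3, c(40, 50))
  cfg0 <- preprocessConfig(rotationRange = 0, translationRange = 0,
                           contrastRange = c(1, 1), flipProb = 0)
  expect_identical(augmentImage(img, cfg0), img)
  # flip is an involution
  p <- list(angle = 0, dx = 0, dy = 0, contrast = 1, flip = TRUE)
  expect_identical(applyAugment(applyAugment(img, p), p), img)
  # fixed contrast of 1 with zero geometry is also the identity
  p1 <- list(angle = 0, dx = 0, dy = 0, contrast = 1, flip = FALSE)
  expect_identical(applyAugment(img, p1), img)
})

test_that("augmentation is reproducible under a fixed seed", {
  img <- tinyImage(4, c(60, 60))
  cfg <- preprocessConfig()
  a <- withr::with_seed(99, augmentImage(img, cfg))
  b <- withr::with_seed(99, augmentImage(img, cfg))
  expect_identical(a, b)
  expect_false(identical(a, img))
  expect_true(all(a >= 0 & a <= 1))
  # translation moves content by the requested offset
  p <- list(angle = 0, dx = 5, dy = -3, contrast = 1, flip = FALSE)
  shifted <- applyAugment(img, p)
  expect_equal(shifted[10, 20], img[13, 15])
})
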