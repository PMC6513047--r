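test_that("channel bookkeeping: GAP width and final spatial sizes", {
  net <- buildDenovoNet(networkConfig(), seed = 1)
  img <- tinyImage(1, c(150, 256))
  featsL <- octsum:::netFeatureMaps(net, img)
  expect_equal(dim(featsL), c(1, 2, 609))   # seven floor-halvings of 150x256
  netC <- buildDenovoNet(networkConfig(poolingMode = "cam_friendly"), seed = 1)
  featsC <- octsum:::netFeatureMaps(netC, img)
  expect_equal(dim(featsC), c(4, 8, 609))   # five halvings only
  expect_equal(countTrainable(net), countTrainable(netC))
})

test_that("trainable parameters match the closed-form sum", {
  expect_equal(paramCountFormula(), 1389700L)
  expect_equal(countTrainable(buildDenovoNet(networkConfig())), 1389700L)
  # conv stack alone: 1,388,480 = 1,389,700 - (609 * 2 + 2)
  expect_equal(paramCountFormula() - (609L * 2L + 2L), 1388480L)
  # property: arbitrary filter widths
  withr::with_seed(10, {
    for (trial in 1:8) {
      fw <- sample(2:12, 7, replace = TRUE)
      cfg <- networkConfig(filterWidths = fw, inputShape = c(32L, 32L))
      expect_equal(countTrainable(buildDenovoNet(cfg, seed = trial)),
                   paramCountFormula(fw))
    }
  })
  # first-layer bookkeeping: 8 filters of 3x3 on 1 input channel = 9*8 + 8
  net8 <- buildDenovoNet(networkConfig(filterWidths = c(8L, rep(1L, 6)),
                                       inputShape = c(32L, 32L)))
  expect_equal(length(net8@convW[[1]]) + length(net8@convB[[1]]), 80L)
  expect_error(networkConfig(filterWidths = c(8, 8)), "7 conv layers")
})

test_that("balanced cross-entropy matches hand computations", {
  expect_equal(balancedCrossEntropy(c(1, 0), c(0.5, 0.5)),
               -2 * log(0.5), tolerance = 1e-9)
  expect_equal(balancedCrossEntropy(c(1, 0, 0), c(0.9, 0.2, 0.4)),
               2 * (-log(0.9)) + (-log(0.8) - log(0.6)), tolerance = 1e-9)
  # near-perfect prediction: loss vanishes
  expect_lt(balancedCrossEntropy(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-5)
  expect_error(balancedCrossEntropy(numeric(), numeric()), "empty")
})

test_that("loss weighting balances duplicated classes symmetrically", {
  y <- c(1, 0, 0, 0)
  p <- c(0.7, 0.4, 0.3, 0.2)
  base <- balancedCrossEntropy(y, p)
  # each class's total weight is (#own) * (#other) = 3 for both classes
  # duplicating the minority sample 3 times makes the batch balanced:
  # weights become 3 per sample, total per class 9 each
  y2 <- c(rep(1, 3), 0, 0, 0)
  p2 <- c(rep(0.7, 3), 0.4, 0.3, 0.2)
  expect_equal(balancedCrossEntropy(y2, p2), 3 * base, tolerance = 1e-9)
  # order invariance
  perm <- c(3, 1, 4, 2)
  expect_equal(balancedCrossEntropy(y[perm], p[perm]), base, tolerance = 1e-12)
})

test_that("zero FC weights give exactly 0.5 probabilities and zero CAM", {
  cfg <- tinyNetConfig()
  net <- buildDenovoNet(cfg, seed = 2)
  net@fcW[] <- 0
  net@fcB[] <- 0
  img <- tinyImage(5, cfg$inputShape)
  pred <- predictSlices(net, img)
  expect_equal(pred$probability, 0.5)
  expect_true(pred$flag)  # threshold is >= 0.5
  cam <- computeCAM(net, img, 2)
  expect_true(all(cam$map == 0))
})

test_that("CAM equals the explicit weighted feature sum and is linear", {
  cfg <- tinyNetConfig("cam_friendly")
  net <- buildDenovoNet(cfg, seed = 3)
  img <- tinyImage(6, cfg$inputShape)
  feats <- octsum:::netFeatureMaps(net, img)
  for (cls in 1:2) {
    oracle <- apply(sweep(feats, 3, net@fcW[cls, ], `*`), c(1, 2), sum)
    expect_equal(computeCAM(net, img, cls)$map, oracle, tolerance = 1e-5)
  }
  m1 <- computeCAM(net, img, 1)$map
  m2 <- computeCAM(net, img, 2)$map
  sumNet <- net
  sumNet@fcW[1, ] <- net@fcW[1, ] + net@fcW[2, ]
  expect_equal(computeCAM(sumNet, img, 1)$map, m1 + m2, tolerance = 1e-5)
  expect_equal(dim(computeCAM(net, img, 2)$upsampled), cfg$inputShape)
  expect_error(computeCAM(net, img, 3), "classIndex")
})

test_that("analytic gradients match directional finite differences", {
  cfg <- networkConfig(filterWidths = rep(2L, 7), inputShape = c(16L, 20L))
  net <- buildDenovoNet(cfg, seed = 3)
  pool <- octsum:::poolSchedule(cfg)
  x <- withr::with_seed(42, array(runif(16 * 20 * 2), c(16, 20, 2)))
  y <- c(1L, 0L)
  w <- c(1.5, 2)
  lossAt <- function(n) octsum:::cpp_net_grad(n@convW, n@convB, n@fcW, n@fcB,
                                              x, y, w, pool, 1e-7)$loss
  g <- octsum:::cpp_net_grad(net@convW, net@convB, net@fcW, net@fcB,
                             x, y, w, pool, 1e-7)
  dirs <- withr::with_seed(7, lapply(net@convW, function(m)
    matrix(rnorm(length(m)), nrow(m))))
  dirFc <- withr::with_seed(8, matrix(rnorm(length(net@fcW)), nrow(net@fcW)))
  shift <- function(n, s) {
    for (i in 1:7) n@convW[[i]] <- n@convW[[i]] + s * dirs[[i]]
    n@fcW <- n@fcW + s * dirFc
    n
  }
  eps <- 1e-3
  fd <- (lossAt(shift(net, eps)) - lossAt(shift(net, -eps))) / (2 * eps)
  an <- sum(mapply(function(gm, d) sum(gm * d), g$convW, dirs)) +
    sum(g$fcW * dirFc)
  expect_equal(an, fd, tolerance = 1e-3)
})

test_that("prediction flags are a monotone 0.5 threshold on probabilities", {
  cfg <- tinyNetConfig()
  net <- buildDenovoNet(cfg, seed = 9)
  x <- withr::with_seed(11, array(runif(prod(cfg$inputShape) * 6),
                                  c(cfg$inputShape, 6)))
  pred <- predictSlices(net, x)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_identical(pred$flag, pred$probability >= 0.5)
  expect_error(predictSlices(net, array(0, c(10, 10, 2))), "input stack")
})

test_that("checkpoints round-trip the network exactly enough to reproduce", {
  cfg <- tinyNetConfig()
  net <- buildDenovoNet(cfg, seed = 12)
  tf <- withr::local_tempfile(fileext = ".json")
  saveNet(net, tf)
  back <- loadNet(tf)
  expect_equal(back@convW, net@convW, tolerance = 1e-12)
  expect_equal(back@fcW, net@fcW, tolerance = 1e-12)
  img <- tinyImage(13, cfg$inputShape)
  expect_equal(predictSlices(back, img)$probability,
               predictSlices(net, img)$probability, tolerance = 1e-7)
})
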