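test_that("tverskyIndex matches hand-counted cases and the printed formula", {
  X <- c(1, 1, 1, 1, 0, 0)
  Y <- c(1, 1, 0, 0, 1, 0)   # |X|=4, |Y|=3, |X∩Y|=2
  expect_equal(tverskyIndex(X, Y, beta = 0.5, epsilon = 0), 2 / 3.5,
               tolerance = 1e-12)
  expect_equal(tverskyIndex(X, Y, beta = 0.75, epsilon = 0), 2 / 3.75,
               tolerance = 1e-12)
  expect_equal(tverskyIndex(Y, Y, beta = 0.3), 1, tolerance = 1e-6)
  expect_error(tverskyIndex(c(1, 0), c(1, 0, 1)), "shape mismatch")
})

test_that("focal Tversky loss follows alpha * (1 - T)^gamma", {
  X <- c(1, 1, 1, 1, 0, 0); Y <- c(1, 1, 0, 0, 1, 0)
  cfg <- lossConfig(epsilon = 1e-12)
  t <- 2 / 3.75
  expect_equal(focalTverskyLoss(X, Y, cfg), (1 - t)^2, tolerance = 1e-6)
  expect_lt(focalTverskyLoss(Y, Y, cfg), 1e-10)
  disjoint <- lossConfig(beta = 0.5, epsilon = 1e-12)
  expect_equal(focalTverskyLoss(c(1, 0), c(0, 1), disjoint), 1, tolerance = 1e-6)
})

test_that("boundary-smoothing loss equals the double-loop finite-difference oracle", {
  # 4x4 step edge versus a flat truth
  P <- matrix(rep(c(0, 0, 1, 1), each = 4), 4, 4, byrow = TRUE)
  Tm <- matrix(0, 4, 4)
  expect_equal(boundarySmoothnessLoss(P, Tm, lambdaSmooth = 0.3),
               bfBoundaryLoss(P, Tm, 0.3), tolerance = 1e-12)
  expect_equal(boundarySmoothnessLoss(P, P, lambdaSmooth = 0.3), 0)
  expect_equal(boundarySmoothnessLoss(P, Tm, lambdaSmooth = 0), 0)
  set.seed(11)
  for (i in 1:20) {
    A <- matrix(runif(30), 5, 6)
    B <- matrix(runif(30), 5, 6)
    expect_equal(boundarySmoothnessLoss(A, B, 0.7), bfBoundaryLoss(A, B, 0.7),
                 tolerance = 1e-10)
  }
})

test_that("total loss is the sum of its two oracle-checked terms", {
  set.seed(12)
  cfg <- lossConfig(lambdaSmooth = 0.05)
  for (i in 1:10) {
    X <- matrix(runif(64), 8, 8)
    Y <- randomMask(8, 8)
    expect_equal(totalLoss(X, Y, cfg),
                 bfFocalTversky(X, Y, beta = 0.75) + bfBoundaryLoss(X, Y, 0.05),
                 tolerance = 1e-8)
  }
  cfg0 <- lossConfig(lambdaSmooth = 0)
  X <- matrix(runif(64), 8, 8); Y <- randomMask(8, 8)
  expect_equal(totalLoss(X, Y, cfg0), focalTverskyLoss(X, Y, cfg0))
  expect_lt(totalLoss(Y, Y, cfg), 1e-5)
})

test_that("Dice and IoU match hand counts, identities, and edge conventions", {
  X <- c(1, 1, 1, 1, 0, 0); Y <- c(1, 1, 0, 0, 1, 0)
  expect_equal(diceScore(X, Y), 4 / 7, tolerance = 1e-12)
  expect_equal(iouScore(X, Y), 2 / 5, tolerance = 1e-12)
  expect_equal(diceScore(X, Y), 2 * iouScore(X, Y) / (1 + iouScore(X, Y)))
  expect_equal(diceScore(Y, Y), 1)
  expect_equal(iouScore(c(1, 0), c(0, 1)), 0)
  expect_equal(diceScore(numeric(4), numeric(4)), 1)   # empty vs empty
})

test_that("reduction identities hold over random mask pairs", {
  set.seed(13)
  for (i in 1:200) {
    X <- randomMask(6, 6, runif(1, 0.2, 0.8))
    Y <- randomMask(6, 6, runif(1, 0.2, 0.8))
    d <- diceScore(X, Y)
    expect_equal(tverskyIndex(X, Y, beta = 0.5, epsilon = 1e-9), d,
                 tolerance = 1e-6)
    expect_equal(d, 2 * iouScore(X, Y) / (1 + iouScore(X, Y)), tolerance = 1e-12)
    # printed and standard Tversky agree on hard masks (beta roles swapped):
    # beta|X| + (1-beta)|Y| = TP + beta FP + (1-beta) FN
    expect_equal(tverskyIndex(X, Y, beta = 0.75, variant = "printed"),
                 tverskyIndex(X, Y, beta = 1 - 0.75, variant = "standard"),
                 tolerance = 1e-9)
  }
})

test_that("focal Tversky loss is monotone non-increasing in the Tversky index", {
  cfg <- lossConfig()
  ts <- seq(0, 1, by = 0.01)
  ls <- cfg@alpha * (1 - ts)^cfg@gamma
  expect_true(all(diff(ls) <= 1e-15))
})

test_that("multi-class loss reduction averages one-vs-rest foreground classes", {
  set.seed(14)
  lab <- matrix(sample(0:2, 64, TRUE), 8, 8)
  probs <- array(runif(8 * 8 * 3), c(8, 8, 3))
  probs <- probs / rep(apply(probs, c(1, 2), sum), times = 3)
  cfg <- lossConfig(lambdaSmooth = 0.02)
  manual <- mean(c(focalTverskyLoss(probs[, , 2], (lab == 1) * 1, cfg),
                   focalTverskyLoss(probs[, , 3], (lab == 2) * 1, cfg)))
  expect_equal(focalTverskyLoss(probs, lab, cfg), manual, tolerance = 1e-12)
  manualSm <- mean(c(boundarySmoothnessLoss(probs[, , 2], (lab == 1) * 1, 0.02),
                     boundarySmoothnessLoss(probs[, , 3], (lab == 2) * 1, 0.02)))
  expect_equal(boundarySmoothnessLoss(probs, lab, 0.02), manualSm,
               tolerance = 1e-12)
})

test_that("multiclassMetrics reports per-class scores and the foreground mean", {
  pred <- matrix(c(0, 1, 1, 2, 2, 0), 2, 3)
  truth <- matrix(c(0, 1, 2, 2, 2, 0), 2, 3)
  m <- multiclassMetrics(pred, truth)
  expect_equal(nrow(m), 3L)
  d1 <- diceScore((pred == 1) * 1, (truth == 1) * 1)
  d2 <- diceScore((pred == 2) * 1, (truth == 2) * 1)
  expect_equal(m$dice[m$class == "mean_foreground"], mean(c(d1, d2)))
})

test_that("cross-entropy matches direct computation and Dice loss is a config", {
  set.seed(15)
  lab <- matrix(sample(0:2, 16, TRUE), 4, 4)
  probs <- array(runif(4 * 4 * 3, 0.05, 1), c(4, 4, 3))
  probs <- probs / rep(apply(probs, c(1, 2), sum), times = 3)
  manual <- 0
  for (i in 1:4) for (j in 1:4)
    manual <- manual - log(probs[i, j, lab[i, j] + 1])
  expect_equal(crossEntropyLoss(probs, lab), manual / 16, tolerance = 1e-12)
  # perfect one-hot prediction: zero cross-entropy (up to the log floor)
  onehot <- array(0, c(4, 4, 3))
  for (i in 1:4) for (j in 1:4) onehot[i, j, lab[i, j] + 1] <- 1
  expect_lt(crossEntropyLoss(onehot, lab), 1e-10)
  # soft Dice loss is the beta = 0.5, gamma = 1 member of the family
  X <- matrix(runif(16), 4, 4); Y <- randomMask(4, 4)
  cfgDice <- lossConfig(beta = 0.5, gamma = 1, lambdaSmooth = 0, epsilon = 1e-9)
  expect_equal(focalTverskyLoss(X, Y, cfgDice), 1 - diceScore2soft(X, Y),
               tolerance = 1e-6)
})
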