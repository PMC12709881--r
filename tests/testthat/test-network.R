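test_that("forward pass preserves spatial dimensions and maps to 3 classes", {
  cfg <- tinyNetConfig(base = 8, levels = 3)
  m <- buildModel(cfg, seed = 1)
  logits <- modelForward(m, matrix(runif(64 * 64), 64, 64))
  expect_identical(dim(logits), c(64L, 64L, 3L))
  # non-square input divisible by 2^(levels-1)
  logits2 <- modelForward(m, matrix(runif(32 * 64), 32, 64))
  expect_identical(dim(logits2), c(32L, 64L, 3L))
  expect_error(modelForward(m, matrix(0.5, 30, 30)), "not divisible by 4")
})

test_that("seeded builds are reproducible and seeds change the parameters", {
  cfg <- tinyNetConfig(base = 8, levels = 3)
  m1 <- buildModel(cfg, seed = 5)
  m2 <- buildModel(cfg, seed = 5)
  expect_identical(modelChecksum(m1), modelChecksum(m2))
  expect_identical(m1$params, m2$params)
  m3 <- buildModel(cfg, seed = 6)
  expect_false(identical(modelChecksum(m1), modelChecksum(m3)))
})

test_that("ablation switches remove the attention blocks (plain U-Net baseline)", {
  plain <- buildModel(networkConfig(levels = 3, baseFilters = 8,
                                    useCBAM = FALSE, useSE = FALSE), seed = 2)
  expect_false(any(grepl("cbam|\\.se\\.", names(plain$params))))
  full <- buildModel(tinyNetConfig(base = 8, levels = 3), seed = 2)
  expect_true(any(grepl("cbam", names(full$params))))
  expect_true(any(grepl("\\.se\\.", names(full$params))))
  # both forward cleanly on the same input
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(dim(modelForward(plain, x)), c(32L, 32L, 3L))
  # bottleneck CBAM is off by default and adds parameters when enabled
  withBn <- buildModel(networkConfig(levels = 3, baseFilters = 8,
                                     cbamReduction = 8, seReduction = 8,
                                     cbamAtBottleneck = TRUE), seed = 2)
  expect_true(any(grepl("enc3.cbam", names(withBn$params))))
  expect_false(any(grepl("enc3.cbam", names(full$params))))
})

test_that("bilinear upsampling variant forwards and trains like the default", {
  cfg <- networkConfig(levels = 2, baseFilters = 4, cbamReduction = 2,
                       seReduction = 2, spatialKernel = 3,
                       upsampleMode = "bilinear")
  m <- buildModel(cfg, seed = 3)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(dim(modelForward(m, x)), c(16L, 16L, 3L))
})

test_that("predictVolume emits {0,1,2} labels matching the per-pixel argmax", {
  cfg <- tinyNetConfig(base = 8, levels = 3)
  m <- buildModel(cfg, seed = 4)
  vol <- CTVolume(array(runif(3 * 32 * 32, 0, 255), c(3, 32, 32)))
  pred <- predictVolume(m, vol)
  expect_s4_class(pred, "LabelVolume")
  expect_identical(dim(pred), dim(vol))
  expect_true(all(voxelData(pred) %in% 0:2))
  # brute-force argmax over the 3 logits for one slice
  logits <- modelForward(m, matrix(voxelData(vol)[2, , ], 32, 32))
  ref <- matrix(0L, 32, 32)
  for (i in 1:32) for (j in 1:32) ref[i, j] <- which.max(logits[i, j, ]) - 1L
  expect_identical(matrix(voxelData(pred)[2, , ], 32, 32), ref)
})

test_that("analytic gradients agree with finite differences everywhere", {
  ns <- asNamespace("kernelCT")
  set.seed(42)
  cfg <- networkConfig(levels = 3, baseFilters = 4, cbamReduction = 2,
                       seReduction = 2, spatialKernel = 3)
  m <- buildModel(cfg, seed = 7)
  x <- array(runif(64), c(8, 8, 1))
  lab <- matrix(sample(0:2, 64, TRUE), 8, 8)
  lc <- lossConfig(lambdaSmooth = 0.1)
  lossOf <- function(model) {
    fw <- ns$netForward(model, x, training = TRUE)
    ns$segmentationLoss(ns$softmaxProbs(fw$logits), lab, lc)$value
  }
  fw <- ns$netForward(m, x, training = TRUE)
  probs <- ns$softmaxProbs(fw$logits)
  sl <- ns$segmentationLoss(probs, lab, lc)
  grads <- ns$netBackward(m, fw$cache, ns$softmaxBackward(sl$grad, probs))
  eps <- 1e-5
  for (nm in names(grads)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      num <- (lossOf(m2) - lossOf(m3)) / (2 * eps)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-6 + 1e-3 * max(abs(num), abs(ana)))
    }
  }
})

test_that("batch normalisation running statistics drive inference mode", {
  ns <- asNamespace("kernelCT")
  cfg <- networkConfig(levels = 2, baseFilters = 4, cbamReduction = 2,
                       seReduction = 2, spatialKernel = 3)
  m <- buildModel(cfg, seed = 8)
  x <- array(runif(16 * 16), c(16, 16, 1))
  fw <- ns$netForward(m, x, training = TRUE)
  expect_false(identical(fw$state, m$state))   # running stats updated
  m$state <- fw$state
  e1 <- ns$netForward(m, x, training = FALSE)
  e2 <- ns$netForward(m, x, training = FALSE)
  expect_identical(e1$logits, e2$logits)       # inference is deterministic
  expect_identical(e1$state, m$state)          # and does not mutate state
})
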