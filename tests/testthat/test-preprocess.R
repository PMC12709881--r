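test_that("clampPixels truncates exactly and is idempotent", {
  expect_equal(clampPixels(300), 255)
  expect_equal(clampPixels(-7), 0)
  expect_equal(clampPixels(128), 128)
  set.seed(1)
  x <- array(runif(4 * 5 * 6, -100, 400), c(4, 5, 6))
  once <- clampPixels(x)
  expect_identical(dim(once), dim(x))
  expect_equal(clampPixels(once), once)
  expect_true(all(once >= 0 & once <= 255))
  expect_error(clampPixels(x, 10, 5), "must not exceed")
})

test_that("percentile stretch is the closed-form linear map and stays in range", {
  # two-level image: p1 and p99 are the two levels, so they map to 0 and 255
  img <- matrix(rep(c(100, 140), each = 50), 10, 10)
  out <- enhanceContrast(img)
  expect_setequal(unique(as.vector(out)), c(0, 255))
  expect_equal(enhanceContrast(matrix(90, 8, 8)), matrix(90, 8, 8))
  set.seed(2)
  r <- matrix(runif(64, 0, 255), 8, 8)
  s <- enhanceContrast(r)
  expect_true(min(s) >= 0 && max(s) <= 255)
  # monotone non-decreasing mapping of intensities
  o <- order(r)
  expect_true(all(diff(s[o]) >= -1e-12))
  expect_error(enhanceContrast(r, method = "sharpen"), "arg")
})

test_that("remapLabels replaces values exactly and preserves class counts", {
  set.seed(3)
  raw <- matrix(sample(c(0, 128, 255), 100, TRUE), 10, 10)
  out <- remapLabels(raw, c("0" = 0, "255" = 1, "128" = 2))
  expect_setequal(unique(as.vector(out)), 0:2)
  expect_equal(sum(out == 1), sum(raw == 255))
  expect_equal(sum(out == 2), sum(raw == 128))
  expect_equal(sum(out == 0), sum(raw == 0))
  expect_identical(remapLabels(matrix(0, 4, 4)), matrix(0L, 4, 4))
  raw[1, 1] <- 17
  expect_error(remapLabels(raw), "unmapped label value.*17")
})

test_that("otsuThreshold separates a bimodal histogram perfectly", {
  set.seed(4)
  lowVals <- rnorm(500, 80, 5)
  highVals <- rnorm(500, 200, 5)
  thr <- otsuThreshold(c(lowVals, highVals))
  # every cut in the empty inter-mode gap maximises the between-class
  # variance; ties break toward the lower cut, which still recovers both
  # classes exactly
  expect_true(all(lowVals <= thr))
  expect_true(all(highVals > thr))
  # the induced partition agrees with the independent EBImage implementation
  v <- c(lowVals, highVals)
  ref <- EBImage::otsu(EBImage::Image(pmin(pmax(v, 0), 255) / 255,
                                      dim = c(50, 20)), range = c(0, 1)) * 255
  expect_identical(v <= thr, v <= ref)
  # overlapping histogram: threshold sits strictly between the modes
  set.seed(5)
  w <- c(rnorm(2000, 90, 25), rnorm(2000, 190, 25))
  thr2 <- otsuThreshold(clampPixels(w))
  expect_gt(thr2, 110)
  expect_lt(thr2, 170)
})

test_that("splitBatchScan recovers the kernels of a synthetic batch scene", {
  specs <- lapply(1:3, function(i)
    phantomSpec(shape = c(24, 40, 40), semiAxesUm = c(9, 15, 13) * 27,
                noiseSd = 4, seed = 100 + i))
  scene <- generateBatchScene(specs, spacingVox = 10)
  crops <- splitBatchScan(scene$ct, expectedKernels = 3)
  expect_length(crops, 3L)
  for (i in 1:3) {
    b <- crops[[i]]@bbox
    centre <- c(mean(b[1:2]), mean(b[3:4]), mean(b[5:6]))
    expect_true(all(abs(centre - scene$truth[[i]]$centroid) <= 2))
  }
  # union of returned boxes covers nearly all ground-truth foreground
  inBox <- 0; total <- 0
  for (i in 1:3) {
    tb <- scene$truth[[i]]$bbox
    total <- total + scene$truth[[i]]$seedCount
    for (crop in crops) {
      cb <- crop@bbox
      if (cb[5] <= tb[5] && cb[6] >= tb[6] && cb[3] <= tb[3] && cb[4] >= tb[4] &&
          cb[1] <= tb[1] && cb[2] >= tb[2])
        inBox <- inBox + scene$truth[[i]]$seedCount
    }
  }
  expect_gte(inBox / total, 0.99)
})

test_that("splitBatchScan ranks components by size and errors when too few", {
  blank <- CTVolume(array(10, c(6, 16, 16)))
  expect_error(splitBatchScan(blank, 1), "found 0")
  specs <- list(
    phantomSpec(shape = c(20, 34, 34), semiAxesUm = c(8, 14, 14) * 27, seed = 1),
    phantomSpec(shape = c(20, 26, 26), semiAxesUm = c(6, 10, 10) * 27, seed = 2),
    phantomSpec(shape = c(20, 42, 42), semiAxesUm = c(9, 17, 17) * 27, seed = 3))
  scene <- generateBatchScene(specs, spacingVox = 8)
  crops <- splitBatchScan(scene$ct, expectedKernels = 2)
  expect_length(crops, 2L)
  # the two largest phantoms (1 and 3) are kept; the small middle one dropped
  counts <- vapply(scene$truth, function(t) t$seedCount, numeric(1))
  keepIdx <- sort(order(counts, decreasing = TRUE)[1:2])
  for (j in seq_along(crops)) {
    centre <- c(mean(crops[[j]]@bbox[1:2]), mean(crops[[j]]@bbox[3:4]),
                mean(crops[[j]]@bbox[5:6]))
    expect_true(all(abs(centre - scene$truth[[keepIdx[j]]]$centroid) <= 2))
  }
})

test_that("standardizeForModel preserves aspect, pads with zeros, scales to [0,1]", {
  sl <- matrix(255, 128, 64)
  out <- standardizeForModel(sl, side = 256)
  expect_identical(dim(out), c(1L, 256L, 256L))
  # 128x64 -> 256x128 content centred in a zero canvas
  expect_true(all(out[1, , 1:64] == 0))
  expect_true(all(out[1, , 193:256] == 0))
  expect_true(all(abs(out[1, , 65:192] - 1) < 1e-9))
  sq <- matrix(128, 256, 256)
  out2 <- standardizeForModel(sq, side = 256)
  expect_equal(out2[1, , ], sq / 255)
  set.seed(5)
  r <- matrix(runif(48 * 80, 0, 255), 48, 80)
  o <- standardizeForModel(r, side = 64)
  expect_true(min(o) >= 0 && max(o) <= 1)
})

test_that("labelComponents3d finds 26-connected components deterministically", {
  m <- array(FALSE, c(4, 8, 8))
  m[1:2, 1:3, 1:3] <- TRUE          # component A (18 voxels)
  m[3:4, 6:8, 6:8] <- TRUE          # component B (18 voxels), diagonal-only
  labs <- labelComponents3d(m)
  expect_equal(max(labs), 2L)
  # equal sizes: tie broken toward smaller centroid x
  expect_equal(unique(as.vector(labs[1:2, 1:3, 1:3])), 1L)
  # diagonal adjacency within and across slices merges into one component
  diag3 <- array(FALSE, c(3, 3, 3))
  diag3[1, 1, 1] <- diag3[2, 2, 2] <- diag3[3, 3, 3] <- TRUE
  expect_equal(max(labelComponents3d(diag3)), 1L)
})
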