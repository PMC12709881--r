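test_that("class masks split directly from labels and by Otsu from grayscale", {
  lab <- array(0L, c(2, 4, 4))
  lab[1, 1:3, 1] <- 1L            # 5 starchy voxels
  lab[1, 1:2, 2] <- 1L
  lab[2, 1:4, 1] <- 2L            # 7 vitreous voxels
  lab[2, 1:3, 2] <- 2L
  masks <- separateClassMasks(LabelVolume(lab))
  expect_equal(sum(masks$vitreous), 7)
  expect_equal(sum(masks$starchy), 5)
  expect_false(any(masks$vitreous & masks$starchy))

  # bimodal grayscale mask with modes 80 and 200: 100% class recovery
  set.seed(41)
  gray <- array(0, c(4, 16, 16))
  trueV <- array(runif(length(gray)) < 0.4, dim(gray))
  trueS <- !trueV & array(runif(length(gray)) < 0.5, dim(gray))
  gray[trueV] <- pmin(pmax(round(rnorm(sum(trueV), 200, 8)), 1), 255)
  gray[trueS] <- pmin(pmax(round(rnorm(sum(trueS), 80, 8)), 1), 255)
  m2 <- separateClassMasks(gray)
  expect_identical(m2$vitreous, trueV)
  expect_identical(m2$starchy, trueS)

  expect_error(separateClassMasks(array(100, c(2, 4, 4))),
               "cannot separate classes")
})

test_that("voxel-counting volumetry equals the triple-loop oracle exactly", {
  expect_equal(computeComponentVolume(array(c(rep(1, 10), rep(0, 22)),
                                            c(8, 2, 2)), 27),
               10 * 27^3)
  expect_equal(computeComponentVolume(array(0, c(4, 4, 4)), 27), 0)
  expect_error(computeComponentVolume(array(1, c(2, 2, 2)), -27), "> 0")
  set.seed(42)
  for (i in 1:5) {
    mask <- array(runif(16^3) < 0.3, c(16, 16, 16))
    expect_equal(computeComponentVolume(mask, 27), bfVoxelCount(mask) * 27^3)
  }
})

test_that("digitised ellipsoid volume is within 2% of (4/3) pi a b c", {
  ax <- c(40, 30, 20)
  spec <- phantomSpec(shape = c(84, 64, 44), semiAxesUm = c(ax[1], ax[2], ax[3]) * 27,
                      noiseSd = 0, blurSigma = 0)
  ph <- generateKernelPhantom(spec)
  # noiseless, unblurred: every voxel brighter than background is seed
  seedMask <- voxelData(ph$ct) > spec@intensityBg
  count <- sum(seedMask)
  vol <- computeComponentVolume(seedMask, 27)
  analytic <- 4 / 3 * pi * prod(ax) * 27^3
  expect_lt(abs(vol - analytic) / analytic, 0.02)
  expect_equal(vol, count * 27^3)
})

test_that("bounding-box dimensions are sorted extents in micrometres", {
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(unname(boundingBoxDims(single, 27)), c(27, 27, 27))
  box <- array(FALSE, c(12, 8, 6))
  box[2:11, 2:6, 2:4] <- TRUE     # 10 x 5 x 3 voxels
  expect_equal(boundingBoxDims(box, 27),
               c(length = 270, width = 135, thickness = 81))
  set.seed(43)
  for (i in 1:5) {
    m <- array(runif(6^3) < 0.3, c(6, 6, 6))
    if (!any(m)) next
    d <- boundingBoxDims(m, 27)
    expect_true(d[1] >= d[2] && d[2] >= d[3] && d[3] > 0)
  }
  expect_error(boundingBoxDims(array(FALSE, c(2, 2, 2))), "empty mask")
})

test_that("extractKernelMask recovers the phantom seed within 2%", {
  spec <- phantomSpec(shape = c(40, 56, 48), semiAxesUm = c(16, 24, 20) * 27,
                      seed = 44)
  ph <- generateKernelPhantom(spec)
  mask <- extractKernelMask(ph$ct)
  expect_lt(abs(sum(mask) - ph$truth$seedCount) / ph$truth$seedCount, 0.02)
  # the seed mask contains the endosperm classes
  lab <- voxelData(ph$labels)
  expect_gte(mean(mask[lab > 0]), 0.999)
  expect_error(extractKernelMask(CTVolume(array(10, c(4, 8, 8)))),
               "no foreground")
})

test_that("phenotype records match generator truth and keep their invariants", {
  spec <- phantomSpec(shape = c(40, 56, 48), semiAxesUm = c(16, 24, 20) * 27,
                      seed = 45)
  ph <- generateKernelPhantom(spec)
  rec <- computePhenotypes(ph$ct, ph$labels, kernelId = "ph1", group = "TST")
  expect_equal(rec$VV, ph$truth$vitreousCount * 27^3)   # exact from labels
  expect_equal(rec$SV, ph$truth$starchyCount * 27^3)
  expect_gte(rec$V, rec$VV + rec$SV)
  expect_lte(rec$VV_over_V + rec$SV_over_V, 1)
  expect_true(rec$length >= rec$width && rec$width >= rec$thickness)
  # analytic ratios: scaled-ellipsoid volume fractions of the seed
  expect_equal(rec$VV_over_V, spec@shellFraction^3 - spec@coreFraction^3,
               tolerance = 0.02)
  expect_equal(rec$SV_over_V, spec@coreFraction^3, tolerance = 0.02)

  # all-background labels with a non-empty seed: zero volumes and ratios
  empty <- LabelVolume(array(0L, dim(ph$ct)))
  rec0 <- computePhenotypes(ph$ct, empty, "ph0")
  expect_equal(rec0$VV, 0)
  expect_equal(rec0$SV, 0)
  expect_equal(rec0$VV_over_V + rec0$SV_over_V, 0)
})

test_that("volume is additive over disjoint masks", {
  set.seed(46)
  a <- array(runif(8^3) < 0.3, c(8, 8, 8))
  b <- array(runif(8^3) < 0.3, c(8, 8, 8)) & !a
  expect_equal(computeComponentVolume(a | b, 27),
               computeComponentVolume(a, 27) + computeComponentVolume(b, 27))
})

test_that("group aggregation reproduces box-plot summary statistics", {
  rec <- do.call(rbind, lapply(1:3, function(i)
    data.frame(kernel_id = paste0("k", i), V = 1000, VV = i * 100, SV = 50,
               VV_over_V = i * 0.1, SV_over_V = 0.05, length = 1, width = 1,
               thickness = 1, group = "SS")))
  agg <- aggregateByGroup(rec)
  vv <- agg[agg$variable == "VV", ]
  expect_equal(vv$mean, 200)
  expect_equal(vv$median, 200)
  expect_equal(vv$n, 3L)
  single <- aggregateByGroup(rec[1, ])
  expect_true(all(single$sd == 0))
  expect_true(all(single$n == 1L))
  rec2 <- rec; rec2$group <- c("SS", "NSS", "NSS")
  agg2 <- aggregateByGroup(rec2)
  expect_equal(sum(agg2$n[agg2$variable == "VV"]), nrow(rec2))
  expect_error(aggregateByGroup(rec[0, ]), "no phenotype records")
})
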