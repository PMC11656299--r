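# Full-reference and physical image quality metrics.

test_that("SSIM closed forms, symmetry and oracle agreement hold", {
  set.seed(1)
  x <- matrix(rnorm(64 * 64, 0, 200), 64)
  expect_identical(ssim(x, x, 2000), 1)

  # zero-variance case: constant images a, b
  a <- matrix(100, 32, 32); b <- matrix(200, 32, 32)
  C1 <- (0.01 * 2000)^2
  expect_equal(ssim(a, b, 2000), (2 * 100 * 200 + C1) / (100^2 + 200^2 + C1),
               tolerance = 1e-12)

  # symmetry
  for (i in 1:20) {
    p <- matrix(rnorm(32 * 32, 0, 100), 32)
    q <- p + matrix(rnorm(32 * 32, 0, 40), 32)
    expect_lt(abs(ssim(p, q, 2000) - ssim(q, p, 2000)), 1e-12)
  }

  # checkerboard vs inverted checkerboard: negative, matches the reference
  cb <- 1000 * outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  inv <- 1000 - cb
  sOurs <- ssim(cb, inv, 1000)
  expect_lt(sOurs, 0)
  f1 <- writeMatrixTxt(cb, tempfile()); f2 <- writeMatrixTxt(inv, tempfile())
  expect_equal(sOurs, pythonOracle("oracle-ssim.py", c(f1, f2, "1000")),
               tolerance = 1e-6)

  # 10 random pairs against the reference implementation
  set.seed(2)
  for (i in 1:10) {
    p <- matrix(rnorm(48 * 48, 0, 300), 48)
    q <- p + matrix(rnorm(48 * 48, 0, 20 * i), 48)
    f1 <- writeMatrixTxt(p, tempfile()); f2 <- writeMatrixTxt(q, tempfile())
    expect_equal(ssim(q, p, 2000),
                 pythonOracle("oracle-ssim.py", c(f2, f1, "2000")),
                 tolerance = 1e-6)
  }

  expect_error(ssim(matrix(0, 3, 3), matrix(0, 4, 4)), "dimensions")
  expect_error(ssim(x, x, dataRange = 0), "dataRange")
})

test_that("PSNR closed forms and monotonicity hold", {
  ref <- matrix(0, 32, 32)
  expect_equal(psnr(ref + 20, ref, 2000), 40)           # 20*log10(2000/20)
  expect_equal(psnr(ref + 2000, ref, 2000), 0)          # MSE = L^2
  expect_error(psnr(ref, ref, 2000), class = "identicalImagesError")

  set.seed(3)
  base <- matrix(rnorm(64 * 64, 0, 100), 64)
  vals <- vapply(c(5, 10, 20, 40), function(s)
    psnr(base + matrix(rnorm(64 * 64, 0, s), 64), base, 2000), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("RMSE behaves on masks, boxes and offsets", {
  ref <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  expect_identical(rmseHU(ref, ref), 0)
  expect_equal(rmseHU(ref + 10, ref), 10)
  fullBox <- c(0L, 16L, 0L, 16L, 0L, 2L)
  expect_equal(rmseHU(ref + 3, ref, fullBox), rmseHU(ref + 3, ref))
  expect_error(rmseHU(ref, ref, array(FALSE, dim = dim(ref))), "empty")
  # PSNR-RMSE consistency on one selection
  expect_equal(psnr(ref + 7, ref, 2000),
               20 * log10(2000) - 20 * log10(rmseHU(ref + 7, ref)))
})

test_that("VIF equals 1 on identity, decreases with noise, matches oracle", {
  set.seed(4)
  x <- matrix(rnorm(96 * 96, 50, 250), 96)
  expect_equal(vif(x, x), 1, tolerance = 1e-6)

  vals <- vapply(c(5, 10, 20, 40), function(s)
    vif(x + matrix(rnorm(96 * 96, 0, s), 96), x), numeric(1))
  expect_true(all(diff(vals) < 0))

  for (i in 1:10) {
    p <- matrix(rnorm(80 * 80, 0, 300), 80)
    q <- p + matrix(rnorm(80 * 80, 0, 15 * i), 80)
    f1 <- writeMatrixTxt(p, tempfile()); f2 <- writeMatrixTxt(q, tempfile())
    expect_equal(vif(q, p), pythonOracle("oracle-vif.py", c(f1, f2)),
                 tolerance = 1e-4)
  }

  expect_error(vif(x, matrix(5, 96, 96)), class = "zeroVarianceError")
})

test_that("VIF penalizes blur-then-noise more than noise alone", {
  set.seed(5)
  kern <- CTDenoiseBench:::.gaussKernel1d(2)
  ref <- CTDenoiseBench:::.sepFilter2(matrix(rnorm(96 * 96, 0, 300), 96),
                                      CTDenoiseBench:::.gaussKernel1d(1.2))
  blurred <- CTDenoiseBench:::.sepFilter2(ref, kern)
  distA <- blurred + matrix(rnorm(96 * 96, 0, 30), 96)
  mseA <- mean((distA - ref)^2)
  # noise-only distortion at matched MSE
  nz <- matrix(rnorm(96 * 96), 96)
  distB <- ref + nz * sqrt(mseA / mean(nz^2))
  expect_equal(mean((distB - ref)^2), mseA, tolerance = 1e-10)
  expect_lt(vif(distA, ref), vif(distB, ref))
})

test_that("CNR follows its definition and contrast equivariance", {
  img <- matrix(0, 64, 64)
  roiS <- circularROI(0L, c(20, 20), 5)
  roiB <- circularROI(0L, c(44, 44), 5)
  nB <- length(CTDenoiseBench:::.roiValues(array(img, c(64, 64, 1)), roiB))
  # background with sample mean exactly 30 and sample sd exactly 10:
  # k symmetric pairs 30 +/- c0 (plus a neutral 30 if the count is odd)
  k <- nB %/% 2
  c0 <- 10 * sqrt((nB - 1) / (2 * k))
  bvals <- c(rep(c(30 - c0, 30 + c0), k), rep(30, nB %% 2))
  arr <- array(img, c(64, 64, 1))
  ix <- matrix(seq_len(64) - 1, 64, 64); iy <- t(ix)
  sMask <- (ix - 20)^2 + (iy - 20)^2 <= 25
  bMask <- (ix - 44)^2 + (iy - 44)^2 <= 25
  sl <- arr[, , 1]; sl[sMask] <- 50; sl[bMask] <- bvals; arr[, , 1] <- sl
  expect_equal(cnr(arr, roiS, roiB), 2, tolerance = 1e-9)
  # CNR = |mu_s - mu_b| / sd_b: a global HU rescale cancels, while doubling
  # the signal-background contrast at fixed background doubles it
  expect_equal(cnr(arr * 2, roiS, roiB), 2, tolerance = 1e-9)
  arr2 <- arr; sl2 <- arr2[, , 1]; sl2[sMask] <- 70; arr2[, , 1] <- sl2
  expect_equal(cnr(arr2, roiS, roiB), 4, tolerance = 1e-9)

  # null case: identical homogeneous ROIs with noise
  set.seed(6)
  nzimg <- array(matrix(rnorm(64 * 64, 100, 10), 64), c(64, 64, 1))
  expect_lt(cnr(nzimg, roiS, roiB), 3 / sqrt(nB))

  expect_error(cnr(arr, roiS, circularROI(0L, c(22, 22), 5)), "disjoint")
  expect_error(cnr(arr, roiS, circularROI(0L, c(62, 62), 5)), "bounds")
})

test_that("CT-number deviations are per-ROI absolute mean differences", {
  set.seed(7)
  ref <- array(rnorm(32 * 32 * 2, 50, 20), c(32, 32, 2))
  rois <- list(circularROI(0L, c(10, 10), 4), circularROI(1L, c(20, 20), 5))
  expect_equal(ctNumberDeviation(ref, ref, rois), c(0, 0))
  expect_equal(ctNumberDeviation(ref + 5, ref, rois), c(5, 5))
  expect_equal(ctNumberDeviation(ref + 5, ref, rev(rois)),
               rev(ctNumberDeviation(ref + 5, ref, rois)))
  expect_error(ctNumberDeviation(ref, ref, list()), "at least one")
})

test_that("line profiles interpolate bilinearly", {
  const <- matrix(42, 16, 16)
  seg <- lineSegment(c(1, 1), c(14, 14), 10L)
  expect_equal(lineProfile(const, seg), rep(42, 10))

  two <- matrix(0, 4, 4); two[3, ] <- 100  # voxels x=1 (0-based) 0, x=2: 100
  mid <- lineProfile(two, lineSegment(c(1.5, 1), c(1.5, 2), 2L))
  expect_equal(mid, c(50, 50))

  step <- matrix(rep(c(0, 100), each = 4 * 8), 8)   # 8x8 step edge
  prof <- lineProfile(step, lineSegment(c(0, 3.5), c(7, 3.5), 50L))
  expect_true(all(prof >= 0 & prof <= 100))

  expect_error(lineProfile(const, lineSegment(c(-1, 0), c(2, 2))), "inside")
})

test_that("lesion metrics restrict RMSE/PSNR to bounding boxes", {
  pair <- cachedPair("abdomen", 1L)
  hd <- highDose(pair)
  expect_error(lesionMetrics(hd, hd, lesionBoxes(pair)),
               class = "identicalImagesError")
  expect_identical(rmseHU(hd, hd, lesionBoxes(pair)[[1]]$box), 0)

  off <- hd; off@hu <- off@hu + 12
  lm <- lesionMetrics(off, hd, lesionBoxes(pair))
  expect_equal(lm$rmse, rep(12, nrow(lm)))
  expect_true(all(is.finite(lm$psnr)))

  # aggregation: mean over lesions equals mean of per-lesion values
  boxes <- list(list(box = c(10L, 20L, 10L, 20L, 0L, 1L), label = "a"),
                list(box = c(30L, 40L, 30L, 40L, 0L, 1L), label = "b"))
  lm2 <- lesionMetrics(off, hd, boxes)
  expect_equal(mean(lm2$rmse), mean(c(lm2$rmse[1], lm2$rmse[2])))
})
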