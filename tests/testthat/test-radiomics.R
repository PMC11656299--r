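# Radiomic feature extraction and the radiomic feature similarity.

# brute-force co-occurrence counter used as the enumeration oracle
bruteGLCM <- function(arrD, offset, Ng) {
  d <- dim(arrD)
  P <- matrix(0, Ng, Ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    i2 <- i + offset[1]; j2 <- j + offset[2]; k2 <- k + offset[3]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3])
      next
    a <- arrD[i, j, k]; b <- arrD[i2, j2, k2]
    if (is.na(a) || is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

normFM <- function(values) {
  fm <- new("FeatureMatrix", values = values, scanId = "s",
            normalized = FALSE, droppedFeatures = character(),
            extractionConfig = list())
  normalizeFeatures(fm)
}

test_that("first-order features match hand computations", {
  const <- array(37, c(3, 3, 1))
  f <- extractFeatures(const, array(TRUE, c(3, 3, 1)))
  expect_equal(unname(f["fo_Mean"]), 37)
  expect_equal(unname(f["fo_Variance"]), 0)
  expect_equal(unname(f["fo_Skewness"]), 0)   # defined as 0 for flat regions

  sq <- array(c(1, 3, 2, 4), c(2, 2, 1))     # values {1,2,3,4}
  f2 <- extractFeatures(sq, array(TRUE, c(2, 2, 1)))
  expect_equal(unname(f2["fo_Energy"]), 30)  # 1 + 4 + 9 + 16
  expect_equal(unname(f2["fo_Mean"]), 2.5)
  expect_equal(unname(f2["fo_Range"]), 3)
})

test_that("GLCM of a strict checkerboard matches the enumeration oracle", {
  cb <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) * 25)
  arr <- array(cb, c(6, 6, 1))
  mask <- array(TRUE, c(6, 6, 1))
  arrD <- array(NA_integer_, dim = dim(arr))
  arrD[mask] <- CTDenoiseBench:::.discretize(arr[mask], 25)
  P <- CTDenoiseBench:::.glcmMatrix(arrD, c(1L, 0L, 0L), 2L)
  expect_identical(P, bruteGLCM(arrD, c(1L, 0L, 0L), 2L))
  # all horizontal neighbours differ by one bin: contrast is maximal (1)
  p <- P / sum(P)
  expect_identical(sum(p * (outer(1:2, 1:2, "-")^2)), 1)
  expect_identical(diag(P), c(0, 0))

  # random masked volumes against the oracle, all 13 directions
  set.seed(8)
  for (rep in 1:3) {
    vol <- array(sample(0:100, 5 * 4 * 3, TRUE), c(5, 4, 3))
    msk <- array(runif(60) > 0.3, c(5, 4, 3))
    msk[1, 1, 1] <- TRUE
    aD <- array(NA_integer_, dim = dim(vol))
    aD[msk] <- CTDenoiseBench:::.discretize(vol[msk], 25)
    Ng <- max(aD, na.rm = TRUE)
    for (r in seq_len(nrow(CTDenoiseBench:::.DIRECTIONS13))) {
      off <- CTDenoiseBench:::.DIRECTIONS13[r, ]
      expect_identical(CTDenoiseBench:::.glcmMatrix(aD, off, Ng),
                       bruteGLCM(aD, off, Ng))
    }
  }
})

test_that("run-length counts agree with a direct rle oracle on rows", {
  v <- c(1, 1, 2, 2, 2, 1)
  arr <- array(rep(v, 2), c(6, 2, 1))
  aD <- array(as.integer(arr), dim = dim(arr))
  P <- CTDenoiseBench:::.glrlmMatrix(aD, c(1L, 0L, 0L), 2L, 6L)
  # each column: runs 1x2, 2x3, 1x1 -> two columns
  expect_equal(P[1, 1], 2)  # two single-voxel runs of level 1
  expect_equal(P[1, 2], 2)  # two length-2 runs of level 1
  expect_equal(P[2, 3], 2)  # two length-3 runs of level 2
  expect_equal(sum(P), 6)
})

test_that("feature count is fixed and masks are honoured", {
  pair <- cachedPair("abdomen", 1L)
  organ <- organMasks(pair)$liver
  f <- extractFeatures(highDose(pair), organ)
  expect_length(f, 37L)
  expect_true(all(is.finite(f)))
  expect_error(extractFeatures(highDose(pair),
                               array(FALSE, dim(huData(highDose(pair))))),
               "empty")
})

test_that("min-max normalization maps endpoints to 0 and -1 and drops
           degenerate features", {
  vals <- rbind(HD = c(a = 2, b = 0, c = 5), A1 = c(1, 4, 5), A2 = c(3, 2, 5))
  fm <- normFM(vals)
  R <- featureValues(fm)
  expect_equal(unname(R[, "a"]), c(-0.5, -1, 0))   # column [2,1,3]
  expect_equal(max(R), 0)
  expect_equal(min(R), -1)
  expect_false("c" %in% colnames(R))               # constant column dropped
  expect_true("c" %in% fm@droppedFeatures)

  # all-degenerate input is rejected
  allc <- rbind(HD = c(a = 5), A1 = 5)
  expect_error(normFM(allc), "degenerate")

  # conventional variant maps to [0, 1]
  fm2 <- normalizeFeatures(new("FeatureMatrix", values = vals, scanId = "s",
                               normalized = FALSE,
                               droppedFeatures = character(),
                               extractionConfig = list()),
                           variant = "min-subtract")
  expect_equal(range(featureValues(fm2)), c(0, 1))
})

test_that("RFS reproduces the worked example and basic identities", {
  vals <- rbind(HD = c(f1 = 2, f2 = 0), A1 = c(1, 4), A2 = c(3, 2))
  out <- rfs(normFM(vals))
  expect_equal(out$rfs, c(0.4472, 0.8944), tolerance = 5e-5)

  # algorithm identical to the high-dose row (A2 must not attain every
  # feature maximum, or its normalized row would be the zero vector)
  v2 <- rbind(HD = c(f1 = 2, f2 = 0), A1 = c(2, 0), A2 = c(3, -1))
  out2 <- rfs(normFM(v2))
  expect_equal(out2$rfs[out2$algorithm == "A1"], 1, tolerance = 1e-12)

  # orthogonal normalized rows
  fmOrtho <- new("FeatureMatrix",
                 values = rbind(HD = c(0, -1), A1 = c(-1, 0)),
                 scanId = "s", normalized = TRUE,
                 droppedFeatures = character(), extractionConfig = list())
  expect_equal(rfs(fmOrtho)$rfs, 0)

  # zero-norm row rejected
  fmZero <- new("FeatureMatrix",
                values = rbind(HD = c(0, -1), A1 = c(0, 0)),
                scanId = "s", normalized = TRUE,
                droppedFeatures = character(), extractionConfig = list())
  expect_error(rfs(fmZero), class = "zeroNormRowError")
})

test_that("RFS is invariant to per-feature affine maps and feature order", {
  set.seed(9)
  done <- 0L
  while (done < 100L) {
    J <- sample(3:8, 1); n <- sample(2:5, 1)
    vals <- matrix(rnorm(n * J), n, J,
                   dimnames = list(c("HD", paste0("A", seq_len(n - 1))),
                                   paste0("f", seq_len(J))))
    # a row attaining every feature maximum has an all-zero normalized row;
    # RFS is undefined there by design, so only admissible draws are used
    base <- tryCatch(rfs(normFM(vals))$rfs, error = function(e) NULL)
    if (is.null(base)) next
    done <- done + 1L
    # positive rescale + shift of one feature applied to ALL algorithms
    j <- sample(J, 1)
    valsT <- vals
    valsT[, j] <- valsT[, j] * runif(1, 0.1, 10) + rnorm(1, 0, 5)
    expect_equal(rfs(normFM(valsT))$rfs, base, tolerance = 1e-9)
    # feature permutation
    perm <- sample(J)
    expect_equal(rfs(normFM(vals[, perm, drop = FALSE]))$rfs, base,
                 tolerance = 1e-12)
  }
})

test_that("for one algorithm RFS never reaches 1 unless rows coincide", {
  set.seed(10)
  # identical rows leave no non-degenerate feature: rejected, not RFS = 1
  hd <- rnorm(4)
  valsEq <- rbind(HD = hd, A1 = hd)
  colnames(valsEq) <- paste0("f", 1:4)
  expect_error(normFM(valsEq), "degenerate")

  for (rep in 1:50) {
    J <- sample(3:6, 1)
    hd <- rnorm(J)
    a1 <- hd + rnorm(J, 0, 0.5)
    vals <- rbind(HD = hd, A1 = a1)
    colnames(vals) <- paste0("f", seq_len(J))
    out <- tryCatch(rfs(normFM(vals))$rfs, error = function(e) NULL)
    if (is.null(out)) next   # zero-norm draw, undefined by design
    expect_lt(out, 1 - 1e-12)
  }
})

test_that("RFS summaries aggregate scans within seeds, then seeds", {
  rec <- data.frame(
    algorithm = "A", examType = "abdomen",
    seed = rep(c("s0", "s1"), each = 3),
    scanId = rep(c("p1", "p2", "p3"), 2),
    rfs = c(0.8, 0.9, 1.0, 0.7, 0.8, 0.9))
  out <- rfsSummary(rec)
  expect_equal(out$mean, mean(c(0.9, 0.8)))
  expect_equal(out$sd, sd(c(0.9, 0.8)))
  expect_false(out$singleSeed)

  single <- rfsSummary(rec[rec$seed == "s0", ])
  expect_equal(single$mean, 0.9)
  expect_equal(single$sd, 0)
  expect_true(single$singleSeed)

  eq <- rec; eq$rfs <- rep(c(0.8, 0.9, 1.0), 2)
  expect_equal(rfsSummary(eq)$sd, 0)
})
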