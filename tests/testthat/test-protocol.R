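# Dataset splitting, sampling, slice filtering, statistics and ranking.

fakeManifest <- function(nPerType = 50L, nSlices = 10L) {
  do.call(rbind, lapply(c("abdomen", "head", "chest"), function(et)
    data.frame(scanId = sprintf("%s-%02d", et, seq_len(nPerType)),
               patientId = sprintf("%s-%02d", et, seq_len(nPerType)),
               examType = et, nSlices = nSlices)))
}

# independent enumeration oracle: counts (a > b) pairs over all subsets
bruteMW <- function(a, b, alternative) {
  n <- length(a); m <- length(b)
  Ustat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  U <- Ustat(a, b)
  pooled <- c(a, b)
  idx <- combn(n + m, n)
  Us <- apply(idx, 2, function(ii) Ustat(pooled[ii], pooled[-ii]))
  switch(alternative,
         less = mean(Us <= U),
         greater = mean(Us >= U),
         two.sided = min(1, 2 * min(mean(Us <= U), mean(Us >= U))))
}

bruteWilcoxon <- function(d, alternative) {
  d <- d[d != 0]
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  Vs <- as.numeric(signs %*% r)
  switch(alternative,
         greater = mean(Vs >= V),
         less = mean(Vs <= V),
         two.sided = min(1, 2 * min(mean(Vs <= V), mean(Vs >= V))))
}

test_that("patient splits follow 70/20/10 with largest-remainder rounding", {
  man <- fakeManifest(50L)
  sp <- splitDataset(man, seed = 1L)
  for (et in c("abdomen", "head", "chest")) {
    parts <- sp$byExamType[[et]]
    expect_length(parts$train, 35L)
    expect_length(parts$validation, 10L)
    expect_length(parts$test, 5L)
    all50 <- c(parts$train, parts$validation, parts$test)
    expect_setequal(all50, man$patientId[man$examType == et])
    expect_identical(anyDuplicated(all50), 0L)
  }
  expect_identical(splitDataset(man, seed = 1L), sp)
  expect_false(identical(splitDataset(man, seed = 2L), sp))
  expect_error(splitDataset(fakeManifest(2L), 1L), "fewer than 3")
})

test_that("sampling weights equalize exam types and patients", {
  man <- rbind(
    data.frame(scanId = c("a1", "a2"), patientId = c("a1", "a2"),
               examType = "abdomen", nSlices = c(10L, 30L)),
    data.frame(scanId = "h1", patientId = "h1", examType = "head",
               nSlices = 20L))
  w <- samplingWeights(man)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  # exam marginal 1/2 each; patients within abdomen 1/4 each
  byExam <- tapply(w$weight, w$examType, sum)
  expect_equal(as.numeric(byExam), c(0.5, 0.5))
  byPat <- tapply(w$weight, w$patientId, sum)
  expect_equal(as.numeric(byPat[c("a1", "a2")]), c(0.25, 0.25))

  # empirical draws: patients with 10 vs 30 slices drawn equally often
  set.seed(15)
  nDraw <- 2e4
  draws <- sample(seq_len(nrow(w)), nDraw, replace = TRUE, prob = w$weight)
  pA1 <- mean(w$patientId[draws] == "a1")
  se <- sqrt(0.25 * 0.75 / nDraw)
  expect_lt(abs(pA1 - 0.25), 3 * se)

  expect_error(samplingWeights(man[0, ]), "empty")
  manZero <- man; manZero$nSlices[1] <- 0L
  expect_error(samplingWeights(manZero), "zero slices")
})

test_that("test-slice filtering follows organ presence rules", {
  mk <- function(slices, nz = 8L) {
    m <- array(FALSE, c(4, 4, nz))
    m[2, 2, slices] <- TRUE
    m
  }
  vol <- new("CTVolume", hu = array(0, c(4, 4, 8)), voxelSpacing = c(1, 1),
             examType = "head", patientId = "p", doseTag = "high")
  expect_identical(filterTestSlices(vol, list(brain = mk(4:8))), 3:7)

  volC <- vol; volC@examType <- "chest"
  expect_identical(filterTestSlices(volC, list(lung = mk(1:2))), 0:1)
  expect_warning(out <- filterTestSlices(volC, list(lung = mk(integer()))),
                 "no evaluable")
  expect_length(out, 0L)

  volA <- vol; volA@examType <- "abdomen"
  expect_identical(filterTestSlices(volA, list()), 0:7)       # no lung mask
  expect_identical(filterTestSlices(volA, list(lung = mk(1:3))), 3:7)

  expect_error(filterTestSlices(vol, list(lung = mk(1))), "missing required")
})

test_that("method evaluation aggregates slices, scans and seeds", {
  hu <- array(rep(c(0, 50), each = 8 * 8), c(8, 8, 2))
  mkVol <- function(hu, tag) new("CTVolume", hu = hu,
                                 voxelSpacing = c(1, 1),
                                 examType = "abdomen", patientId = "p1",
                                 doseTag = tag)
  pair <- new("ScanPair", high = mkVol(hu, "high"),
              low = mkVol(hu + 4, "low"), organMasks = list(),
              lesionBoxes = list(), seed = 0L)
  # fake denoiser: adds a per-seed constant offset
  spec <- denoiserSpec("offset", 2020L,
    fitFun = function(tp, hp, seed) list(method = "offset", delta = seed),
    applyFun = function(state, v) { v@hu <- v@hu + state$delta; v })
  states <- list(seed0 = list(method = "offset", delta = 1),
                 seed1 = list(method = "offset", delta = 3))
  tab <- evaluateMethod(spec, states, list(pair), metricList = "RMSE")
  # seed0: volume offset 4+1=5 -> RMSE 5; seed1: offset 7
  expect_equal(tab$mean, mean(c(5, 7)))
  expect_equal(tab$sd, sd(c(5, 7)))
  expect_identical(tab$year, 2020L)

  # deterministic method: zero spread
  idSpec <- getDenoiser("identity")
  tabId <- evaluateMethod(idSpec, list(seed0 = list(method = "identity"),
                                       seed1 = list(method = "identity")),
                          list(pair), metricList = "RMSE")
  expect_identical(tabId$sd, 0)
  expect_equal(tabId$mean, 4)

  ps <- attr(tab, "perSlice")
  expect_equal(nrow(ps), 2 * 2)   # 2 seeds x 2 slices
})

test_that("Mann-Whitney p-values match enumeration and stats::wilcox.test", {
  out <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6), "less")
  expect_identical(out$p, 0.05)   # 1 / C(6,3)
  expect_true(out$exact)

  # identical samples up to permutation
  same <- mannWhitneyU(c(1, 2, 3), c(3, 1, 2), "two.sided")
  expect_gte(same$p, 0.99)
  const <- mannWhitneyU(c(2, 2), c(2, 2))
  expect_identical(const$p, 1)
  expect_true(const$degenerate)

  set.seed(16)
  # exhaustive small instances incl. ties vs the independent oracle
  for (rep in 1:40) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    vals <- sample(1:6, n + m, replace = TRUE)   # forces ties
    a <- vals[seq_len(n)]; b <- vals[-seq_len(n)]
    for (alt in c("less", "greater", "two.sided")) {
      expect_equal(mannWhitneyU(a, b, alt)$p, bruteMW(a, b, alt),
                   info = paste(alt, paste(a, collapse = ","),
                                paste(b, collapse = ",")))
    }
  }
  # tie-free cases agree with stats::wilcox.test exact p
  for (rep in 1:10) {
    a <- sample(1:100, 5); b <- sample(101:200, 4) - 50
    if (length(intersect(a, b))) next
    expect_equal(mannWhitneyU(a, b, "two.sided")$p,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # large samples: normal approximation equals wilcox.test's approximation
  set.seed(17)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  expect_equal(mannWhitneyU(a, b, "two.sided")$p,
               wilcox.test(a, b, correct = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("Wilcoxon signed-rank matches sign enumeration", {
  out <- wilcoxonSignedRank(c(1, 2, 3, 4, 5), c(0, 1, 2, 3, 4), "greater")
  expect_identical(out$p, 1 / 2^5)

  same <- wilcoxonSignedRank(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_identical(same$p, 1)
  expect_true(same$degenerate)

  set.seed(18)
  for (rep in 1:25) {
    d <- sample(c(-3:-1, 1:3), 8, replace = TRUE)
    for (alt in c("less", "greater", "two.sided"))
      expect_equal(wilcoxonSignedRank(d, NULL, alt)$p, bruteWilcoxon(d, alt))
  }
  expect_error(wilcoxonSignedRank(1:3, 4:6), "length")
})

test_that("significance marks compare against the previously published best", {
  mkSeeds <- function(method, et, metric, vals)
    data.frame(method = method, seed = paste0("s", seq_along(vals)),
               examType = et, metric = metric, value = vals)
  perSeed <- rbind(
    mkSeeds("LD", "abdomen", "SSIM", rep(0.5, 5)),
    mkSeeds("old", "abdomen", "SSIM", c(0.70, 0.71, 0.72, 0.69, 0.70)),
    mkSeeds("old2", "abdomen", "SSIM", c(0.60, 0.61, 0.62, 0.59, 0.60)),
    mkSeeds("new", "abdomen", "SSIM", c(0.80, 0.81, 0.82, 0.79, 0.80)),
    mkSeeds("worse", "abdomen", "SSIM", c(0.20, 0.21, 0.22, 0.19, 0.20)))
  years <- c(old = 2017, old2 = 2017, new = 2019, worse = 2019)
  marks <- significanceMarks(perSeed, years, alpha = 0.05)
  getMark <- function(m) marks$mark[marks$method == m]
  getComp <- function(m) marks$comparator[marks$method == m]
  expect_identical(getMark("new"), "better")
  expect_identical(getComp("new"), "old")     # best of the 2017 methods
  expect_identical(getMark("worse"), "worse")
  expect_identical(getMark("old"), "better")  # earliest year -> vs LD

  # identical samples vs the LD baseline: no mark
  perSeed2 <- rbind(mkSeeds("LD", "head", "SSIM", rep(0.5, 5)),
                    mkSeeds("only", "head", "SSIM", rep(0.5, 5)))
  m2 <- significanceMarks(perSeed2, c(only = 2018))
  expect_identical(m2$mark, "none")

  # permutation of seed order leaves marks unchanged (align rows by method)
  shuf <- perSeed[sample(nrow(perSeed)), ]
  marksShuf <- significanceMarks(shuf, years)
  key <- function(m) paste(m$method, m$examType, m$metric)
  expect_identical(marksShuf$mark[match(key(marks), key(marksShuf))],
                   marks$mark)
  expect_error(significanceMarks(perSeed, years[-1]), "year missing")
})

test_that("competition ranking skips ranks after ties", {
  out <- competitionRanks(c(3, 5, 5, 9))
  expect_identical(out$rank, c(1L, 2L, 2L, 4L))
  expect_identical(out$tied, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(competitionRanks(7)$rank, 1L)

  tab <- expand.grid(method = c("A", "B", "C"), examType = c("e1", "e2"),
                     metric = "SSIM", stringsAsFactors = FALSE)
  tab$mean <- c(0.9, 0.8, 0.7, 0.95, 0.85, 0.75)
  rk <- competitionRank(tab)
  expect_identical(rk$rank[rk$method == "A"], 1L)
  expect_identical(rk$rank[rk$method == "C"], 3L)

  # strictly monotone transform of one metric leaves ranks unchanged
  tab2 <- tab; tab2$mean <- exp(5 * tab2$mean)
  expect_identical(competitionRank(tab2)$rank, rk$rank)

  # adding a dominated method preserves relative order
  tab3 <- rbind(tab, data.frame(method = "D", examType = c("e1", "e2"),
                                metric = "SSIM", mean = c(0.1, 0.1)))
  rk3 <- competitionRank(tab3)
  expect_identical(rk3$rank[match(c("A", "B", "C"), rk3$method)], 1:3)

  expect_error(competitionRank(tab[-1, ]), "incomplete")

  # lower-is-better metrics rank in reverse
  tabR <- tab; tabR$metric <- "RMSE"
  rkR <- competitionRank(tabR)
  expect_identical(rkR$rank[rkR$method == "C"], 1L)
})

test_that("hard subsets select the lowest method-averaged SSIM slices", {
  grid <- expand.grid(method = c("m1", "m2"), sliceIndex = 0:9,
                      stringsAsFactors = FALSE)
  grid$examType <- "abdomen"
  grid$scanId <- "s1"
  base <- (grid$sliceIndex + 1) / 10
  grid$value <- ifelse(grid$method == "m1", base - 0.05, base + 0.05)

  sub <- ldctHardSubset(grid, 20)
  expect_identical(sub$slices$abdomen$sliceIndex, c(0L, 1L))
  expect_identical(nrow(ldctHardSubset(grid, 100)$slices$abdomen), 10L)

  # nesting over q
  qs <- c(10, 30, 60, 100)
  subs <- lapply(qs, function(q) ldctHardSubset(grid, q)$slices$abdomen)
  for (i in seq_len(length(qs) - 1)) {
    key <- function(df) paste(df$scanId, df$sliceIndex)
    expect_true(all(key(subs[[i]]) %in% key(subs[[i + 1]])))
  }

  expect_error(ldctHardSubset(grid[-1, ], 50), "missing method-slice")
  expect_error(ldctHardSubset(grid, 0), "q > 0")
})

test_that("normalization statistics come from the training split only", {
  cfg <- ctSimConfig(imageSize = 64L, nAngles = 96L, voxelSpacing = 3,
                     nSlices = 1L)
  pairs <- lapply(1:4, function(i) simulateCase("abdomen", NULL, i, cfg))
  man <- datasetManifest(pairs)
  sp <- splitDataset(man, 1L, fractions = c(0.5, 0.25, 0.25))
  st <- normalizationStats(pairs, sp)
  expect_identical(st$examType, "abdomen")
  expect_gt(st$sd, 0)
  trainIds <- sp$byExamType$abdomen$train
  manual <- unlist(lapply(pairs, function(pr)
    if (patientId(pr) %in% trainIds) as.numeric(huData(lowDose(pr)))))
  expect_equal(st$mean, mean(manual))
  expect_equal(st$sd, sd(manual))
})
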