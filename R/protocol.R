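# Evaluation protocol: patient-level splits, sampling weights, test-slice
# filtering, metric aggregation over retraining seeds, exact nonparametric
# tests, significance marks against the previously published best method,
# competition ranking, and hard-slice subsets.

#' Build a dataset manifest from simulated pairs
#'
#' @param pairs list of \linkS4class{ScanPair}s.
#' @return data.frame with scanId, patientId, examType, nSlices.
#' @export
datasetManifest <- function(pairs) {
  do.call(rbind, lapply(pairs, function(pr) data.frame(
    scanId = patientId(pr), patientId = patientId(pr),
    examType = examType(pr), nSlices = dim(pr@high@hu)[3])))
}

#' Patient-level train/validation/test split
#'
#' For each exam type separately, patients are shuffled with the seed and
#' partitioned 70/20/10 into train/validation/test using largest-remainder
#' rounding (50 patients give 35/10/5). Splits are patient-disjoint.
#'
#' @param manifest data.frame with \code{patientId} and \code{examType}.
#' @param seed integer seed.
#' @param fractions numeric length-3 summing to 1.
#' @return A \code{DatasetSplit}: per exam type, a list with \code{train},
#'   \code{validation}, \code{test} patient vectors.
#' @export
splitDataset <- function(manifest, seed = 0L,
                         fractions = c(0.7, 0.2, 0.1)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  out <- list()
  for (et in unique(manifest$examType)) {
    pats <- unique(manifest$patientId[manifest$examType == et])
    n <- length(pats)
    if (n < 3L)
      stop(sprintf("exam type '%s' has fewer than 3 patients", et),
           call. = FALSE)
    pats <- .withSeed(.childSeed(seed, paste0("split-", et)), sample(pats))
    raw <- fractions * n
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    if (rem > 0) {
      extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    cuts <- cumsum(sizes)
    out[[et]] <- list(train = pats[seq_len(cuts[1])],
                      validation = pats[(cuts[1] + 1L):cuts[2]],
                      test = if (cuts[3] > cuts[2])
                        pats[(cuts[2] + 1L):cuts[3]] else character())
  }
  structure(list(byExamType = out, seed = as.integer(seed),
                 fractions = fractions), class = "DatasetSplit")
}

#' Per-slice training sampling weights
#'
#' Weighted sampling such that exam types and, within an exam type,
#' patients are drawn with equal probability regardless of slice counts:
#' a slice of patient p in exam type e gets weight
#' \eqn{1 / (E \cdot P_e \cdot S_p)}; weights sum to 1.
#'
#' @param manifest data.frame with patientId, examType, nSlices.
#' @param split optional \code{DatasetSplit}; weights are computed on its
#'   training patients only.
#' @return data.frame(examType, patientId, sliceIndex, weight).
#' @export
samplingWeights <- function(manifest, split = NULL) {
  if (!is.null(split)) {
    keep <- mapply(function(p, e) p %in% split$byExamType[[e]]$train,
                   manifest$patientId, manifest$examType)
    manifest <- manifest[keep, , drop = FALSE]
  }
  if (!nrow(manifest)) stop("empty training split", call. = FALSE)
  if (any(manifest$nSlices < 1L))
    stop("patient with zero slices", call. = FALSE)
  E <- length(unique(manifest$examType))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    e <- manifest$examType[i]
    Pe <- length(unique(manifest$patientId[manifest$examType == e]))
    Sp <- manifest$nSlices[i]
    data.frame(examType = e, patientId = manifest$patientId[i],
               sliceIndex = seq_len(Sp) - 1L,
               weight = 1 / (E * Pe * Sp))
  })
  do.call(rbind, rows)
}

#' Select evaluable test slices per exam type
#'
#' Head scans keep slices where the brain is present, chest scans where the
#' lung is present, abdomen scans where the lung is absent (all slices when
#' no lung mask exists).
#'
#' @param scan a \linkS4class{ScanPair} (or \linkS4class{CTVolume} with
#'   \code{organMasks} supplied).
#' @param organMasks named list of logical mask arrays.
#' @return Integer vector of 0-based slice indices; an empty selection is
#'   flagged with a warning.
#' @export
filterTestSlices <- function(scan, organMasks = NULL) {
  if (is(scan, "ScanPair")) {
    if (is.null(organMasks)) organMasks <- scan@organMasks
    et <- examType(scan)
    nz <- dim(scan@high@hu)[3]
  } else {
    et <- examType(scan)
    nz <- dim(scan@hu)[3]
  }
  organPresent <- function(nm) {
    m <- organMasks[[nm]]
    if (is.null(m)) stop(sprintf("missing required mask '%s'", nm),
                         call. = FALSE)
    vapply(seq_len(nz), function(k) any(m[, , k]), logical(1))
  }
  idx <- switch(et,
    head = which(organPresent("brain")),
    chest = which(organPresent("lung")),
    abdomen = {
      if (is.null(organMasks$lung)) seq_len(nz)
      else which(!vapply(seq_len(nz), function(k)
        any(organMasks$lung[, , k]), logical(1)))
    })
  if (!length(idx))
    warning(sprintf("no evaluable slices for this %s scan", et))
  as.integer(idx - 1L)
}

.sliceMetric <- function(metric, testSl, refSl, dataRange) {
  switch(metric,
         SSIM = ssim(testSl, refSl, dataRange),
         PSNR = psnr(testSl, refSl, dataRange),
         VIF = vif(testSl, refSl),
         RMSE = rmseHU(testSl, refSl),
         stop(sprintf("unknown metric '%s'", metric), call. = FALSE))
}

#' Evaluate a fitted method on a test set
#'
#' For every retraining seed, the method denoises each test scan's low-dose
#' volume; metrics are computed per evaluable slice (see
#' \code{\link{filterTestSlices}}) against the high-dose volume, averaged
#' over slices, then over scans of each exam type. Rows report mean and
#' standard deviation over the retraining seeds. Per-seed and per-slice
#' values are attached as attributes \code{"perSeed"} and \code{"perSlice"}
#' for significance testing and hard-subset construction.
#'
#' @param spec a \linkS4class{DenoiserSpec}.
#' @param fittedStates named list of fitted states, one per retraining seed.
#' @param testSet list of \linkS4class{ScanPair}s.
#' @param metricList metrics among SSIM, PSNR, VIF, RMSE.
#' @param dataRange data range in HU for SSIM/PSNR.
#' @return data.frame(method, examType, metric, mean, sd, year).
#' @export
evaluateMethod <- function(spec, fittedStates, testSet,
                           metricList = c("SSIM", "PSNR", "VIF"),
                           dataRange = 2000) {
  stopifnot(length(fittedStates) >= 1L, length(testSet) >= 1L)
  if (is.null(names(fittedStates)))
    names(fittedStates) <- paste0("seed", seq_along(fittedStates) - 1L)
  perSeed <- NULL
  perSlice <- NULL
  for (sd_nm in names(fittedStates)) {
    scanRows <- NULL
    for (pr in testSet) {
      den <- applyDenoiser(spec, fittedStates[[sd_nm]], pr@low)
      keep <- filterTestSlices(pr) + 1L
      if (!length(keep)) next
      for (met in metricList) {
        vals <- vapply(keep, function(k)
          .sliceMetric(met, den@hu[, , k], pr@high@hu[, , k], dataRange),
          numeric(1))
        scanRows <- rbind(scanRows, data.frame(
          method = spec@name, seed = sd_nm, examType = examType(pr),
          scanId = patientId(pr), metric = met, value = mean(vals)))
        perSlice <- rbind(perSlice, data.frame(
          method = spec@name, seed = sd_nm, examType = examType(pr),
          scanId = patientId(pr), sliceIndex = keep - 1L, metric = met,
          value = vals))
      }
    }
    agg <- aggregate(scanRows["value"],
                     scanRows[c("method", "seed", "examType", "metric")],
                     mean)
    perSeed <- rbind(perSeed, agg)
  }
  out <- aggregate(perSeed["value"],
                   perSeed[c("method", "examType", "metric")],
                   function(x) c(mean = mean(x),
                                 sd = if (length(x) > 1) sd(x) else 0))
  res <- data.frame(out[c("method", "examType", "metric")],
                    mean = out$value[, "mean"], sd = out$value[, "sd"],
                    year = spec@year)
  attr(res, "perSeed") <- perSeed
  attr(res, "perSlice") <- perSlice
  res
}

.rankSumW <- function(a, b) {
  # Mann-Whitney U of sample a (ties counted half)
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Exact p-value by enumeration of all group assignments of the pooled
#' sample (mid-ranks for ties) when n + m <= 14; normal approximation with
#' tie correction and continuity correction otherwise. Two identical
#' constant samples return p = 1 with a \code{degenerate} flag.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative "two.sided", "less" (a shifted below b) or "greater".
#' @return list(U, p, exact, degenerate).
#' @export
mannWhitneyU <- function(a, b,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  n <- length(a); m <- length(b)
  U <- .rankSumW(a, b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1, exact = TRUE, degenerate = TRUE))
  if (n + m <= 14L) {
    idx <- combn(n + m, n)
    Us <- apply(idx, 2, function(ii)
      .rankSumW(pooled[ii], pooled[-ii]))
    pLess <- mean(Us <= U)
    pGreater <- mean(Us >= U)
    p <- switch(alternative, less = pLess, greater = pGreater,
                two.sided = min(1, 2 * min(pLess, pGreater)))
    return(list(U = U, p = p, exact = TRUE, degenerate = FALSE))
  }
  N <- n + m
  ties <- table(pooled)
  muU <- n * m / 2
  sigU <- sqrt(n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
  z <- U - muU
  cc <- 0.5  # continuity correction
  p <- switch(alternative,
    less = pnorm((z + cc) / sigU),
    greater = pnorm((z - cc) / sigU, lower.tail = FALSE),
    two.sided = min(1, 2 * min(pnorm((z + cc) / sigU),
                               pnorm((z - cc) / sigU, lower.tail = FALSE))))
  list(U = U, p = p, exact = FALSE, degenerate = FALSE)
}

#' Wilcoxon signed-rank test for paired deviations
#'
#' Zero differences are dropped; the exact null distribution is obtained by
#' enumerating all sign assignments when the number of non-zero pairs is at
#' most 12, otherwise a normal approximation with tie correction is used.
#' All-zero differences return p = 1 with a \code{degenerate} flag.
#'
#' @param a,b paired numeric samples of equal length >= 5 (or \code{b =
#'   NULL} to test differences \code{a} against 0).
#' @param alternative "two.sided", "greater" (a above b) or "less".
#' @return list(V, p, exact, degenerate).
#' @export
wilcoxonSignedRank <- function(a, b = NULL,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(b)) a else {
    stopifnot(length(a) == length(b))
    a - b
  }
  stopifnot(length(d) >= 5L)
  d <- d[d != 0]
  if (!length(d)) return(list(V = 0, p = 1, exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  n <- length(d)
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    pGreater <- mean(Vs >= V)
    pLess <- mean(Vs <= V)
    p <- switch(alternative, greater = pGreater, less = pLess,
                two.sided = min(1, 2 * min(pLess, pGreater)))
    return(list(V = V, p = p, exact = TRUE, degenerate = FALSE))
  }
  muV <- n * (n + 1) / 4
  ties <- table(r)
  sigV <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                 sum(ties^3 - ties) / 48)
  z <- V - muV
  p <- switch(alternative,
    greater = pnorm((z - 0.5) / sigV, lower.tail = FALSE),
    less = pnorm((z + 0.5) / sigV),
    two.sided = min(1, 2 * min(pnorm((z + 0.5) / sigV),
                               pnorm((z - 0.5) / sigV,
                                     lower.tail = FALSE))))
  list(V = V, p = p, exact = FALSE, degenerate = FALSE)
}

.HIGHER_BETTER <- c(SSIM = TRUE, PSNR = TRUE, VIF = TRUE, RFS = TRUE,
                    CNR = TRUE, RMSE = FALSE, DEV = FALSE)

#' Significance marks against the previously published best method
#'
#' For every (method, exam type, metric) cell, the comparator is the method
#' with the best mean among methods with a strictly earlier publication
#' year; methods with no earlier competitor are compared against the
#' low-dose baseline ("LD"). One-sided Mann-Whitney tests in both
#' directions at level alpha yield marks "better", "worse" or "none".
#'
#' @param perSeed long data.frame(method, seed, examType, metric, value) of
#'   per-seed results, including an "LD" baseline method.
#' @param years named vector of publication years (no entry needed for
#'   "LD").
#' @param alpha significance level (default 0.05).
#' @param higherBetter named logical vector per metric; defaults cover
#'   SSIM/PSNR/VIF/RFS/CNR (higher) and RMSE/DEV (lower).
#' @return data.frame(method, examType, metric, mark, comparator, p).
#' @export
significanceMarks <- function(perSeed, years, alpha = 0.05,
                              higherBetter = .HIGHER_BETTER) {
  methods <- setdiff(unique(perSeed$method), "LD")
  if (!all(methods %in% names(years)))
    stop("publication year missing for some methods", call. = FALSE)
  rows <- NULL
  for (et in unique(perSeed$examType)) {
    for (met in unique(perSeed$metric)) {
      cell <- perSeed[perSeed$examType == et & perSeed$metric == met, ]
      hb <- higherBetter[[met]] %||% TRUE
      for (M in methods) {
        earlier <- methods[years[methods] < years[M]]
        comparator <- if (!length(earlier)) "LD" else {
          mns <- vapply(earlier, function(e)
            mean(cell$value[cell$method == e]), numeric(1))
          earlier[if (hb) which.max(mns) else which.min(mns)]
        }
        x <- cell$value[cell$method == M]
        y <- cell$value[cell$method == comparator]
        altBetter <- if (hb) "greater" else "less"
        altWorse <- if (hb) "less" else "greater"
        pb <- mannWhitneyU(x, y, altBetter)$p
        pw <- mannWhitneyU(x, y, altWorse)$p
        mark <- if (pb < alpha) "better" else if (pw < alpha) "worse"
                else "none"
        rows <- rbind(rows, data.frame(
          method = M, examType = et, metric = met, mark = mark,
          comparator = comparator, p = min(pb, pw)))
      }
    }
  }
  rows
}

#' Competition ranks of summed scores
#'
#' Ties share a rank and the following rank is skipped ("1-2-2-4").
#'
#' @param scores numeric vector, lower is better.
#' @return data.frame(score, rank, tied) in input order.
#' @export
competitionRanks <- function(scores) {
  rk <- rank(scores, ties.method = "min")
  data.frame(score = scores, rank = as.integer(rk),
             tied = duplicated(scores) | duplicated(scores, fromLast = TRUE))
}

#' Competition ranking of methods over all exam types and metrics
#'
#' Within every (exam type, metric) cell, methods are ranked by mean value
#' (direction-aware); per-cell ranks are summed per method and the sums are
#' competition-ranked, ties sharing a rank with the next rank skipped.
#'
#' @param metricTable data.frame(method, examType, metric, mean).
#' @param higherBetter named logical vector per metric.
#' @return A RankTable data.frame(method, score, rank, tied).
#' @export
competitionRank <- function(metricTable, higherBetter = .HIGHER_BETTER) {
  methods <- unique(metricTable$method)
  cells <- unique(metricTable[c("examType", "metric")])
  total <- setNames(numeric(length(methods)), methods)
  for (i in seq_len(nrow(cells))) {
    cell <- metricTable[metricTable$examType == cells$examType[i] &
                          metricTable$metric == cells$metric[i], ]
    if (!all(methods %in% cell$method))
      stop("incomplete metric grid", call. = FALSE)
    hb <- higherBetter[[cells$metric[i]]] %||% TRUE
    v <- setNames(cell$mean, cell$method)[methods]
    rk <- rank(if (hb) -v else v, ties.method = "min")
    total <- total + rk
  }
  out <- competitionRanks(unname(total))
  data.frame(method = methods, score = out$score, rank = out$rank,
             tied = out$tied)
}

#' Hard-slice subsets (lowest method-averaged SSIM)
#'
#' Per exam type, slices are scored by the average SSIM over all evaluated
#' methods, sorted ascending (ties broken by scanId, then slice index), and
#' the first \eqn{\lceil q n / 100 \rceil} slices are retained. Subsets are
#' nested in q.
#'
#' @param perSliceSSIM data.frame(method, examType, scanId, sliceIndex,
#'   value) with an SSIM value for every method and slice.
#' @param q percentage in (0, 100].
#' @return A HardSubsetSpec: list(q, slices) with per-exam-type
#'   data.frame(scanId, sliceIndex).
#' @export
ldctHardSubset <- function(perSliceSSIM, q) {
  stopifnot(q > 0, q <= 100)
  nMethods <- length(unique(perSliceSSIM$method))
  out <- list()
  for (et in unique(perSliceSSIM$examType)) {
    sub <- perSliceSSIM[perSliceSSIM$examType == et, ]
    agg <- aggregate(sub["value"], sub[c("scanId", "sliceIndex")],
                     function(x) c(mean = mean(x), n = length(x)))
    if (any(agg$value[, "n"] != nMethods))
      stop("missing method-slice SSIM values", call. = FALSE)
    ord <- order(agg$value[, "mean"], agg$scanId, agg$sliceIndex)
    k <- ceiling(q * nrow(agg) / 100)
    sel <- agg[ord[seq_len(k)], c("scanId", "sliceIndex")]
    rownames(sel) <- NULL
    out[[et]] <- sel
  }
  structure(list(q = q, slices = out), class = "HardSubsetSpec")
}

#' Per-exam-type normalization statistics from the training split
#'
#' Mean and standard deviation of low-dose voxel intensities over the
#' training patients of each exam type; computed on the training split only
#' and intended to be applied unchanged to validation and test data.
#'
#' @param pairs list of \linkS4class{ScanPair}s.
#' @param split a \code{DatasetSplit}.
#' @return data.frame(examType, mean, sd).
#' @export
normalizationStats <- function(pairs, split) {
  rows <- NULL
  for (et in names(split$byExamType)) {
    tr <- split$byExamType[[et]]$train
    vals <- unlist(lapply(pairs, function(pr)
      if (examType(pr) == et && patientId(pr) %in% tr)
        as.numeric(pr@low@hu) else NULL))
    if (is.null(vals) || !length(vals)) next
    s <- sd(vals)
    if (!(s > 0)) stop("zero-variance training intensities", call. = FALSE)
    rows <- rbind(rows, data.frame(examType = et, mean = mean(vals), sd = s))
  }
  rows
}
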