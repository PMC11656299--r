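# Radiomic feature extraction (first-order, GLCM, GLRLM) on organ masks and
# the radiomic feature similarity (RFS) between denoised and high-dose scans.

# 13 unique 3-D direction offsets at distance 1 (one of each +/- pair).
.DIRECTIONS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(1, -1, -1))

#' Radiomic extraction configuration
#'
#' @param binWidth gray-level discretization bin width in HU.
#' @param distance co-occurrence / run distance in voxels.
#' @return A named list.
#' @export
radiomicsConfig <- function(binWidth = 25, distance = 1L) {
  list(binWidth = binWidth, distance = as.integer(distance),
       directions = "13-direction 3-D", version = "fo+glcm+glrlm-v1")
}

.cropToMask <- function(arr, mask) {
  idx <- which(mask, arr.ind = TRUE)
  rg <- apply(idx, 2, range)
  list(arr = arr[rg[1, 1]:rg[2, 1], rg[1, 2]:rg[2, 2], rg[1, 3]:rg[2, 3],
                 drop = FALSE],
       mask = mask[rg[1, 1]:rg[2, 1], rg[1, 2]:rg[2, 2], rg[1, 3]:rg[2, 3],
                   drop = FALSE])
}

.discretize <- function(v, binWidth, lo = min(v)) {
  pmax(1L, as.integer(floor((v - lo) / binWidth)) + 1L)
}

# Symmetric gray-level co-occurrence counts for one direction offset.
.glcmMatrix <- function(arrD, offset, Ng) {
  d <- dim(arrD)
  lo <- pmax(1, 1 - offset)
  hi <- pmin(d, d - offset)
  if (any(lo > hi)) return(matrix(0, Ng, Ng))
  xr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; zr <- lo[3]:hi[3]
  a <- arrD[xr, yr, zr]
  b <- arrD[xr + offset[1], yr + offset[2], zr + offset[3]]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, Ng, Ng))
  counts <- as.numeric(tabulate(a[ok] + (b[ok] - 1L) * Ng, nbins = Ng * Ng))
  P <- matrix(counts, Ng, Ng)
  P + t(P)
}

# Gray-level run-length counts for one direction offset; runs break at mask
# boundaries (NA) and gray-level changes.
.glrlmMatrix <- function(arrD, offset, Ng, maxLen) {
  d <- dim(arrD)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  ax <- which(offset != 0)[1]
  t <- g[[ax]]
  k1 <- g$i - t * offset[1]
  k2 <- g$j - t * offset[2]
  k3 <- g$k - t * offset[3]
  ord <- order(k1, k2, k3, t)
  v <- arrD[cbind(g$i, g$j, g$k)][ord]
  newLine <- c(TRUE, diff(k1[ord]) != 0 | diff(k2[ord]) != 0 |
                 diff(k3[ord]) != 0)
  prevV <- c(NA, v[-length(v)])
  newRun <- newLine | (is.na(v) != is.na(prevV)) |
    (!is.na(v) & !is.na(prevV) & v != prevV)
  runId <- cumsum(newRun)
  runLen <- tabulate(runId)
  runVal <- v[newRun]
  keep <- !is.na(runVal)
  if (!any(keep)) return(matrix(0, Ng, maxLen))
  counts <- as.numeric(
    tabulate(runVal[keep] + (pmin(runLen[keep], maxLen) - 1L) * Ng,
             nbins = Ng * maxLen))
  matrix(counts, Ng, maxLen)
}

.firstOrderFeatures <- function(v, binWidth) {
  m <- mean(v)
  va <- mean((v - m)^2)
  sk <- if (va > 0) mean((v - m)^3) / va^1.5 else 0
  ku <- if (va > 0) mean((v - m)^4) / va^2 else 0
  p <- tabulate(.discretize(v, binWidth))
  p <- p[p > 0] / length(v)
  c(fo_Mean = m, fo_Variance = va, fo_Skewness = sk, fo_Kurtosis = ku,
    fo_Median = median(v), fo_Minimum = min(v), fo_Maximum = max(v),
    fo_Range = diff(range(v)),
    fo_Percentile10 = unname(quantile(v, 0.10, type = 7)),
    fo_Percentile90 = unname(quantile(v, 0.90, type = 7)),
    fo_InterquartileRange = unname(diff(quantile(v, c(0.25, 0.75), type = 7))),
    fo_MeanAbsoluteDeviation = mean(abs(v - m)),
    fo_RootMeanSquared = sqrt(mean(v^2)), fo_Energy = sum(v^2),
    fo_Entropy = -sum(p * log2(p)), fo_Uniformity = sum(p^2))
}

.glcmFeatures <- function(P) {
  tot <- sum(P)
  if (tot == 0) P <- diag(nrow(P))  # single-voxel degenerate case
  p <- P / sum(P)
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(seq_len(Ng) * px); my <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - my)^2 * py))
  pn0 <- p[p > 0]
  corr <- if (sx > 0 && sy > 0)
    sum(p * (i - mx) * (j - my)) / (sx * sy) else 1
  c(glcm_JointEnergy = sum(p^2),
    glcm_Contrast = sum(p * (i - j)^2),
    glcm_Dissimilarity = sum(p * abs(i - j)),
    glcm_InverseDifference = sum(p / (1 + abs(i - j))),
    glcm_InverseDifferenceMoment = sum(p / (1 + (i - j)^2)),
    glcm_Correlation = corr,
    glcm_JointEntropy = -sum(pn0 * log2(pn0)),
    glcm_ClusterShade = sum(p * (i + j - mx - my)^3),
    glcm_ClusterProminence = sum(p * (i + j - mx - my)^4),
    glcm_MaximumProbability = max(p))
}

.glrlmFeatures <- function(P, nVoxelsTimesDirs) {
  Nr <- sum(P)
  if (Nr == 0) return(setNames(numeric(11), paste0("glrlm_", c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "RunLengthNonUniformity", "RunPercentage", "LowGrayLevelRunEmphasis",
    "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
    "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LongRunHighGrayLevelEmphasis"))))
  Ng <- nrow(P); L <- ncol(P)
  gi <- matrix(seq_len(Ng), Ng, L)
  rl <- matrix(seq_len(L), Ng, L, byrow = TRUE)
  c(glrlm_ShortRunEmphasis = sum(P / rl^2) / Nr,
    glrlm_LongRunEmphasis = sum(P * rl^2) / Nr,
    glrlm_GrayLevelNonUniformity = sum(rowSums(P)^2) / Nr,
    glrlm_RunLengthNonUniformity = sum(colSums(P)^2) / Nr,
    glrlm_RunPercentage = Nr / nVoxelsTimesDirs,
    glrlm_LowGrayLevelRunEmphasis = sum(P / gi^2) / Nr,
    glrlm_HighGrayLevelRunEmphasis = sum(P * gi^2) / Nr,
    glrlm_ShortRunLowGrayLevelEmphasis = sum(P / (gi^2 * rl^2)) / Nr,
    glrlm_ShortRunHighGrayLevelEmphasis = sum(P * gi^2 / rl^2) / Nr,
    glrlm_LongRunLowGrayLevelEmphasis = sum(P * rl^2 / gi^2) / Nr,
    glrlm_LongRunHighGrayLevelEmphasis = sum(P * gi^2 * rl^2) / Nr)
}

#' Extract radiomic features within an organ mask
#'
#' Computes a fixed, documented feature set on the HU values inside a mask:
#' 16 first-order statistics, 10 gray-level co-occurrence (GLCM) features
#' and 11 gray-level run-length (GLRLM) features. Texture matrices are
#' computed on HU values discretized at a fixed bin width and aggregated
#' (summed) over 13 3-D directions at distance 1. Shape features are
#' deliberately absent: the same (high-dose) mask is reused for every
#' algorithm, so shape carries no signal.
#'
#' @param volume a \linkS4class{CTVolume} or 3-D HU array.
#' @param organMask logical array congruent with the volume, non-empty.
#' @param config a \code{\link{radiomicsConfig}} list.
#' @return Named numeric vector of 37 features, order fixed.
#' @export
extractFeatures <- function(volume, organMask, config = radiomicsConfig()) {
  arr <- .huArr(volume)
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  if (is.matrix(organMask))
    organMask <- array(organMask, dim = c(dim(organMask), 1L))
  .assertCongruent(arr, organMask, "volume and mask")
  if (!any(organMask)) stop("empty organ mask", call. = FALSE)
  cr <- .cropToMask(arr, organMask)
  v <- cr$arr[cr$mask]
  fo <- .firstOrderFeatures(v, config$binWidth)

  arrD <- array(NA_integer_, dim = dim(cr$arr))
  arrD[cr$mask] <- .discretize(v, config$binWidth)
  Ng <- max(arrD, na.rm = TRUE)
  maxLen <- max(dim(cr$arr))
  glcmP <- matrix(0, Ng, Ng)
  glrlmP <- matrix(0, Ng, maxLen)
  for (r in seq_len(nrow(.DIRECTIONS13))) {
    off <- .DIRECTIONS13[r, ] * config$distance
    glcmP <- glcmP + .glcmMatrix(arrD, off, Ng)
    glrlmP <- glrlmP + .glrlmMatrix(arrD, off, Ng, maxLen)
  }
  out <- c(fo, .glcmFeatures(glcmP),
           .glrlmFeatures(glrlmP, length(v) * nrow(.DIRECTIONS13)))
  attr(out, "extractionConfig") <- config
  out
}

#' Assemble a per-scan feature matrix over algorithms
#'
#' @param volumes named list of \linkS4class{CTVolume}s / arrays; the first
#'   entry must be the high-dose reference.
#' @param organMask logical array (the high-dose segmentation, reused for
#'   all algorithms).
#' @param scanId character.
#' @param config a \code{\link{radiomicsConfig}}.
#' @return A \linkS4class{FeatureMatrix} (not yet normalized).
#' @export
featureMatrix <- function(volumes, organMask, scanId = "scan",
                          config = radiomicsConfig()) {
  stopifnot(length(volumes) >= 1L, !is.null(names(volumes)))
  rows <- lapply(volumes, extractFeatures, organMask = organMask,
                 config = config)
  vals <- do.call(rbind, rows)
  rownames(vals) <- names(volumes)
  new("FeatureMatrix", values = vals, scanId = scanId, normalized = FALSE,
      droppedFeatures = character(), extractionConfig = config)
}

#' Min-max feature normalization across algorithms
#'
#' Per feature j, computes
#' \eqn{(R_{i,j} - \max_k R_{k,j}) / (\max_k R_{k,j} - \min_k R_{k,j})},
#' mapping every value into [-1, 0] (the max-attaining algorithm to 0, the
#' min-attaining to -1), so each feature carries equal a-priori weight.
#' Features constant across algorithms (max = min) are removed from all rows
#' and recorded in \code{droppedFeatures}. The conventional
#' \code{"min-subtract"} variant \eqn{(R - \min) / (\max - \min)} (values in
#' [0, 1]) is available as a switch.
#'
#' @param fm a \linkS4class{FeatureMatrix} with >= 2 algorithm rows.
#' @param variant "max-subtract" (default) or "min-subtract".
#' @return A normalized \linkS4class{FeatureMatrix}.
#' @export
normalizeFeatures <- function(fm, variant = c("max-subtract", "min-subtract")) {
  variant <- match.arg(variant)
  R <- fm@values
  if (nrow(R) < 2L) stop("need at least 2 algorithms (incl. HD)",
                         call. = FALSE)
  mx <- apply(R, 2, max)
  mn <- apply(R, 2, min)
  degen <- mx == mn
  if (all(degen)) stop("all features degenerate (max = min)", call. = FALSE)
  R <- R[, !degen, drop = FALSE]
  mx <- mx[!degen]; mn <- mn[!degen]
  Rn <- if (variant == "max-subtract")
    sweep(sweep(R, 2, mx, "-"), 2, mx - mn, "/")
  else
    sweep(sweep(R, 2, mn, "-"), 2, mx - mn, "/")
  new("FeatureMatrix", values = Rn, scanId = fm@scanId, normalized = TRUE,
      droppedFeatures = c(fm@droppedFeatures, colnames(fm@values)[degen]),
      extractionConfig = fm@extractionConfig)
}

#' Radiomic feature similarity (RFS)
#'
#' Cosine similarity between each algorithm's normalized feature vector and
#' the high-dose row (row 1):
#' \eqn{RFS_i(s) = r_i \cdot r_0 / (\|r_i\| \|r_0\|)}.
#'
#' @param fm a normalized \linkS4class{FeatureMatrix} (see
#'   \code{\link{normalizeFeatures}}); row 1 is the high-dose reference.
#' @return data.frame with columns \code{scanId}, \code{algorithm},
#'   \code{rfs}, one row per algorithm i = 1..n.
#' @export
rfs <- function(fm) {
  if (!fm@normalized)
    stop("feature matrix must be normalized first", call. = FALSE)
  R <- fm@values
  nrm <- sqrt(rowSums(R^2))
  if (any(nrm == 0))
    stop(errorCondition(
      sprintf("zero-norm feature row(s): %s",
              paste(rownames(R)[nrm == 0], collapse = ", ")),
      class = c("zeroNormRowError", "error", "condition")))
  r0 <- R[1, ]
  vals <- as.numeric(R[-1, , drop = FALSE] %*% r0) / (nrm[-1] * nrm[1])
  data.frame(scanId = fm@scanId, algorithm = rownames(R)[-1], rfs = vals,
             row.names = NULL)
}

#' Summarize RFS over scans and training seeds
#'
#' Per group (method and exam type), averages RFS over scans within each
#' training seed, then reports mean and standard deviation over seeds. With
#' a single seed the spread is reported as 0 and flagged.
#'
#' @param records data.frame with columns \code{algorithm}, \code{examType},
#'   \code{seed}, \code{scanId}, \code{rfs}.
#' @param grouping character columns to group by (default method and exam
#'   type).
#' @return data.frame with \code{mean}, \code{sd}, \code{nSeeds},
#'   \code{singleSeed} per group.
#' @export
rfsSummary <- function(records, grouping = c("algorithm", "examType")) {
  stopifnot(nrow(records) >= 1L,
            all(c(grouping, "seed", "rfs") %in% names(records)))
  perSeed <- aggregate(records["rfs"],
                       records[c(grouping, "seed")], mean)
  out <- aggregate(perSeed["rfs"], perSeed[grouping], function(x)
    c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0,
      n = length(x)))
  res <- data.frame(out[grouping], mean = out$rfs[, "mean"],
                    sd = out$rfs[, "sd"], nSeeds = as.integer(out$rfs[, "n"]))
  res$singleSeed <- res$nSeeds == 1L
  res
}
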