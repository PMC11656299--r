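# Full-reference image quality metrics (SSIM, PSNR, RMSE, VIF) and physical
# CT metrics (CNR, CT-number deviation, line profiles), computed on
# Hounsfield-unit images.

.huArr <- function(x) if (is(x, "CTVolume")) x@hu else x

.metricMeanOverSlices <- function(test, reference, fun) {
  ts <- .asSlices(.huArr(test)); rs <- .asSlices(.huArr(reference))
  if (length(ts) != length(rs)) stop("slice counts differ", call. = FALSE)
  mean(vapply(seq_along(ts), function(k) fun(ts[[k]], rs[[k]]), numeric(1)))
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with a Gaussian window (Wang et al. variant: 11-tap
#' Gaussian of sigma 1.5, population covariances). Local statistics use
#' reflect padding and the window-radius border strip is excluded from the
#' final average. Symmetric in its arguments. 3-D inputs are evaluated per
#' axial slice and averaged.
#'
#' @param test,reference congruent numeric matrices / 3-D arrays (HU) or
#'   \linkS4class{CTVolume}s.
#' @param dataRange assumed dynamic range of the data (HU), > 0.
#' @param windowConfig list with \code{sigma}, \code{K1}, \code{K2}.
#' @return SSIM in [-1, 1].
#' @export
ssim <- function(test, reference, dataRange = 2000,
                 windowConfig = list(sigma = 1.5, K1 = 0.01, K2 = 0.03)) {
  test <- .huArr(test); reference <- .huArr(reference)
  .assertCongruent(test, reference)
  if (!(dataRange > 0)) stop("dataRange must be > 0", call. = FALSE)
  if (!is.matrix(test))
    return(.metricMeanOverSlices(test, reference, function(a, b)
      ssim(a, b, dataRange, windowConfig)))
  sigma <- windowConfig$sigma %||% 1.5
  K1 <- windowConfig$K1 %||% 0.01
  K2 <- windowConfig$K2 %||% 0.03
  kern <- .gaussKernel1d(sigma)
  pad <- (length(kern) - 1L) / 2L
  ux <- .sepFilter2(test, kern)
  uy <- .sepFilter2(reference, kern)
  uxx <- .sepFilter2(test * test, kern)
  uyy <- .sepFilter2(reference * reference, kern)
  uxy <- .sepFilter2(test * reference, kern)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  vxy <- uxy - ux * uy
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  keepR <- (pad + 1L):(nrow(S) - pad)
  keepC <- (pad + 1L):(ncol(S) - pad)
  mean(S[keepR, keepC])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak signal-to-noise ratio (dB)
#'
#' \eqn{10 \log_{10}(L^2 / MSE)} with MSE computed in HU over the supplied
#' selection. Identical images have no finite PSNR and signal a condition of
#' class \code{"identicalImagesError"}.
#'
#' @inheritParams ssim
#' @param maskOrBox optional logical mask congruent with the images, or an
#'   integer length-6 lesion box \code{c(x0,x1,y0,y1,z0,z1)} (0-based,
#'   half-open) restricting the computation.
#' @return PSNR in dB.
#' @export
psnr <- function(test, reference, dataRange = 2000, maskOrBox = NULL) {
  if (!(dataRange > 0)) stop("dataRange must be > 0", call. = FALSE)
  r <- rmseHU(test, reference, maskOrBox)
  if (r == 0)
    stop(errorCondition("identical images: PSNR is unbounded",
                        class = c("identicalImagesError", "error",
                                  "condition")))
  10 * log10(dataRange^2 / r^2)
}

.selectVoxels <- function(arr, maskOrBox) {
  if (is.null(maskOrBox)) return(as.numeric(arr))
  if (is.logical(maskOrBox)) {
    .assertCongruent(arr, maskOrBox, "image and mask")
    return(arr[maskOrBox])
  }
  if (is.numeric(maskOrBox) && length(maskOrBox) == 6L) {
    if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
    b <- as.integer(maskOrBox)
    return(as.numeric(arr[(b[1] + 1L):b[2], (b[3] + 1L):b[4],
                          (b[5] + 1L):b[6]]))
  }
  stop("maskOrBox must be a logical mask or a length-6 box", call. = FALSE)
}

#' Root-mean-squared error in HU
#'
#' @inheritParams psnr
#' @return RMSE in HU over the selected voxels.
#' @export
rmseHU <- function(test, reference, maskOrBox = NULL) {
  test <- .huArr(test); reference <- .huArr(reference)
  .assertCongruent(test, reference)
  d <- .selectVoxels(test, maskOrBox) - .selectVoxels(reference, maskOrBox)
  if (!length(d)) stop("empty voxel selection", call. = FALSE)
  sqrt(mean(d^2))
}

#' Visual information fidelity (pixel domain, multi-scale)
#'
#' Pixel-domain VIF accumulated over 4 dyadic scales: at each scale the
#' images are smoothed with a Gaussian window (size \eqn{2^{5-s}+1}, sd a
#' fifth of that), local gain and visual-noise parameters are estimated from
#' windowed moments, and the ratio of distorted-to-reference information
#' terms is returned. Equals 1 for identical images (to numerical
#' tolerance).
#'
#' @inheritParams ssim
#' @param config list with \code{sigmaNsq}, the HVS noise variance.
#' @return VIF >= 0.
#' @export
vif <- function(test, reference, config = list(sigmaNsq = 2)) {
  test <- .huArr(test); reference <- .huArr(reference)
  .assertCongruent(test, reference)
  if (!is.matrix(test))
    return(.metricMeanOverSlices(test, reference, function(a, b)
      vif(a, b, config)))
  if (var(as.numeric(reference)) == 0)
    stop(errorCondition("zero-variance reference: VIF undefined",
                        class = c("zeroVarianceError", "error", "condition")))
  sigmaNsq <- config$sigmaNsq %||% 2
  eps <- 1e-10
  num <- den <- 0
  ref <- reference; dst <- test
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    g1 <- .gaussKernel1d(N / 5, radius = (N - 1L) / 2L)
    if (scale > 1) {
      ref <- .sepFilter2Valid(ref, g1)
      dst <- .sepFilter2Valid(dst, g1)
      ref <- ref[seq(1, nrow(ref), by = 2), seq(1, ncol(ref), by = 2),
                 drop = FALSE]
      dst <- dst[seq(1, nrow(dst), by = 2), seq(1, ncol(dst), by = 2),
                 drop = FALSE]
    }
    mu1 <- .sepFilter2Valid(ref, g1)
    mu2 <- .sepFilter2Valid(dst, g1)
    s1 <- .sepFilter2Valid(ref * ref, g1) - mu1^2
    s2 <- .sepFilter2Valid(dst * dst, g1) - mu2^2
    s12 <- .sepFilter2Valid(ref * dst, g1) - mu1 * mu2
    s1[s1 < 0] <- 0
    s2[s2 < 0] <- 0
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0; sv[s1 < eps] <- s2[s1 < eps]; s1[s1 < eps] <- 0
    g[s2 < eps] <- 0; sv[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= eps] <- eps
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigmaNsq)))
    den <- den + sum(log10(1 + s1 / sigmaNsq))
  }
  num / den
}

#' Circular region of interest
#'
#' @param sliceIndex 0-based axial slice index.
#' @param center numeric length-2, 0-based voxel coordinates of the centre.
#' @param radius radius in voxels.
#' @return A \code{CircularROI} list.
#' @export
circularROI <- function(sliceIndex, center, radius) {
  stopifnot(radius > 0, length(center) == 2L)
  structure(list(sliceIndex = as.integer(sliceIndex), center = center,
                 radius = radius), class = "CircularROI")
}

.roiValues <- function(arr, roi) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  d <- dim(arr)
  if (roi$sliceIndex < 0L || roi$sliceIndex >= d[3])
    stop("ROI slice outside volume", call. = FALSE)
  if (any(roi$center - roi$radius < 0) ||
      roi$center[1] + roi$radius > d[1] - 1 ||
      roi$center[2] + roi$radius > d[2] - 1)
    stop("ROI extends outside image bounds", call. = FALSE)
  sl <- arr[, , roi$sliceIndex + 1L]
  ix <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  iy <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  inside <- (ix - roi$center[1])^2 + (iy - roi$center[2])^2 <= roi$radius^2
  sl[inside]
}

#' Contrast-to-noise ratio
#'
#' \eqn{|mean(signal) - mean(background)| / sd(background)} between two
#' disjoint circular ROIs.
#'
#' @param image numeric matrix / 3-D array (HU) or \linkS4class{CTVolume}.
#' @param roiSignal,roiBackground \code{\link{circularROI}} objects.
#' @return CNR (dimensionless).
#' @export
cnr <- function(image, roiSignal, roiBackground) {
  arr <- .huArr(image)
  vs <- .roiValues(arr, roiSignal)
  vb <- .roiValues(arr, roiBackground)
  if (roiSignal$sliceIndex == roiBackground$sliceIndex) {
    dc <- sqrt(sum((roiSignal$center - roiBackground$center)^2))
    if (dc < roiSignal$radius + roiBackground$radius)
      stop("signal and background ROIs must be disjoint", call. = FALSE)
  }
  sb <- sd(vb)
  if (sb == 0) stop("zero background standard deviation", call. = FALSE)
  abs(mean(vs) - mean(vb)) / sb
}

#' Absolute CT-number deviation per ROI
#'
#' Per ROI, the absolute difference of mean HU between a test and a
#' reference reconstruction.
#'
#' @param test,reference images or \linkS4class{CTVolume}s on one grid.
#' @param rois list of \code{\link{circularROI}} objects (>= 1).
#' @return Numeric vector of absolute deviations (HU), one per ROI.
#' @export
ctNumberDeviation <- function(test, reference, rois) {
  if (!length(rois)) stop("at least one ROI required", call. = FALSE)
  test <- .huArr(test); reference <- .huArr(reference)
  .assertCongruent(test, reference)
  vapply(rois, function(roi) {
    v <- .roiValues(test, roi)
    if (!length(v)) stop("empty ROI", call. = FALSE)
    abs(mean(v) - mean(.roiValues(reference, roi)))
  }, numeric(1))
}

#' Line segment for profile sampling
#'
#' @param start,end numeric length-2, 0-based voxel coordinates.
#' @param nSamples number of evenly spaced samples (>= 2).
#' @return A \code{LineSegment} list.
#' @export
lineSegment <- function(start, end, nSamples = 100L) {
  stopifnot(nSamples >= 2L, length(start) == 2L, length(end) == 2L)
  structure(list(start = start, end = end, nSamples = as.integer(nSamples)),
            class = "LineSegment")
}

#' Line profile by bilinear interpolation
#'
#' Samples the image at \code{nSamples} evenly spaced points from start to
#' end using bilinear interpolation (0-based voxel coordinates).
#'
#' @param image numeric matrix (a single axial slice, HU).
#' @param segment a \code{\link{lineSegment}}.
#' @return Numeric vector of sampled HU values.
#' @export
lineProfile <- function(image, segment) {
  d <- dim(image)
  for (p in list(segment$start, segment$end))
    if (any(p < 0) || p[1] > d[1] - 1 || p[2] > d[2] - 1)
      stop("segment endpoints must lie inside the image", call. = FALSE)
  t <- seq(0, 1, length.out = segment$nSamples)
  xs <- segment$start[1] + t * (segment$end[1] - segment$start[1])
  ys <- segment$start[2] + t * (segment$end[2] - segment$start[2])
  i0 <- pmin(floor(xs), d[1] - 2); j0 <- pmin(floor(ys), d[2] - 2)
  fx <- xs - i0; fy <- ys - j0
  v00 <- image[cbind(i0 + 1, j0 + 1)]
  v10 <- image[cbind(i0 + 2, j0 + 1)]
  v01 <- image[cbind(i0 + 1, j0 + 2)]
  v11 <- image[cbind(i0 + 2, j0 + 2)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Per-lesion RMSE and PSNR within bounding boxes
#'
#' Restricts RMSE and PSNR to each lesion bounding box of a scan, comparing
#' a (denoised or low-dose) volume against the high-dose reference.
#'
#' @param test a denoised/low-dose \linkS4class{CTVolume} or array, or a
#'   \linkS4class{ScanPair} (whose low-dose volume is evaluated).
#' @param reference the high-dose \linkS4class{CTVolume} or array; ignored
#'   when \code{test} is a \linkS4class{ScanPair}.
#' @param boxes list of lesions (\code{list(box, label, ...)}) or raw
#'   length-6 boxes; defaults to the pair's annotations.
#' @param dataRange PSNR data range (HU).
#' @return data.frame with columns \code{label}, \code{rmse}, \code{psnr}.
#' @export
lesionMetrics <- function(test, reference = NULL, boxes = NULL,
                          dataRange = 2000) {
  if (is(test, "ScanPair")) {
    if (is.null(boxes)) boxes <- test@lesionBoxes
    reference <- test@high
    test <- test@low
  }
  if (is.null(boxes) || !length(boxes)) stop("no lesion boxes", call. = FALSE)
  rows <- lapply(seq_along(boxes), function(i) {
    les <- boxes[[i]]
    b <- if (is.list(les)) les$box else les
    lab <- if (is.list(les) && !is.null(les$label)) les$label
           else sprintf("lesion-%d", i)
    data.frame(label = lab,
               rmse = rmseHU(test, reference, b),
               psnr = psnr(test, reference, dataRange, b))
  })
  do.call(rbind, rows)
}
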