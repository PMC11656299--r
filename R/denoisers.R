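# Denoiser plugin interface and desk-scale reference denoisers: identity,
# Gaussian, bilateral (parameters selected by SMBO) and a three-layer CNN
# trained on patches with an MSE loss.

.denoiserRegistry <- new.env(parent = emptyenv())

#' Construct a denoiser plugin specification
#'
#' @param name registry key.
#' @param year publication year of the method.
#' @param fitFun function(trainPairs, hyperparams, seed) -> fitted state (a
#'   list carrying \code{method = name}).
#' @param applyFun function(state, volume) -> denoised \linkS4class{CTVolume}.
#' @param space optional hyperparameter \linkS4class{SearchSpace}.
#' @param deterministic logical, TRUE if applyFun is deterministic.
#' @return A \linkS4class{DenoiserSpec}.
#' @export
denoiserSpec <- function(name, year, fitFun, applyFun, space = NULL,
                         deterministic = TRUE) {
  new("DenoiserSpec", name = name, year = as.integer(year), space = space,
      fitFun = fitFun, applyFun = applyFun,
      deterministic = isTRUE(deterministic))
}

#' Register / resolve denoiser plugins
#'
#' @param spec a \linkS4class{DenoiserSpec}.
#' @return \code{registerDenoiser} returns the spec invisibly;
#'   \code{getDenoiser} the spec registered under \code{name};
#'   \code{listDenoisers} the registered names.
#' @export
registerDenoiser <- function(spec) {
  stopifnot(is(spec, "DenoiserSpec"))
  assign(spec@name, spec, envir = .denoiserRegistry)
  invisible(spec)
}

#' @rdname registerDenoiser
#' @param name registry key to resolve.
#' @export
getDenoiser <- function(name) {
  if (!exists(name, envir = .denoiserRegistry))
    stop(sprintf("no denoiser registered under '%s'", name), call. = FALSE)
  get(name, envir = .denoiserRegistry)
}

#' @rdname registerDenoiser
#' @export
listDenoisers <- function() sort(ls(envir = .denoiserRegistry))

#' Apply a fitted denoiser to a low-dose volume
#'
#' @param spec a \linkS4class{DenoiserSpec}.
#' @param state fitted state produced by the spec's fit function.
#' @param lowVolume the low-dose \linkS4class{CTVolume}.
#' @return A denoised \linkS4class{CTVolume} on the same grid, tagged
#'   \code{denoised:<name>}.
#' @export
applyDenoiser <- function(spec, state, lowVolume) {
  if (!is.list(state) || !identical(state$method, spec@name))
    stop(sprintf("state is not a fitted '%s' state", spec@name),
         call. = FALSE)
  out <- spec@applyFun(state, lowVolume)
  stopifnot(identical(dim(out@hu), dim(lowVolume@hu)))
  out@doseTag <- paste0("denoised:", spec@name)
  validObject(out)
  out
}

.volumeMap <- function(volume, sliceFun) {
  hu <- volume@hu
  for (k in seq_len(dim(hu)[3])) hu[, , k] <- sliceFun(volume@hu[, , k])
  out <- volume
  out@hu <- hu
  out
}

#' Edge-preserving bilateral filter
#'
#' Standard bilateral weights: a spatial Gaussian (voxel units) times a
#' range Gaussian (HU), normalized per pixel; window radius three spatial
#' sigmas. Large \code{sigmaRange} degenerates to plain Gaussian filtering.
#'
#' @param image numeric matrix (HU).
#' @param sigmaSpatial spatial standard deviation in voxels, > 0.
#' @param sigmaRange range standard deviation in HU, > 0.
#' @return Filtered matrix.
#' @export
bilateralFilter <- function(image, sigmaSpatial, sigmaRange) {
  stopifnot(sigmaSpatial > 0, sigmaRange > 0)
  .bilateral_cpp(image, sigmaSpatial, sigmaRange)
}

#' Fit the bilateral denoiser by sequential model-based optimization
#'
#' Selects (sigmaSpatial, sigmaRange) by maximizing the mean SSIM of the
#' filtered low-dose slices against the high-dose slices of the training
#' pairs, using \code{\link{runSMBO}}.
#'
#' @param trainPairs list of \linkS4class{ScanPair}s (>= 1).
#' @param searchConfig list with \code{nIter} and \code{nInit}.
#' @param seed integer seed; the fit is reproducible.
#' @param dataRange SSIM data range (HU).
#' @return Fitted state list with the selected sigmas and the HPO history.
#' @export
fitBilateral <- function(trainPairs, searchConfig = list(nIter = 12L,
                                                         nInit = 4L),
                         seed = 0L, dataRange = 2000) {
  if (!length(trainPairs)) stop("empty training set", call. = FALSE)
  space <- searchSpace(
    paramSpec("sigmaSpatial", "uniform", 0.5, 3),
    paramSpec("sigmaRange", "log-uniform", 5, 500))
  objective <- function(lambda) {
    mean(vapply(trainPairs, function(pr) {
      den <- .volumeMap(pr@low, function(sl)
        .bilateral_cpp(sl, lambda$sigmaSpatial, lambda$sigmaRange))
      ssim(den, pr@high, dataRange)
    }, numeric(1)))
  }
  hist <- runSMBO(objective, space, nIter = searchConfig$nIter,
                  nInit = searchConfig$nInit, seed = seed)
  list(method = "bilateral", sigmaSpatial = hist@bestLambda$sigmaSpatial,
       sigmaRange = hist@bestLambda$sigmaRange, history = hist, seed = seed)
}

# ---- three-layer CNN on patches -------------------------------------------

.im2colBatch <- function(A, k) {
  # A: (p, p, B) array -> (p*p*B) x k^2 matrix, zero padding, 'same' output
  p <- dim(A)[1]; B <- dim(A)[3]; r <- (k - 1L) / 2L
  P <- array(0, dim = c(p + 2L * r, p + 2L * r, B))
  P[(r + 1L):(r + p), (r + 1L):(r + p), ] <- A
  out <- matrix(0, p * p * B, k * k)
  cc <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    cc <- cc + 1L
    out[, cc] <- as.vector(P[di:(di + p - 1L), dj:(dj + p - 1L), ])
  }
  out
}

.col2imBatch <- function(M, p, B, k) {
  # adjoint of .im2colBatch: (p*p*B) x k^2 -> (p, p, B)
  r <- (k - 1L) / 2L
  P <- array(0, dim = c(p + 2L * r, p + 2L * r, B))
  cc <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    cc <- cc + 1L
    P[di:(di + p - 1L), dj:(dj + p - 1L), ] <-
      P[di:(di + p - 1L), dj:(dj + p - 1L), ] +
      array(M[, cc], dim = c(p, p, B))
  }
  P[(r + 1L):(r + p), (r + 1L):(r + p), , drop = FALSE]
}

.convForward <- function(X, W, b, p, B, k) {
  # X: (p*p*B) x Cin activation matrix -> list(col, out (p*p*B) x Cout)
  cin <- ncol(X)
  col <- matrix(0, p * p * B, k * k * cin)
  for (c in seq_len(cin))
    col[, ((c - 1L) * k * k + 1L):(c * k * k)] <-
      .im2colBatch(array(X[, c], dim = c(p, p, B)), k)
  list(col = col, out = sweep(col %*% W, 2, b, "+"))
}

.convBackward <- function(col, W, dOut, p, B, k, cin) {
  dW <- crossprod(col, dOut)
  db <- colSums(dOut)
  dcol <- dOut %*% t(W)
  dX <- matrix(0, p * p * B, cin)
  for (c in seq_len(cin)) {
    idx <- ((c - 1L) * k * k + 1L):(c * k * k)
    dX[, c] <- as.vector(.col2imBatch(dcol[, idx, drop = FALSE], p, B, k))
  }
  list(dW = dW, db = db, dX = dX)
}

# leaky ReLU (slope 0.1) keeps gradients alive in the narrow net
.lrelu <- function(x) ifelse(x > 0, x, 0.1 * x)
.lreluGrad <- function(x) ifelse(x > 0, 1, 0.1)

.cnnForward <- function(params, X, p, B) {
  k <- params$kernel
  c1 <- .convForward(X, params$W1, params$b1, p, B, k)
  a1 <- .lrelu(c1$out)
  c2 <- .convForward(a1, params$W2, params$b2, p, B, k)
  a2 <- .lrelu(c2$out)
  c3 <- .convForward(a2, params$W3, params$b3, p, B, k)
  pred <- X + c3$out  # residual connection
  list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3, pred = pred)
}

.cnnInit <- function(nFilters, kernel) {
  he <- function(fanIn, nOut) matrix(rnorm(fanIn * nOut, 0,
                                           sqrt(2 / fanIn)), fanIn, nOut)
  k2 <- kernel * kernel
  list(W1 = he(k2, nFilters), b1 = numeric(nFilters),
       W2 = he(k2 * nFilters, nFilters), b2 = numeric(nFilters),
       W3 = he(k2 * nFilters, 1L) * 0.1, b3 = numeric(1L),
       kernel = kernel, nFilters = nFilters)
}

#' Fit a small three-layer CNN denoiser
#'
#' A three-layer convolutional regressor (Conv-ReLU-Conv-ReLU-Conv with a
#' residual connection) trained on low/high-dose patch pairs with an MSE
#' loss and the Adam optimizer, at desk scale on the CPU. Images are
#' standardized by the training low-dose mean/sd; the statistics are stored
#' in the state and reapplied at inference.
#'
#' @param trainPairs list of \linkS4class{ScanPair}s.
#' @param hyperparams list with \code{learningRate}, \code{patchSize},
#'   \code{batchSize}, \code{maxIter}, \code{nFilters}, \code{kernel}.
#' @param seed integer seed; identical seed and data give identical weights.
#' @return Fitted state list including the loss trace.
#' @export
fitSmallCNN <- function(trainPairs,
                        hyperparams = list(learningRate = 5e-3,
                                           patchSize = 24L, batchSize = 6L,
                                           maxIter = 800L, nFilters = 6L,
                                           kernel = 3L),
                        seed = 0L) {
  if (!length(trainPairs)) stop("empty training set", call. = FALSE)
  hp <- modifyList(list(learningRate = 5e-3, patchSize = 24L, batchSize = 6L,
                        maxIter = 800L, nFilters = 6L, kernel = 3L),
                   hyperparams)
  ps <- as.integer(hp$patchSize); B <- as.integer(hp$batchSize)
  lows <- lapply(trainPairs, function(pr) pr@low@hu)
  highs <- lapply(trainPairs, function(pr) pr@high@hu)
  mu <- mean(unlist(lapply(lows, mean)))
  sg <- sd(unlist(lapply(lows, as.numeric)))
  if (!is.finite(sg) || sg == 0) sg <- 1

  .withSeed(.childSeed(seed, "cnn"), {
    params <- .cnnInit(hp$nFilters, as.integer(hp$kernel))
    k <- params$kernel
    mState <- vState <- lapply(params[c("W1", "b1", "W2", "b2", "W3", "b3")],
                               function(x) x * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lossTrace <- numeric(hp$maxIter)
    for (it in seq_len(hp$maxIter)) {
      X <- array(0, dim = c(ps, ps, B)); Yt <- array(0, dim = c(ps, ps, B))
      for (b in seq_len(B)) {
        # rejection-sample patches so that most are not pure air
        for (try in 1:20) {
          pidx <- sample.int(length(lows), 1L)
          d <- dim(lows[[pidx]])
          z <- sample.int(d[3], 1L)
          if (d[1] < ps || d[2] < ps)
            stop("patchSize larger than the training slices", call. = FALSE)
          i0 <- sample.int(d[1] - ps + 1L, 1L)
          j0 <- sample.int(d[2] - ps + 1L, 1L)
          patch <- lows[[pidx]][i0:(i0 + ps - 1L), j0:(j0 + ps - 1L), z]
          if (mean(patch > -900) >= 0.3 || try == 20L) break
        }
        X[, , b] <- (patch - mu) / sg
        Yt[, , b] <- (highs[[pidx]][i0:(i0 + ps - 1L), j0:(j0 + ps - 1L), z] - mu) / sg
      }
      Xm <- matrix(as.vector(X), ncol = 1L)
      fw <- .cnnForward(params, Xm, ps, B)
      resid <- fw$pred - matrix(as.vector(Yt), ncol = 1L)
      loss <- mean(resid^2)
      lossTrace[it] <- loss
      if (!is.finite(loss))
        stop(errorCondition("CNN training diverged (non-finite loss)",
                            class = c("trainingDivergedError", "error",
                                      "condition")))
      dPred <- 2 * resid / length(resid)
      g3 <- .convBackward(fw$c3$col, params$W3, dPred, ps, B, k, hp$nFilters)
      dA2 <- g3$dX * .lreluGrad(fw$c2$out)
      g2 <- .convBackward(fw$c2$col, params$W2, dA2, ps, B, k, hp$nFilters)
      dA1 <- g2$dX * .lreluGrad(fw$c1$out)
      g1 <- .convBackward(fw$c1$col, params$W1, dA1, ps, B, k, 1L)
      grads <- list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                    W3 = g3$dW, b3 = g3$db)
      for (nm in names(grads)) {
        mState[[nm]] <- beta1 * mState[[nm]] + (1 - beta1) * grads[[nm]]
        vState[[nm]] <- beta2 * vState[[nm]] + (1 - beta2) * grads[[nm]]^2
        mh <- mState[[nm]] / (1 - beta1^it)
        vh <- vState[[nm]] / (1 - beta2^it)
        params[[nm]] <- params[[nm]] - hp$learningRate * mh / (sqrt(vh) + eps)
      }
    }
    list(method = "smallcnn", params = params, mu = mu, sigma = sg,
         hyperparams = hp, lossTrace = lossTrace, seed = seed)
  })
}

.applyCNNSlice <- function(state, sl) {
  p <- nrow(sl)
  Xn <- (sl - state$mu) / state$sigma
  fw <- .cnnForward(state$params, matrix(as.vector(Xn), ncol = 1L), p, 1L)
  out <- matrix(fw$pred, p, p) * state$sigma + state$mu
  out + (mean(sl) - mean(out))   # preserve the slice mean (CT numbers)
}

.registerBuiltins <- function() {
  registerDenoiser(denoiserSpec(
    "identity", 2000L,
    fitFun = function(trainPairs, hyperparams, seed) list(method = "identity"),
    applyFun = function(state, volume) volume))
  registerDenoiser(denoiserSpec(
    "gaussian", 2005L,
    fitFun = function(trainPairs, hyperparams = list(sigma = 1.2), seed = 0L)
      list(method = "gaussian", sigma = hyperparams$sigma %||% 1.2),
    applyFun = function(state, volume) {
      kern <- .gaussKernel1d(state$sigma)
      .volumeMap(volume, function(sl) .sepFilter2(sl, kern))
    }))
  registerDenoiser(denoiserSpec(
    "bilateral", 2022L,
    fitFun = function(trainPairs, hyperparams = list(), seed = 0L)
      fitBilateral(trainPairs,
                   searchConfig = hyperparams$searchConfig %||%
                     list(nIter = 12L, nInit = 4L),
                   seed = seed),
    applyFun = function(state, volume)
      .volumeMap(volume, function(sl)
        .bilateral_cpp(sl, state$sigmaSpatial, state$sigmaRange)),
    space = searchSpace(
      paramSpec("sigmaSpatial", "uniform", 0.5, 3),
      paramSpec("sigmaRange", "log-uniform", 5, 500)),
    deterministic = FALSE))
  registerDenoiser(denoiserSpec(
    "smallcnn", 2017L,
    fitFun = function(trainPairs, hyperparams = list(), seed = 0L)
      fitSmallCNN(trainPairs, hyperparams, seed = seed),
    applyFun = function(state, volume)
      .volumeMap(volume, function(sl) .applyCNNSlice(state, sl)),
    space = searchSpace(
      paramSpec("learningRate", "log-uniform", 1e-5, 0.01),
      paramSpec("maxIter", "uniform", 100, 1000, integer = TRUE),
      paramSpec("batchSize", "uniform", 2, 16, integer = TRUE),
      paramSpec("patchSize", "uniform", 16, 48, integer = TRUE)),
    deterministic = FALSE))
}

.onLoad <- function(libname, pkgname) .registerBuiltins()
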