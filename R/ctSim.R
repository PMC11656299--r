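#' Simulation configuration
#'
#' Default settings for the paired high/low-dose scan simulator. Attenuation
#' is parameterized in Hounsfield units and converted to linear attenuation
#' via \code{muWater}; organ shapes are ellipses with seeded jitter.
#'
#' @param imageSize in-plane image size (voxels).
#' @param nAngles number of projection angles over \eqn{[0, \pi)}.
#' @param voxelSpacing in-plane voxel spacing (mm).
#' @param sliceSpacing slice spacing (mm).
#' @param nSlices integer length-2 range; the slice count of each scan is
#'   drawn uniformly from this range (a length-1 value fixes it).
#' @param photonsPerRay photons per detector bin at full dose (I0).
#' @param muWater linear attenuation of water (1/mm).
#' @param filterName reconstruction filter, "ramp" or "hann".
#' @param tissuesHU named list of tissue attenuation levels (HU) with jitter
#'   half-widths: each entry \code{c(value, jitter)}.
#' @param organJitter relative half-width of organ size/position jitter.
#' @param lesionRadiusMM lesion radius range (mm).
#' @param nLesions number of lesions per scan.
#' @return A named list of simulator settings.
#' @export
ctSimConfig <- function(imageSize = 256L, nAngles = 512L, voxelSpacing = 1,
                        sliceSpacing = 3, nSlices = c(8L, 32L),
                        photonsPerRay = 1e5, muWater = 0.02,
                        filterName = "hann",
                        tissuesHU = list(soft = c(40, 10), liver = c(55, 10),
                                         brain = c(35, 5), lung = c(-700, 50),
                                         bone = c(800, 100),
                                         lesionContrast = c(-35, 10),
                                         lungLesion = c(-400, 50)),
                        organJitter = 0.1, lesionRadiusMM = c(4, 9),
                        nLesions = 1L) {
  list(imageSize = as.integer(imageSize), nAngles = as.integer(nAngles),
       voxelSpacing = voxelSpacing, sliceSpacing = sliceSpacing,
       nSlices = as.integer(nSlices), photonsPerRay = photonsPerRay,
       muWater = muWater, filterName = filterName, tissuesHU = tissuesHU,
       organJitter = organJitter, lesionRadiusMM = lesionRadiusMM,
       nLesions = as.integer(nLesions))
}

.huToMu <- function(hu, muWater) pmax(muWater * (1 + hu / 1000), 0)

.ellipseMask <- function(X, Y, cx, cy, ax, ay) {
  ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1
}

#' Generate a parametric digital phantom
#'
#' Builds a 3-D phantom for one exam type: a soft-tissue body ellipse, the
#' exam type's organ (abdomen: liver; head: brain inside a bone rim; chest:
#' two lungs), and at least one low-contrast lesion inside the organ. All
#' sizes and positions are drawn deterministically from the seed.
#'
#' @param examType one of "abdomen", "head", "chest".
#' @param seed integer seed; the same seed and config give a bit-identical
#'   phantom.
#' @param config a \code{\link{ctSimConfig}} list.
#' @return A \linkS4class{Phantom}.
#' @export
makePhantom <- function(examType, seed, config = ctSimConfig()) {
  if (!(is.character(examType) && length(examType) == 1L &&
        examType %in% EXAM_TYPES))
    stop("unknown examType: must be one of abdomen, head, chest",
         call. = FALSE)
  seed <- as.integer(seed)
  .withSeed(.childSeed(seed, paste0("phantom-", examType)), {
    n <- config$imageSize
    fov <- n * config$voxelSpacing
    ctr <- (seq_len(n) - (n + 1) / 2) * config$voxelSpacing
    X <- matrix(ctr, n, n)
    Y <- matrix(ctr, n, n, byrow = TRUE)
    nz <- if (length(config$nSlices) > 1L)
      sample(config$nSlices[1]:config$nSlices[2], 1L) else config$nSlices[1]

    jit <- function(x) x * (1 + runif(1, -config$organJitter, config$organJitter))
    tis <- function(nm) {
      t <- config$tissuesHU[[nm]]
      t[1] + runif(1, -t[2], t[2])
    }
    softHU <- tis("soft"); boneHU <- tis("bone")
    organ <- EXAM_ORGAN[[examType]]

    # body outline and per-exam organ layout (mm, relative to fov)
    if (examType == "head") {
      bodyAx <- jit(0.32 * fov); bodyAy <- jit(0.38 * fov)
    } else {
      bodyAx <- jit(0.43 * fov); bodyAy <- jit(0.33 * fov)
    }
    bodyCx <- runif(1, -0.02, 0.02) * fov
    bodyCy <- runif(1, -0.02, 0.02) * fov

    organHU <- switch(examType, abdomen = tis("liver"), head = tis("brain"),
                      chest = tis("lung"))
    lesHU <- if (examType == "chest") tis("lungLesion")
             else organHU + tis("lesionContrast")

    hu <- array(-1000, dim = c(n, n, nz))
    bodyM <- organM <- array(FALSE, dim = c(n, n, nz))
    zc <- if (nz == 1L) 0 else (seq_len(nz) - (nz + 1) / 2) / (nz / 2)

    for (k in seq_len(nz)) {
      bsc <- sqrt(pmax(1 - 0.25 * zc[k]^2, 0))
      body <- .ellipseMask(X, Y, bodyCx, bodyCy, bodyAx * bsc, bodyAy * bsc)
      sl <- matrix(-1000, n, n)
      sl[body] <- softHU
      org <- matrix(FALSE, n, n)
      if (examType == "abdomen") {
        osc <- sqrt(pmax(1 - 0.5 * zc[k]^2, 0))
        org <- .ellipseMask(X, Y, bodyCx - jit(0.12 * fov),
                            bodyCy + jit(0.05 * fov),
                            0.20 * fov * osc * jit(1), 0.15 * fov * osc * jit(1))
        org <- org & body
        sl[org] <- organHU
        spine <- .ellipseMask(X, Y, bodyCx, bodyCy - 0.22 * fov,
                              0.05 * fov, 0.05 * fov) & body
        sl[spine] <- boneHU
      } else if (examType == "head") {
        skullOut <- body
        skullIn <- .ellipseMask(X, Y, bodyCx, bodyCy, bodyAx * bsc * 0.88,
                                bodyAy * bsc * 0.88)
        sl[skullOut & !skullIn] <- boneHU
        prof <- 1 - (zc[k] / 0.9)^2
        if (prof > 0.05) {
          psc <- sqrt(prof)
          org <- .ellipseMask(X, Y, bodyCx, bodyCy, bodyAx * bsc * 0.80 * psc,
                              bodyAy * bsc * 0.80 * psc) & skullIn
          sl[org] <- organHU
        }
      } else { # chest
        prof <- 1 - (zc[k] / 0.95)^2
        if (prof > 0.05) {
          psc <- sqrt(prof)
          lx <- jit(0.17 * fov)
          for (s in c(-1, 1)) {
            lung1 <- .ellipseMask(X, Y, bodyCx + s * lx,
                                  bodyCy + 0.02 * fov,
                                  0.14 * fov * psc, 0.22 * fov * psc) & body
            org <- org | lung1
          }
          sl[org] <- organHU
        }
        spine <- .ellipseMask(X, Y, bodyCx, bodyCy - 0.21 * fov,
                              0.045 * fov, 0.045 * fov) & body
        sl[spine] <- boneHU
      }
      hu[, , k] <- sl
      bodyM[, , k] <- body
      organM[, , k] <- org
    }

    # place low-contrast lesions fully inside the organ mask
    lesions <- list()
    vox <- config$voxelSpacing
    for (li in seq_len(config$nLesions)) {
      rMM <- runif(1, config$lesionRadiusMM[1], config$lesionRadiusMM[2])
      placed <- FALSE
      for (attempt in seq_len(300L)) {
        rv <- max(1L, as.integer(round(rMM / vox)))
        zs <- which(apply(organM, 3, sum) > 0)
        if (!length(zs)) break
        k <- if (length(zs) == 1L) zs else sample(zs, 1L)
        cand <- which(organM[, , k], arr.ind = TRUE)
        cc <- cand[sample.int(nrow(cand), 1L), ]
        disk <- (X - ctr[cc[1]])^2 + (Y - ctr[cc[2]])^2 <= (rv * vox)^2
        rng <- range(which(disk, arr.ind = TRUE)[, 1])
        rngY <- range(which(disk, arr.ind = TRUE)[, 2])
        # the whole bounding box (not just the disk) must sit in the organ
        if (all(organM[rng[1]:rng[2], rngY[1]:rngY[2], k])) {
          sl <- hu[, , k]
          sl[disk] <- lesHU
          hu[, , k] <- sl
          lesions[[length(lesions) + 1L]] <- list(
            box = as.integer(c(rng[1] - 1L, rng[2], rngY[1] - 1L, rngY[2],
                               k - 1L, k)),
            label = sprintf("lesion-%d", li), organ = organ)
          placed <- TRUE
          break
        }
        if (attempt %% 50L == 0L) rMM <- max(rMM * 0.8, vox)
      }
      if (!placed)
        warning("could not place a lesion inside the organ mask")
    }

    masks <- list(body = bodyM)
    masks[[organ]] <- organM
    new("Phantom", attenuationMap = .huToMu(hu, config$muWater),
        voxelSpacing = c(config$voxelSpacing, config$sliceSpacing),
        organMasks = masks, lesionBoxes = lesions, examType = examType,
        patientId = sprintf("%s-%05d", examType, seed %% 100000L),
        seed = seed)
  })
}

#' Forward projection (discrete parallel-beam Radon transform)
#'
#' Computes mm-weighted line integrals of a 2-D attenuation image for every
#' (angle, detector) pair of the geometry. The operator is linear and its
#' exact matrix transpose is \code{\link{backProject}}.
#'
#' @param image square numeric matrix of linear attenuation (1/mm), side
#'   length equal to \code{geometry@imageSize}.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param photonsPerRay full-dose photon count recorded on the sinogram.
#' @return A \linkS4class{Sinogram} at dose fraction 1.
#' @export
forwardProject <- function(image, geometry, photonsPerRay = 1e5) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix", call. = FALSE)
  if (nrow(image) != geometry@imageSize)
    stop("image does not fit the geometry's field of view", call. = FALSE)
  sino <- t(.forward_project_cpp(image, geometry@angles,
                                 geometry@nDetectors, geometry@detSpacing,
                                 geometry@voxelSpacing))
  new("Sinogram", data = sino, geometry = geometry, doseFraction = 1,
      photonsPerRay = photonsPerRay)
}

#' Unfiltered backprojection (adjoint of the forward projector)
#'
#' @param sinogram a \linkS4class{Sinogram} (or a numeric matrix with
#'   \code{geometry} supplied).
#' @param geometry a \linkS4class{ScanGeometry}; defaults to the sinogram's.
#' @return Numeric matrix, the adjoint image \eqn{R^T p}.
#' @export
backProject <- function(sinogram, geometry = NULL) {
  if (is(sinogram, "Sinogram")) {
    if (is.null(geometry)) geometry <- sinogram@geometry
    sinogram <- sinogram@data
  }
  scale <- geometry@voxelSpacing^2 / geometry@detSpacing
  .backproject_cpp(t(sinogram), geometry@angles, geometry@imageSize,
                   geometry@detSpacing, geometry@voxelSpacing) * scale
}

#' Projection-domain noise insertion
#'
#' Simulates a reduced-dose acquisition: per detector bin, transmitted
#' photon counts are drawn as Poisson with mean \eqn{d I_0 e^{-p}} and the
#' noisy line integral recovered as
#' \eqn{p' = -\log(\max(N, 1) / (d I_0))}. Counts are clamped at one photon
#' so that opaque rays stay finite.
#'
#' @param sinogram a \linkS4class{Sinogram} of noiseless (or routine-dose)
#'   line integrals.
#' @param doseFraction dose fraction d in (0, 1].
#' @param photonsPerRay full-dose photons per ray I0 (> 0).
#' @param seed integer seed; draws are reproducible.
#' @return A \linkS4class{Sinogram} with noisy line integrals.
#' @export
insertNoise <- function(sinogram, doseFraction, photonsPerRay =
                          sinogram@photonsPerRay, seed = 0L) {
  if (!(doseFraction > 0 && doseFraction <= 1))
    stop("doseFraction must lie in (0, 1]", call. = FALSE)
  if (!(photonsPerRay > 0)) stop("photonsPerRay must be > 0", call. = FALSE)
  p <- sinogram@data
  lam <- doseFraction * photonsPerRay * exp(-p)
  counts <- .withSeed(seed, {
    big <- lam > 1e9      # normal approximation where rpois would overflow
    out <- numeric(length(lam))
    if (any(!big)) out[!big] <- rpois(sum(!big), lam[!big])
    if (any(big)) out[big] <- round(rnorm(sum(big), lam[big], sqrt(lam[big])))
    out
  })
  pnoisy <- -log(pmax(counts, 1) / (doseFraction * photonsPerRay))
  new("Sinogram", data = matrix(pnoisy, nrow(p), ncol(p)),
      geometry = sinogram@geometry, doseFraction = doseFraction,
      photonsPerRay = photonsPerRay)
}

.rampFilterFreq <- function(nDet, detSpacing, filterName, padLen) {
  # band-limited ramp (Ram-Lak) defined from its spatial-domain samples
  h <- numeric(padLen)
  h[1] <- 1 / (4 * detSpacing^2)
  nOdd <- seq(1, padLen / 2, by = 2)
  h[nOdd + 1] <- -1 / (pi * nOdd * detSpacing)^2
  h[padLen + 1 - nOdd] <- -1 / (pi * nOdd * detSpacing)^2
  H <- Re(fft(h))
  if (filterName == "hann") {
    f <- pmin(seq_len(padLen) - 1, padLen - (seq_len(padLen) - 1)) / padLen
    H <- H * 0.5 * (1 + cos(2 * pi * f))
  }
  H
}

#' Filtered back projection
#'
#' Ramp (Ram-Lak) or Hann-apodized ramp filtering of each projection via FFT,
#' followed by linear-interpolation backprojection. Linear in the sinogram.
#'
#' @param sinogram a \linkS4class{Sinogram}.
#' @param filterName "ramp" or "hann" (Hann-apodized ramp).
#' @param geometry reconstruction geometry; defaults to the sinogram's.
#' @return Numeric matrix of reconstructed linear attenuation (1/mm).
#' @export
fbp <- function(sinogram, filterName = c("ramp", "hann"), geometry = NULL) {
  filterName <- match.arg(filterName)
  if (is(sinogram, "Sinogram")) {
    if (is.null(geometry)) geometry <- sinogram@geometry
    sinogram <- sinogram@data
  }
  na <- length(geometry@angles)
  if (na < 2L) stop("at least 2 projection angles required", call. = FALSE)
  nd <- geometry@nDetectors
  padLen <- 2^ceiling(log2(2 * nd))
  H <- .rampFilterFreq(nd, geometry@detSpacing, filterName, padLen)
  P <- matrix(0, padLen, na)
  P[seq_len(nd), ] <- t(sinogram)
  Q <- Re(mvfft(mvfft(P) * H, inverse = TRUE)) / padLen
  Q <- Q[seq_len(nd), , drop = FALSE] * geometry@detSpacing
  .backproject_cpp(Q, geometry@angles, geometry@imageSize,
                   geometry@detSpacing, geometry@voxelSpacing) * (pi / na)
}

#' Convert linear attenuation to Hounsfield units
#'
#' \eqn{HU = 1000 (\mu - \mu_{water}) / \mu_{water}}.
#'
#' @param attenuationImage numeric matrix or 3-D array of attenuation (1/mm).
#' @param muWater linear attenuation of water (1/mm), > 0.
#' @param examType,patientId,doseTag,voxelSpacing volume metadata.
#' @return A \linkS4class{CTVolume}.
#' @export
toHU <- function(attenuationImage, muWater = 0.02, examType = "abdomen",
                 patientId = "anon", doseTag = "high",
                 voxelSpacing = c(1, 1)) {
  if (!(muWater > 0)) stop("muWater must be > 0", call. = FALSE)
  hu <- 1000 * (attenuationImage - muWater) / muWater
  if (is.matrix(hu)) hu <- array(hu, dim = c(dim(hu), 1L))
  new("CTVolume", hu = hu, voxelSpacing = voxelSpacing, examType = examType,
      patientId = patientId, doseTag = doseTag)
}

.reconVolume <- function(phantom, geometry, dose, seedKey, config, doseTag) {
  slices <- .asSlices(phantom@attenuationMap)
  hu <- array(0, dim = dim(phantom@attenuationMap))
  for (k in seq_along(slices)) {
    sino <- forwardProject(slices[[k]], geometry, config$photonsPerRay)
    noisy <- insertNoise(sino, dose, config$photonsPerRay,
                         .childSeed(seedKey, paste0("slice-", k)))
    rec <- fbp(noisy, config$filterName)
    hu[, , k] <- 1000 * (rec - config$muWater) / config$muWater
  }
  new("CTVolume", hu = hu, voxelSpacing = phantom@voxelSpacing,
      examType = phantom@examType, patientId = phantom@patientId,
      doseTag = doseTag)
}

#' Simulate a paired high/low-dose scan
#'
#' Builds a phantom, forward projects each axial slice, draws full-dose and
#' reduced-dose photon counts in the projection domain, and reconstructs
#' both with filtered back projection. High- and low-dose volumes share the
#' phantom grid, organ masks and lesion boxes. The default dose fraction is
#' 0.25 for abdomen and head and 0.10 for chest.
#'
#' @param examType one of "abdomen", "head", "chest".
#' @param doseFraction dose fraction in (0, 1]; NULL resolves the exam-type
#'   default.
#' @param seed integer seed; the whole pair is reproducible from it.
#' @param config a \code{\link{ctSimConfig}} list.
#' @return A \linkS4class{ScanPair}.
#' @export
simulateCase <- function(examType, doseFraction = NULL, seed = 0L,
                         config = ctSimConfig()) {
  if (!(examType %in% EXAM_TYPES))
    stop("unknown examType: must be one of abdomen, head, chest",
         call. = FALSE)
  if (is.null(doseFraction)) doseFraction <- EXAM_DOSE[[examType]]
  seed <- as.integer(seed)
  phantom <- makePhantom(examType, seed, config)
  geometry <- scanGeometry(config$imageSize, config$nAngles,
                           config$voxelSpacing)
  high <- .reconVolume(phantom, geometry, 1, .childSeed(seed, "hd"), config,
                       "high")
  low <- .reconVolume(phantom, geometry, doseFraction,
                      .childSeed(seed, "ld"), config, "low")
  new("ScanPair", high = high, low = low, organMasks = phantom@organMasks,
      lesionBoxes = phantom@lesionBoxes, seed = seed)
}

#' Simulate a dataset of paired scans
#'
#' @param scansPerType named integer vector, scans per exam type.
#' @param seed integer master seed; per-scan seeds are derived from it.
#' @param config a \code{\link{ctSimConfig}} list.
#' @param examTypes exam types to simulate.
#' @return A list of \linkS4class{ScanPair}s.
#' @export
simulateDataset <- function(scansPerType = c(abdomen = 2L, head = 2L,
                                             chest = 2L),
                            seed = 0L, config = ctSimConfig(),
                            examTypes = names(scansPerType)) {
  pairs <- list()
  for (et in examTypes) {
    for (i in seq_len(scansPerType[[et]])) {
      s <- .childSeed(seed, sprintf("%s-%d", et, i))
      pairs[[length(pairs) + 1L]] <- simulateCase(et, NULL, s, config)
    }
  }
  pairs
}
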