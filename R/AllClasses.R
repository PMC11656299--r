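#' @import methods
#' @importFrom stats approx dnorm pnorm qnorm rnorm runif rpois sd var median
#'   quantile optim fft mvfft ecdf pwilcox setNames aggregate
#' @importFrom utils head tail combn modifyList
#' @useDynLib CTDenoiseBench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

EXAM_TYPES <- c("abdomen", "head", "chest")
EXAM_ORGAN <- c(abdomen = "liver", head = "brain", chest = "lung")
EXAM_DOSE <- c(abdomen = 0.25, head = 0.25, chest = 0.10)

#' Parallel-beam acquisition geometry
#'
#' Describes a 2-D parallel-beam geometry applied slice-wise to volumes: a
#' linear detector with \code{nDetectors} bins spaced \code{detSpacing} mm
#' apart and a set of projection angles in \eqn{[0, \pi)}.
#'
#' @slot nDetectors integer, number of detector bins.
#' @slot detSpacing numeric, detector bin spacing in mm.
#' @slot angles numeric vector of strictly increasing projection angles
#'   (radians) in \eqn{[0, \pi)}.
#' @slot imageSize integer, in-plane image size in voxels (square images).
#' @slot voxelSpacing numeric, in-plane voxel spacing in mm.
#' @export
setClass("ScanGeometry",
  representation(nDetectors = "integer", detSpacing = "numeric",
                 angles = "numeric", imageSize = "integer",
                 voxelSpacing = "numeric"))

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (length(object@angles) < 1L || is.unsorted(object@angles, strictly = TRUE))
    msg <- c(msg, "angles must be strictly increasing")
  if (any(object@angles < 0) || any(object@angles >= pi))
    msg <- c(msg, "angles must lie in [0, pi)")
  diag_mm <- sqrt(2) * object@imageSize * object@voxelSpacing
  if (object@nDetectors * object@detSpacing < diag_mm)
    msg <- c(msg, "detector row must cover the image diagonal")
  if (object@detSpacing <= 0 || object@voxelSpacing <= 0)
    msg <- c(msg, "spacings must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a parallel-beam geometry
#'
#' @param imageSize in-plane image size in voxels.
#' @param nAngles number of projection angles, equispaced over \eqn{[0, \pi)}.
#' @param voxelSpacing voxel spacing in mm.
#' @param detSpacing detector spacing in mm (defaults to the voxel spacing).
#' @param nDetectors number of detector bins; default is the smallest odd
#'   count covering the image diagonal.
#' @return A \linkS4class{ScanGeometry}.
#' @export
scanGeometry <- function(imageSize, nAngles, voxelSpacing = 1,
                         detSpacing = voxelSpacing, nDetectors = NULL) {
  if (is.null(nDetectors)) {
    nDetectors <- ceiling(sqrt(2) * imageSize * voxelSpacing / detSpacing)
    if (nDetectors %% 2L == 0L) nDetectors <- nDetectors + 1L
  }
  new("ScanGeometry", nDetectors = as.integer(nDetectors),
      detSpacing = detSpacing,
      angles = seq(0, pi, length.out = nAngles + 1L)[seq_len(nAngles)],
      imageSize = as.integer(imageSize), voxelSpacing = voxelSpacing)
}

#' Sinogram: parallel-beam line integrals
#'
#' @slot data numeric matrix [angle x detector] of dimensionless line
#'   integrals of the linear attenuation coefficient (mm-weighted).
#' @slot geometry the \linkS4class{ScanGeometry} the data were measured under.
#' @slot doseFraction dose fraction d in (0, 1] relative to routine dose.
#' @slot photonsPerRay photons per detector bin at full dose (I0).
#' @export
setClass("Sinogram",
  representation(data = "matrix", geometry = "ScanGeometry",
                 doseFraction = "numeric", photonsPerRay = "numeric"))

setValidity("Sinogram", function(object) {
  msg <- character()
  if (!all(is.finite(object@data))) msg <- c(msg, "sinogram data must be finite")
  if (nrow(object@data) != length(object@geometry@angles) ||
      ncol(object@data) != object@geometry@nDetectors)
    msg <- c(msg, "data dimensions must match geometry [angle x detector]")
  if (object@doseFraction <= 0 || object@doseFraction > 1)
    msg <- c(msg, "doseFraction must lie in (0, 1]")
  if (object@photonsPerRay <= 0) msg <- c(msg, "photonsPerRay must be positive")
  if (length(msg)) msg else TRUE
})

#' Reconstructed CT volume in Hounsfield units
#'
#' @slot hu 3-D numeric array of Hounsfield units (x, y, z).
#' @slot voxelSpacing numeric length-2: in-plane spacing and slice spacing, mm.
#' @slot examType one of "abdomen", "head", "chest".
#' @slot patientId character scan/patient identifier.
#' @slot doseTag "high", "low" or "denoised:<method>".
#' @export
setClass("CTVolume",
  representation(hu = "array", voxelSpacing = "numeric",
                 examType = "character", patientId = "character",
                 doseTag = "character"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@hu)) != 3L) msg <- c(msg, "hu must be a 3-D array")
  if (!all(is.finite(object@hu))) msg <- c(msg, "hu must be finite")
  if (!(object@examType %in% EXAM_TYPES))
    msg <- c(msg, "unknown examType")
  if (!grepl("^(high|low|denoised:.+)$", object@doseTag))
    msg <- c(msg, "doseTag must be high, low or denoised:<method>")
  if (length(msg)) msg else TRUE
})

#' Digital phantom: attenuation map, organ masks and lesions
#'
#' @slot attenuationMap 3-D array of linear attenuation coefficients (1/mm),
#'   all values >= 0.
#' @slot voxelSpacing numeric length-2 (in-plane, slice) spacing in mm.
#' @slot organMasks named list of logical arrays congruent with the
#'   attenuation map; contains "body" plus the exam type's organ
#'   ("liver", "brain" or "lung").
#' @slot lesionBoxes list of lesions, each \code{list(box, label, organ)} with
#'   \code{box} an integer vector \code{c(x0, x1, y0, y1, z0, z1)} in 0-based
#'   half-open voxel coordinates.
#' @slot examType,patientId,seed scan metadata.
#' @export
setClass("Phantom",
  representation(attenuationMap = "array", voxelSpacing = "numeric",
                 organMasks = "list", lesionBoxes = "list",
                 examType = "character", patientId = "character",
                 seed = "integer"))

.boxVoxels <- function(box) {
  # 0-based half-open box -> 1-based index grid
  expand.grid(x = (box[1] + 1L):box[2], y = (box[3] + 1L):box[4],
              z = (box[5] + 1L):box[6])
}

setValidity("Phantom", function(object) {
  msg <- character()
  if (any(object@attenuationMap < 0))
    msg <- c(msg, "attenuation values must be >= 0")
  if (!"body" %in% names(object@organMasks))
    msg <- c(msg, "organMasks must contain a body mask")
  organ <- EXAM_ORGAN[[object@examType]]
  if (!organ %in% names(object@organMasks))
    msg <- c(msg, sprintf("organMasks must contain '%s' for %s scans",
                          organ, object@examType))
  dm <- dim(object@attenuationMap)
  for (nm in names(object@organMasks)) {
    m <- object@organMasks[[nm]]
    if (!identical(dim(m), dm))
      msg <- c(msg, sprintf("mask '%s' not congruent with attenuation map", nm))
    else if (nm != "body" && any(m & !object@organMasks[["body"]]))
      msg <- c(msg, sprintf("mask '%s' extends outside the body mask", nm))
  }
  for (les in object@lesionBoxes) {
    b <- les$box
    if (any(b[c(1, 3, 5)] < 0) || b[2] > dm[1] || b[4] > dm[2] || b[6] > dm[3] ||
        any(b[c(2, 4, 6)] <= b[c(1, 3, 5)])) {
      msg <- c(msg, "lesion box outside volume or empty")
      next
    }
    idx <- as.matrix(.boxVoxels(b))
    if (!all(object@organMasks[[les$organ]][idx]))
      msg <- c(msg, sprintf("lesion box not contained in organ mask '%s'",
                            les$organ))
  }
  if (length(msg)) msg else TRUE
})

#' Paired high-dose / low-dose scan
#'
#' The unit of evaluation: a routine-dose reconstruction, its simulated
#' low-dose counterpart, and the organ masks and lesion boxes shared by both.
#'
#' @slot high,low \linkS4class{CTVolume}s on the same grid and patient.
#' @slot organMasks,lesionBoxes as in \linkS4class{Phantom}.
#' @slot seed integer seed the pair was simulated from.
#' @export
setClass("ScanPair",
  representation(high = "CTVolume", low = "CTVolume", organMasks = "list",
                 lesionBoxes = "list", seed = "integer"))

setValidity("ScanPair", function(object) {
  msg <- character()
  if (!identical(dim(object@high@hu), dim(object@low@hu)))
    msg <- c(msg, "high and low volumes must share the grid")
  if (!identical(object@high@patientId, object@low@patientId))
    msg <- c(msg, "high and low volumes must share patient identity")
  if (!identical(object@high@examType, object@low@examType))
    msg <- c(msg, "high and low volumes must share exam type")
  if (length(msg)) msg else TRUE
})

#' Radiomic feature matrix for one scan
#'
#' Rows are algorithms (row 1 = the high-dose reference, index 0), columns
#' are radiomic features.
#'
#' @slot values numeric matrix with rownames = algorithm names (first = "HD")
#'   and colnames = feature names.
#' @slot scanId character.
#' @slot normalized logical; TRUE after per-feature min-max normalization.
#' @slot droppedFeatures character, features removed as degenerate.
#' @slot extractionConfig list fingerprint of the extraction settings.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", scanId = "character",
                 normalized = "logical", droppedFeatures = "character",
                 extractionConfig = "list"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@values))) msg <- c(msg, "feature values must be finite")
  if (nrow(object@values) < 1L || is.null(rownames(object@values)))
    msg <- c(msg, "values must have named algorithm rows")
  if (ncol(object@values) < 1L)
    msg <- c(msg, "at least one feature required (J >= 1)")
  if (length(msg)) msg else TRUE
})

#' Hyperparameter search space
#'
#' An ordered list of parameter specifications; each is a list with fields
#' \code{name}, \code{prior} ("uniform" or "log-uniform"), \code{lower},
#' \code{upper} and \code{integer}.
#'
#' @slot params named list of parameter specs.
#' @export
setClass("SearchSpace", representation(params = "list"))

setValidity("SearchSpace", function(object) {
  msg <- character()
  if (length(object@params) < 1L) msg <- c(msg, "at least one parameter required")
  nms <- vapply(object@params, function(p) p$name, character(1))
  if (anyDuplicated(nms)) msg <- c(msg, "parameter names must be unique")
  for (p in object@params) {
    if (!p$prior %in% c("uniform", "log-uniform"))
      msg <- c(msg, sprintf("unknown prior '%s'", p$prior))
    if (!(p$lower < p$upper))
      msg <- c(msg, sprintf("bounds of '%s' must satisfy lower < upper", p$name))
    if (p$prior == "log-uniform" && p$lower <= 0)
      msg <- c(msg, sprintf("log-uniform '%s' requires lower > 0", p$name))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a search space
#'
#' @param ... parameter specs created with \code{\link{paramSpec}}.
#' @return A \linkS4class{SearchSpace}.
#' @export
searchSpace <- function(...) {
  ps <- list(...)
  names(ps) <- vapply(ps, function(p) p$name, character(1))
  new("SearchSpace", params = ps)
}

#' Specify one hyperparameter
#'
#' @param name parameter name.
#' @param prior "uniform" or "log-uniform".
#' @param lower,upper bounds (lower > 0 for log-uniform).
#' @param integer logical; TRUE for integer-valued parameters (sampled and
#'   proposed in continuous relaxation, rounded to the nearest integer at
#'   evaluation time and clamped to the bounds).
#' @return A parameter spec list.
#' @export
paramSpec <- function(name, prior = c("uniform", "log-uniform"), lower, upper,
                      integer = FALSE) {
  list(name = name, prior = match.arg(prior), lower = lower, upper = upper,
       integer = isTRUE(integer))
}

#' History of a sequential model-based optimization run
#'
#' @slot trials data.frame with columns \code{iteration}, \code{objective},
#'   \code{failed} and one column per hyperparameter.
#' @slot space the \linkS4class{SearchSpace} searched.
#' @slot bestLambda named list, the best configuration found.
#' @slot bestObjective numeric, max of the trial objectives.
#' @slot metricName name of the optimized validation metric.
#' @slot seed integer seed of the run.
#' @export
setClass("HPOHistory",
  representation(trials = "data.frame", space = "SearchSpace",
                 bestLambda = "list", bestObjective = "numeric",
                 metricName = "character", seed = "integer"))

setValidity("HPOHistory", function(object) {
  ok <- !object@trials$failed
  if (any(ok) &&
      abs(object@bestObjective - max(object@trials$objective[ok])) > 1e-12)
    "bestObjective must equal the max over non-failed trials" else TRUE
})

#' Denoiser plugin specification
#'
#' The plugin contract every evaluated method implements: a \code{fit}
#' function \code{(trainPairs, hyperparams, seed) -> state} and an
#' \code{apply} function \code{(state, volume) -> volume}.
#'
#' @slot name method name (registry key).
#' @slot year publication year, used for "previously published best" ordering.
#' @slot space hyperparameter \linkS4class{SearchSpace} (may be empty).
#' @slot fitFun,applyFun the training and inference contracts.
#' @slot deterministic logical; TRUE if apply is deterministic given state.
#' @export
setClass("DenoiserSpec",
  representation(name = "character", year = "integer", space = "ANY",
                 fitFun = "function", applyFun = "function",
                 deterministic = "logical"))

setValidity("DenoiserSpec", function(object) {
  if (length(object@year) != 1L || is.na(object@year))
    "a publication year must be declared" else TRUE
})
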