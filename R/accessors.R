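#' @name accessors
#' @title Accessors for CTDenoiseBench objects
#' @description Slot accessors for the core S4 classes.
#' @param object an object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("huData", function(object) standardGeneric("huData"))
#' @rdname accessors
#' @export
setMethod("huData", "CTVolume", function(object) object@hu)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(object) object@voxelSpacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "Phantom", function(object) object@voxelSpacing)

#' @rdname accessors
#' @export
setGeneric("examType", function(object) standardGeneric("examType"))
#' @rdname accessors
#' @export
setMethod("examType", "CTVolume", function(object) object@examType)
#' @rdname accessors
#' @export
setMethod("examType", "Phantom", function(object) object@examType)
#' @rdname accessors
#' @export
setMethod("examType", "ScanPair", function(object) object@high@examType)

#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setMethod("patientId", "CTVolume", function(object) object@patientId)
#' @rdname accessors
#' @export
setMethod("patientId", "Phantom", function(object) object@patientId)
#' @rdname accessors
#' @export
setMethod("patientId", "ScanPair", function(object) object@high@patientId)

#' @rdname accessors
#' @export
setGeneric("doseTag", function(object) standardGeneric("doseTag"))
#' @rdname accessors
#' @export
setMethod("doseTag", "CTVolume", function(object) object@doseTag)

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "Sinogram", function(object) object@geometry)

#' @rdname accessors
#' @export
setGeneric("sinoData", function(object) standardGeneric("sinoData"))
#' @rdname accessors
#' @export
setMethod("sinoData", "Sinogram", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("doseFraction", function(object) standardGeneric("doseFraction"))
#' @rdname accessors
#' @export
setMethod("doseFraction", "Sinogram", function(object) object@doseFraction)

#' @rdname accessors
#' @export
setGeneric("organMasks", function(object) standardGeneric("organMasks"))
#' @rdname accessors
#' @export
setMethod("organMasks", "Phantom", function(object) object@organMasks)
#' @rdname accessors
#' @export
setMethod("organMasks", "ScanPair", function(object) object@organMasks)

#' @rdname accessors
#' @export
setGeneric("lesionBoxes", function(object) standardGeneric("lesionBoxes"))
#' @rdname accessors
#' @export
setMethod("lesionBoxes", "Phantom", function(object) object@lesionBoxes)
#' @rdname accessors
#' @export
setMethod("lesionBoxes", "ScanPair", function(object) object@lesionBoxes)

#' @rdname accessors
#' @export
setGeneric("attenuationMap", function(object) standardGeneric("attenuationMap"))
#' @rdname accessors
#' @export
setMethod("attenuationMap", "Phantom", function(object) object@attenuationMap)

#' @rdname accessors
#' @export
setGeneric("highDose", function(object) standardGeneric("highDose"))
#' @rdname accessors
#' @export
setMethod("highDose", "ScanPair", function(object) object@high)

#' @rdname accessors
#' @export
setGeneric("lowDose", function(object) standardGeneric("lowDose"))
#' @rdname accessors
#' @export
setMethod("lowDose", "ScanPair", function(object) object@low)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "FeatureMatrix", function(object) object@normalized)

#' @rdname accessors
#' @export
setGeneric("trials", function(object) standardGeneric("trials"))
#' @rdname accessors
#' @export
setMethod("trials", "HPOHistory", function(object) object@trials)

#' @rdname accessors
#' @export
setGeneric("bestLambda", function(object) standardGeneric("bestLambda"))
#' @rdname accessors
#' @export
setMethod("bestLambda", "HPOHistory", function(object) object@bestLambda)

#' @rdname accessors
#' @export
setGeneric("bestObjective", function(object) standardGeneric("bestObjective"))
#' @rdname accessors
#' @export
setMethod("bestObjective", "HPOHistory", function(object) object@bestObjective)

#' @rdname accessors
#' @export
setGeneric("paramNames", function(object) standardGeneric("paramNames"))
#' @rdname accessors
#' @export
setMethod("paramNames", "SearchSpace",
          function(object) vapply(object@params, `[[`, character(1), "name"))

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf("ScanGeometry: %d x %d image @ %g mm, %d angles, %d detectors @ %g mm\n",
              object@imageSize, object@imageSize, object@voxelSpacing,
              length(object@angles), object@nDetectors, object@detSpacing))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angles x %d detectors, dose fraction %.2f, I0 = %g\n",
              nrow(object@data), ncol(object@data), object@doseFraction,
              object@photonsPerRay))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@hu)
  cat(sprintf("CTVolume [%s/%s]: %d x %d x %d, %s, HU range [%.0f, %.0f]\n",
              object@examType, object@doseTag, d[1], d[2], d[3],
              object@patientId, min(object@hu), max(object@hu)))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@attenuationMap)
  cat(sprintf("Phantom [%s, %s]: %d x %d x %d, masks: %s, %d lesion(s)\n",
              object@examType, object@patientId, d[1], d[2], d[3],
              paste(names(object@organMasks), collapse = ", "),
              length(object@lesionBoxes)))
})

setMethod("show", "ScanPair", function(object) {
  d <- dim(object@high@hu)
  cat(sprintf("ScanPair [%s, %s]: %d x %d x %d, %d lesion(s), seed %d\n",
              examType(object), patientId(object), d[1], d[2], d[3],
              length(object@lesionBoxes), object@seed))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d algorithm(s) x %d feature(s)%s\n",
              object@scanId, nrow(object@values), ncol(object@values),
              if (object@normalized) ", normalized" else ""))
})

setMethod("show", "HPOHistory", function(object) {
  cat(sprintf("HPOHistory: %d trial(s), best %s = %.6g\n",
              nrow(object@trials), object@metricName, object@bestObjective))
})

setMethod("show", "DenoiserSpec", function(object) {
  cat(sprintf("DenoiserSpec: %s (%d)%s\n", object@name, object@year,
              if (object@deterministic) ", deterministic" else ""))
})
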