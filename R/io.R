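# Volume, manifest and results IO: NIfTI or raw float32 + JSON sidecar for
# volumes; JSON/CSV for tables and optimization histories.

.fingerprint <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h1 <- .childSeed(1L, s)
  h2 <- .childSeed(7L, s)
  sprintf("%08x%08x", h1, h2)
}

#' Write / read a CT volume
#'
#' Paths ending in \code{.nii} or \code{.nii.gz} use the NIfTI format; any
#' other path writes a raw little-endian float32 array plus a JSON sidecar
#' (\code{<path>.json}) holding shape, spacing, dose tag, exam type and
#' patient id.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param path output path.
#' @return \code{writeVolume}: the path, invisibly. \code{readVolume}: a
#'   \linkS4class{CTVolume}.
#' @export
writeVolume <- function(volume, path) {
  meta <- list(shape = dim(volume@hu), voxelSpacing = volume@voxelSpacing,
               examType = volume@examType, patientId = volume@patientId,
               doseTag = volume@doseTag)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume@hu,
                           pixdim = c(volume@voxelSpacing[1],
                                      volume@voxelSpacing[1],
                                      volume@voxelSpacing[2]))
    RNifti::writeNifti(img, path)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    con <- file(path, "wb")
    writeBin(as.numeric(volume@hu), con, size = 4L, endian = "little")
    close(con)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(errorCondition(sprintf("missing sidecar for '%s'", path),
                        class = c("parseError", "error", "condition")))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  hu <- if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- as.array(RNifti::readNifti(path))
    array(as.numeric(arr), dim = dim(arr))
  } else {
    n <- prod(meta$shape)
    con <- file(path, "rb")
    v <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
    close(con)
    if (length(v) != n)
      stop(errorCondition("truncated raw volume file",
                          class = c("parseError", "error", "condition")))
    array(v, dim = meta$shape)
  }
  new("CTVolume", hu = hu, voxelSpacing = meta$voxelSpacing,
      examType = meta$examType, patientId = meta$patientId,
      doseTag = meta$doseTag)
}

#' Write / read a dataset manifest
#'
#' The manifest lists scans with file paths, exam types, patient ids, slice
#' counts and lesion boxes (0-based, half-open voxel coordinates), plus the
#' seed and config fingerprint that produced the dataset.
#'
#' @param scans list of per-scan entries.
#' @param path JSON path.
#' @param seed,fingerprint provenance fields embedded in the file.
#' @return \code{writeManifestJSON}: path invisibly; \code{readManifestJSON}:
#'   the manifest list.
#' @export
writeManifestJSON <- function(scans, path, seed = NA_integer_,
                              fingerprint = NA_character_) {
  jsonlite::write_json(list(version = 1L, seed = seed,
                            fingerprint = fingerprint, scans = scans),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifestJSON
#' @export
readManifestJSON <- function(path) {
  out <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(errorCondition(
                      sprintf("cannot parse manifest '%s': %s", path,
                              conditionMessage(e)),
                      class = c("parseError", "error", "condition"))))
  if (is.null(out$scans))
    stop(errorCondition("manifest has no 'scans' field",
                        class = c("parseError", "error", "condition")))
  out
}

#' Serialize / deserialize result tables
#'
#' JSON round trips preserve all values at full precision and embed the
#' seed and config fingerprint that produced them.
#'
#' @param table a data.frame (metric table, rank table, marks ...).
#' @param path JSON path.
#' @param meta named list of provenance fields (seed, fingerprint, ...).
#' @return \code{writeTableJSON}: path invisibly; \code{readTableJSON}: the
#'   data.frame with attribute \code{"meta"}.
#' @export
writeTableJSON <- function(table, path, meta = list()) {
  jsonlite::write_json(list(version = 1L, meta = meta, columns = names(table),
                            rows = table),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname writeTableJSON
#' @export
readTableJSON <- function(path) {
  out <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(errorCondition(
                      sprintf("cannot parse '%s': %s", path,
                              conditionMessage(e)),
                      class = c("parseError", "error", "condition"))))
  if (is.null(out$rows) || is.null(out$columns))
    stop(errorCondition("not a serialized table",
                        class = c("parseError", "error", "condition")))
  df <- as.data.frame(out$rows)[, out$columns, drop = FALSE]
  attr(df, "meta") <- out$meta
  df
}

#' Serialize / deserialize an optimization history
#'
#' @param history an \linkS4class{HPOHistory}.
#' @param path JSON path.
#' @return \code{writeHistoryJSON}: path invisibly; \code{readHistoryJSON}:
#'   an \linkS4class{HPOHistory} with trial order preserved.
#' @export
writeHistoryJSON <- function(history, path) {
  sp <- lapply(history@space@params, function(p)
    p[c("name", "prior", "lower", "upper", "integer")])
  jsonlite::write_json(
    list(version = 1L, metricName = history@metricName, seed = history@seed,
         bestObjective = history@bestObjective,
         bestLambda = history@bestLambda, space = unname(sp),
         trials = history@trials),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname writeHistoryJSON
#' @export
readHistoryJSON <- function(path) {
  out <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(errorCondition(
                      sprintf("cannot parse '%s': %s", path,
                              conditionMessage(e)),
                      class = c("parseError", "error", "condition"))))
  if (is.null(out$trials))
    stop(errorCondition("not a serialized optimization history",
                        class = c("parseError", "error", "condition")))
  sp <- do.call(searchSpace, lapply(seq_len(nrow(out$space)), function(i)
    paramSpec(out$space$name[i], out$space$prior[i], out$space$lower[i],
              out$space$upper[i], out$space$integer[i])))
  new("HPOHistory", trials = as.data.frame(out$trials), space = sp,
      bestLambda = as.list(out$bestLambda),
      bestObjective = out$bestObjective, metricName = out$metricName,
      seed = as.integer(out$seed))
}
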