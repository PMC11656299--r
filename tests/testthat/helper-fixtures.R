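# Shared fixtures: small simulation configs and memoised scan pairs so that
# expensive objects are built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

tinySimConfig <- function(...) {
  ctSimConfig(imageSize = 96L, nAngles = 144L, voxelSpacing = 2.5,
              nSlices = 2L, ...)
}

denoiseSimConfig <- function(...) {
  # finer grid so noise, not organ boundaries, dominates local errors
  ctSimConfig(imageSize = 128L, nAngles = 192L, voxelSpacing = 1.5,
              nSlices = 2L, ...)
}

cachedPair <- function(examType = "abdomen", seed = 1L,
                       config = tinySimConfig()) {
  key <- paste(examType, seed, config$imageSize, config$nAngles,
               config$voxelSpacing, config$nSlices[1], config$filterName,
               sep = "-")
  if (!exists(key, envir = .fixtureCache))
    assign(key, simulateCase(examType, NULL, seed, config),
           envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

diskImage <- function(n = 128L, radiusMM = 20, mu = 0.02, spacing = 1) {
  ctr <- (seq_len(n) - (n + 1) / 2) * spacing
  X <- matrix(ctr, n, n)
  Y <- t(X)
  img <- matrix(0, n, n)
  img[X^2 + Y^2 <= radiusMM^2] <- mu
  img
}

# standard deviation of HU inside the organ, away from lesions and borders
organNoiseSD <- function(pair, volume = lowDose(pair)) {
  organ <- setdiff(names(organMasks(pair)), "body")[1]
  m <- organMasks(pair)[[organ]]
  for (les in lesionBoxes(pair)) {
    b <- les$box
    m[max(1, b[1] - 1):min(dim(m)[1], b[2] + 2),
      max(1, b[3] - 1):min(dim(m)[2], b[4] + 2),
      (b[5] + 1):b[6]] <- FALSE
  }
  sd(huData(volume)[m])
}

writeMatrixTxt <- function(m, path) {
  write(t(m), path, ncolumns = ncol(m))
  path
}

pythonOracle <- function(script, args) {
  out <- system2("python", c(file.path(test_path(), script), args),
                 stdout = TRUE, stderr = TRUE)
  as.numeric(out[length(out)])
}
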