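# Pipeline harness: run configuration, the simulate -> fit -> denoise ->
# evaluate -> rank pipeline, and a small command-line front end.

#' Benchmark run configuration
#'
#' Bundles and validates every setting of a benchmark run. Defaults follow
#' the evaluation protocol: dose fractions 0.25 (abdomen/head) and 0.10
#' (chest), 50 SMBO iterations, 10 retraining seeds, alpha = 0.05 and the
#' hard-subset grid q = 100/60/40/20.
#'
#' @param scansPerType named integer vector of scans per exam type.
#' @param doseFractions named numeric vector of dose fractions per exam type.
#' @param sim a \code{\link{ctSimConfig}} list.
#' @param methods denoiser registry names to benchmark.
#' @param metricList metrics among SSIM, PSNR, VIF, RMSE.
#' @param dataRange data range in HU.
#' @param hpo list(nIter, nInit, seed offsets are derived internally).
#' @param evaluation list(retrainSeeds, alpha, qGrid).
#' @param splitFractions train/validation/test fractions.
#' @param seed master seed; all stage seeds derive from it.
#' @param outputDir output directory for CLI runs.
#' @return A validated \code{RunConfig} list.
#' @export
runConfig <- function(scansPerType = c(abdomen = 50L, head = 50L,
                                       chest = 50L),
                      doseFractions = EXAM_DOSE,
                      sim = ctSimConfig(),
                      methods = c("gaussian", "bilateral", "smallcnn"),
                      metricList = c("SSIM", "PSNR", "VIF"),
                      dataRange = 2000,
                      hpo = list(nIter = 50L, nInit = 5L),
                      evaluation = list(retrainSeeds = 10L, alpha = 0.05,
                                        qGrid = c(100, 60, 40, 20)),
                      splitFractions = c(0.7, 0.2, 0.1),
                      seed = 0L, outputDir = "ctbench-out") {
  cfg <- list(scansPerType = scansPerType, doseFractions = doseFractions,
              sim = sim, methods = methods, metricList = metricList,
              dataRange = dataRange, hpo = hpo, evaluation = evaluation,
              splitFractions = splitFractions, seed = as.integer(seed),
              outputDir = outputDir)
  validateRunConfig(cfg)
  cfg
}

#' Validate a run configuration against the schema
#'
#' @param cfg a run configuration list.
#' @return TRUE invisibly; signals an error describing the first violation.
#' @export
validateRunConfig <- function(cfg) {
  fail <- function(msg) stop(sprintf("invalid run config: %s", msg),
                             call. = FALSE)
  need <- c("scansPerType", "doseFractions", "sim", "methods", "metricList",
            "dataRange", "hpo", "evaluation", "splitFractions", "seed",
            "outputDir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) fail(paste("missing fields:", paste(miss, collapse = ", ")))
  if (is.null(names(cfg$scansPerType)) ||
      !all(names(cfg$scansPerType) %in% EXAM_TYPES))
    fail("scansPerType must be named by exam type")
  if (any(cfg$scansPerType < 1)) fail("scansPerType must be >= 1")
  if (!all(names(cfg$scansPerType) %in% names(cfg$doseFractions)))
    fail("doseFractions must cover every simulated exam type")
  if (any(cfg$doseFractions <= 0 | cfg$doseFractions > 1))
    fail("dose fractions must lie in (0, 1]")
  if (!all(cfg$metricList %in% c("SSIM", "PSNR", "VIF", "RMSE")))
    fail("unknown metric in metricList")
  if (!(cfg$dataRange > 0)) fail("dataRange must be > 0")
  if (cfg$hpo$nInit < 2L || cfg$hpo$nIter < cfg$hpo$nInit)
    fail("hpo requires nInit >= 2 and nIter >= nInit")
  if (cfg$evaluation$retrainSeeds < 1L) fail("retrainSeeds must be >= 1")
  if (cfg$evaluation$alpha <= 0 || cfg$evaluation$alpha >= 1)
    fail("alpha must lie in (0, 1)")
  if (any(cfg$evaluation$qGrid <= 0 | cfg$evaluation$qGrid > 100))
    fail("qGrid values must lie in (0, 100]")
  if (abs(sum(cfg$splitFractions) - 1) > 1e-9)
    fail("splitFractions must sum to 1")
  invisible(TRUE)
}

#' Run the full benchmark pipeline
#'
#' simulate -> split -> fit (per retraining seed) -> denoise -> evaluate ->
#' mark significance -> rank. Methods are fitted on the training-split
#' pairs and evaluated on the test-split pairs (the low-dose baseline "LD"
#' is evaluated identically through the identity denoiser).
#'
#' @param cfg a \code{\link{runConfig}}.
#' @param pairs optional pre-simulated list of \linkS4class{ScanPair}s
#'   (skips simulation).
#' @return list(metricTable, rankTable, marks, perSeed, perSlice,
#'   hardSubsets, split, manifest, fittedStates).
#' @export
runBenchmark <- function(cfg, pairs = NULL) {
  validateRunConfig(cfg)
  if (is.null(pairs)) {
    pairs <- list()
    for (et in names(cfg$scansPerType)) {
      for (i in seq_len(cfg$scansPerType[[et]])) {
        s <- .childSeed(cfg$seed, sprintf("%s-%d", et, i))
        pairs[[length(pairs) + 1L]] <-
          simulateCase(et, cfg$doseFractions[[et]], s, cfg$sim)
      }
    }
  }
  manifest <- datasetManifest(pairs)
  split <- splitDataset(manifest, .childSeed(cfg$seed, "split"),
                        cfg$splitFractions)
  inSplit <- function(pr, part) {
    et <- examType(pr)
    patientId(pr) %in% split$byExamType[[et]][[part]]
  }
  trainPairs <- Filter(function(pr) inSplit(pr, "train"), pairs)
  testPairs <- Filter(function(pr) inSplit(pr, "test"), pairs)
  if (!length(testPairs))
    stop("empty test split; increase scansPerType or adjust splitFractions",
         call. = FALSE)

  nSeeds <- cfg$evaluation$retrainSeeds
  allTables <- NULL; perSeedAll <- NULL; perSliceAll <- NULL
  fittedStates <- list()
  years <- c()
  specs <- c("identity", cfg$methods)
  for (nm in specs) {
    spec <- getDenoiser(nm)
    states <- retrainWithSeeds(function(lambda, s)
      spec@fitFun(trainPairs, list(searchConfig = cfg$hpo),
                  .childSeed(cfg$seed, paste0(nm, "-", s))),
      lambda = list(), nSeeds = if (spec@deterministic) 1L else nSeeds)
    fittedStates[[nm]] <- states
    tab <- evaluateMethod(spec, states, testPairs, cfg$metricList,
                          cfg$dataRange)
    ps <- attr(tab, "perSeed"); pl <- attr(tab, "perSlice")
    if (nm == "identity") {  # identity row doubles as the LD baseline
      tab$method <- "LD"; ps$method <- "LD"; pl$method <- "LD"
    } else years[nm] <- spec@year
    allTables <- rbind(allTables, tab)
    perSeedAll <- rbind(perSeedAll, ps)
    perSliceAll <- rbind(perSliceAll, pl)
  }
  marks <- significanceMarks(perSeedAll, years, cfg$evaluation$alpha)
  rankTable <- competitionRank(allTables)
  hard <- NULL
  ssimSlices <- perSliceAll[perSliceAll$metric == "SSIM", ]
  if (nrow(ssimSlices)) {
    seedMean <- aggregate(ssimSlices["value"],
                          ssimSlices[c("method", "examType", "scanId",
                                       "sliceIndex")], mean)
    hard <- lapply(cfg$evaluation$qGrid, function(q)
      ldctHardSubset(seedMean, q))
    names(hard) <- paste0("q", cfg$evaluation$qGrid)
  }
  list(metricTable = allTables, rankTable = rankTable, marks = marks,
       perSeed = perSeedAll, perSlice = perSliceAll, hardSubsets = hard,
       split = split, manifest = manifest, fittedStates = fittedStates)
}

.parseArgs <- function(argv) {
  out <- list(positional = character())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i + 1L <= length(argv) && !startsWith(argv[i + 1L], "--")) {
        out[[key]] <- argv[i + 1L]
        i <- i + 2L
      } else {
        out[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

.cliConfig <- function(args) {
  if (!is.null(args$config)) {
    raw <- jsonlite::read_json(args$config, simplifyVector = TRUE)
    cfg <- runConfig()
    for (nm in names(raw)) {
      if (nm %in% c("sim", "hpo", "evaluation"))
        cfg[[nm]] <- modifyList(cfg[[nm]], as.list(raw[[nm]]))
      else cfg[[nm]] <- raw[[nm]]
    }
    if (!is.null(raw$scansPerType))
      cfg$scansPerType <- unlist(raw$scansPerType)
    if (!is.null(raw$doseFractions))
      cfg$doseFractions <- unlist(raw$doseFractions)
    validateRunConfig(cfg)
    cfg
  } else runConfig()
}

.cliSimulate <- function(args) {
  cfg <- .cliConfig(args)
  if (!is.null(args$seed)) cfg$seed <- as.integer(args$seed)
  outDir <- args$out %||% cfg$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  scans <- list()
  for (et in names(cfg$scansPerType)) {
    for (i in seq_len(cfg$scansPerType[[et]])) {
      s <- .childSeed(cfg$seed, sprintf("%s-%d", et, i))
      pr <- simulateCase(et, cfg$doseFractions[[et]], s, cfg$sim)
      base <- file.path(outDir, patientId(pr))
      writeVolume(pr@high, paste0(base, "_high.f32"))
      writeVolume(pr@low, paste0(base, "_low.f32"))
      saveRDS(pr, paste0(base, "_pair.rds"))
      scans[[length(scans) + 1L]] <- list(
        scanId = patientId(pr), patientId = patientId(pr), examType = et,
        nSlices = dim(pr@high@hu)[3], seed = s,
        high = paste0(patientId(pr), "_high.f32"),
        low = paste0(patientId(pr), "_low.f32"),
        pair = paste0(patientId(pr), "_pair.rds"),
        lesionBoxes = lapply(lesionBoxes(pr), function(l)
          list(box = l$box, label = l$label, organ = l$organ)))
    }
  }
  writeManifestJSON(scans, file.path(outDir, "manifest.json"),
                    seed = cfg$seed, fingerprint = .fingerprint(cfg))
  message(sprintf("wrote %d scan pair(s) to %s", length(scans), outDir))
  0L
}

.cliLoadPairs <- function(dataDir) {
  man <- readManifestJSON(file.path(dataDir, "manifest.json"))
  lapply(man$scans, function(sc)
    readRDS(file.path(dataDir, sc$pair)))
}

.cliRun <- function(args) {
  cfg <- .cliConfig(args)
  if (!is.null(args$seed)) cfg$seed <- as.integer(args$seed)
  pairs <- if (!is.null(args$data)) .cliLoadPairs(args$data) else NULL
  res <- runBenchmark(cfg, pairs)
  outDir <- args$out %||% cfg$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = cfg$seed, fingerprint = .fingerprint(cfg))
  writeTableJSON(res$metricTable, file.path(outDir, "metric_table.json"),
                 meta)
  writeTableJSON(res$rankTable, file.path(outDir, "rank_table.json"), meta)
  writeTableJSON(res$marks, file.path(outDir, "significance_marks.json"),
                 meta)
  utils::write.csv(res$metricTable, file.path(outDir, "metric_table.csv"),
                   row.names = FALSE)
  message(sprintf("benchmark results written to %s", outDir))
  0L
}

.cliFit <- function(args) {
  cfg <- .cliConfig(args)
  if (!is.null(args$seed)) cfg$seed <- as.integer(args$seed)
  if (is.null(args$data) || is.null(args$method)) {
    message("usage: fit --data <dir> --method <name> [--out <file>]")
    return(2L)
  }
  pairs <- .cliLoadPairs(args$data)
  spec <- getDenoiser(args$method)
  state <- spec@fitFun(pairs, list(), .childSeed(cfg$seed, args$method))
  out <- args$out %||% paste0(args$method, "_state.rds")
  saveRDS(state, out)
  jsonlite::write_json(list(method = args$method, seed = cfg$seed,
                            fingerprint = .fingerprint(cfg)),
                       paste0(out, ".json"), auto_unbox = TRUE)
  message(sprintf("fitted state written to %s", out))
  0L
}

.cliDenoise <- function(args) {
  if (is.null(args$data) || is.null(args$state)) {
    message("usage: denoise --data <dir> --state <file> [--out <dir>]")
    return(2L)
  }
  state <- readRDS(args$state)
  spec <- getDenoiser(state$method)
  pairs <- .cliLoadPairs(args$data)
  outDir <- args$out %||% file.path(args$data, "denoised")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (pr in pairs) {
    den <- applyDenoiser(spec, state, pr@low)
    writeVolume(den, file.path(outDir, paste0(patientId(pr), "_",
                                              spec@name, ".f32")))
  }
  message(sprintf("denoised %d volume(s) into %s", length(pairs), outDir))
  0L
}

.cliRank <- function(args) {
  if (is.null(args$metrics)) {
    message("usage: rank --metrics <metric_table.json> [--out <file>]")
    return(2L)
  }
  tab <- readTableJSON(args$metrics)
  rk <- competitionRank(tab)
  out <- args$out %||% "rank_table.json"
  writeTableJSON(rk, out, attr(tab, "meta") %||% list())
  message(sprintf("rank table written to %s", out))
  0L
}

.cliReport <- function(args) {
  if (is.null(args$results)) {
    message("usage: report --results <dir>")
    return(2L)
  }
  tab <- readTableJSON(file.path(args$results, "metric_table.json"))
  rk <- readTableJSON(file.path(args$results, "rank_table.json"))
  for (et in unique(tab$examType)) {
    cat(sprintf("== %s ==\n", et))
    sub <- tab[tab$examType == et, ]
    for (m in unique(sub$method)) {
      rows <- sub[sub$method == m, ]
      cat(sprintf("  %-10s %s\n", m,
                  paste(sprintf("%s %.4g +/- %.2g", rows$metric, rows$mean,
                                rows$sd), collapse = "  ")))
    }
  }
  cat("== ranks ==\n")
  for (i in order(rk$rank))
    cat(sprintf("  %d%s %s\n", rk$rank[i], ifelse(rk$tied[i], "*", " "),
                rk$method[i]))
  0L
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{fit}, \code{denoise},
#' \code{evaluate}, \code{rank}, \code{report}, \code{hpo}. Each reads and
#' writes only the files named on its command line; every artifact embeds
#' the seed and config fingerprint that produced it. Returns a process exit
#' status (0 on success, 2 on usage errors) rather than quitting, so it can
#' be driven from tests; the installed script
#' \code{inst/scripts/ctdenoisebench} wraps it for the shell.
#'
#' @param argv character vector of command-line arguments.
#' @return Integer exit status.
#' @export
benchCLI <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message(paste("usage: ctdenoisebench",
                  "<simulate|fit|denoise|evaluate|rank|report|hpo> [options]"))
    return(2L)
  }
  sub <- argv[1]
  args <- .parseArgs(argv[-1])
  res <- tryCatch(switch(sub,
    simulate = .cliSimulate(args),
    fit = .cliFit(args),
    hpo = .cliFit(args),
    denoise = .cliDenoise(args),
    evaluate = .cliRun(args),
    rank = .cliRank(args),
    report = .cliReport(args),
    {
      message(sprintf("unknown subcommand '%s'", sub))
      2L
    }), error = function(e) {
      message(sprintf("error: %s", conditionMessage(e)))
      1L
    })
  invisible(res)
}
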