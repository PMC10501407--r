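# End-to-end orchestration of the synthetic-preset analysis:
# simulate -> hm -> gep -> comsia -> validate -> design.

.PIPELINE_SCHEMA <- list(
  seed = NULL, stages = NULL, out = NULL,
  split = list(ratio2d = NULL, ratio3d = NULL),
  hm = list(kMax = NULL, stopDelta = NULL, collinearityCap = NULL),
  gep = list(populationSize = NULL, generations = NULL, headLength = NULL,
             nGenes = NULL, fitnessTarget = NULL),
  comsia = list(nMolecules = NULL, noiseSd = NULL, maxComponents = NULL,
                spacing = NULL, margin = NULL, alpha = NULL, minSigma = NULL),
  validate = list(nIter = NULL),
  design = list(n = NULL))

.checkConfig <- function(config, schema = .PIPELINE_SCHEMA, path = "") {
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stopf("unknown config key(s): %s",
          paste0(path, unknown, collapse = ", "))
  for (nm in names(config))
    if (is.list(schema[[nm]]) && is.list(config[[nm]]))
      .checkConfig(config[[nm]], schema[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Default pipeline configuration
#'
#' Problem sizes follow the study-emulation presets: 34 compounds x 500
#' descriptors for the 2D branch (1:3 test:train split), 50 molecules for
#' the 3D branch (1:4 validation:train split), 20 Y-randomization scrambles
#' and 200 designed candidates. The GEP stage runs on the six causal
#' descriptors with a population of 100 for up to 60 generations.
#'
#' @param seed master seed; each stage derives its own fixed offset from it.
#' @param out optional output directory for artifacts.
#' @return a config list for \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(seed = 1L, out = NULL) {
  list(seed = as.integer(seed),
       stages = c("simulate", "hm", "gep", "comsia", "validate", "design"),
       out = out,
       split = list(ratio2d = c(1, 3), ratio3d = c(1, 4)),
       hm = list(kMax = 8L, stopDelta = 0.02, collinearityCap = 0.8),
       gep = list(populationSize = 100L, generations = 60L, headLength = 8L,
                  nGenes = 3L, fitnessTarget = 0.999),
       comsia = list(nMolecules = 50L, noiseSd = 0.06, maxComponents = 10L,
                     spacing = 2, margin = 4, alpha = 0.3, minSigma = 0.05),
       validate = list(nIter = 20L),
       design = list(n = 200L))
}

#' Run the full synthetic-preset QSAR pipeline
#'
#' Executes the requested stages in order with a shared seed ledger
#' (stage seeds are fixed offsets of the master seed). A stage failure
#' aborts the downstream stages; completed results are preserved and the
#' status of every stage is reported. When \code{config$out} is set, the
#' main artifacts (selection trace, model files, design table, manifest
#' with seeds, config hash and package version) are written there.
#'
#' @param config list from \code{\link{defaultPipelineConfig}} (unknown keys
#'   are rejected by name).
#' @return list with one entry per executed stage plus \code{status}
#'   (data.frame) and \code{seeds}.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  .checkConfig(config)
  seed <- as.integer(config$seed)
  seeds <- c(simulate = seed, split = seed + 1L, gep = seed + 3L,
             field = seed + 7L, yrand = seed + 13L, design = seed + 17L)
  stages <- config$stages
  res <- list(seeds = seeds)
  status <- data.frame(stage = stages, status = "skipped",
                       stringsAsFactors = FALSE)
  failed <- FALSE
  runStage <- function(name, fun) {
    if (failed || !(name %in% stages)) return(invisible(NULL))
    out <- tryCatch(fun(), error = function(e) e)
    i <- match(name, status$stage)
    if (inherits(out, "error")) {
      status$status[i] <<- paste("failed:", conditionMessage(out))
      failed <<- TRUE
      NULL
    } else {
      status$status[i] <<- "ok"
      res[[name]] <<- out
      out
    }
  }

  runStage("simulate", function() {
    preset <- paperPresetLinear(seed = seeds[["simulate"]])
    field <- generateAlignedMolecules(
      fieldPlantSpec(nMolecules = config$comsia$nMolecules,
                     noiseSd = config$comsia$noiseSd,
                     seed = seeds[["field"]]),
      spacing = config$comsia$spacing, margin = config$comsia$margin,
      alpha = config$comsia$alpha, minSigma = config$comsia$minSigma)
    list(preset = preset, field = field)
  })

  runStage("hm", function() {
    preset <- res$simulate$preset
    ids <- compoundIds(preset$table)
    heldIdx <- withSeed(seeds[["split"]], {
      n <- length(ids)
      frac <- config$split$ratio2d[1] / sum(config$split$ratio2d)
      sort(sample.int(n, round(n * frac)))
    })
    trainIdx <- setdiff(seq_along(ids), heldIdx)
    m <- descriptorMatrix(preset$table)
    yTr <- preset$activity[trainIdx]
    filtered <- prefilterDescriptors(
      descriptorTable(m[trainIdx, , drop = FALSE]), yTr,
      collinearityCap = config$hm$collinearityCap)
    trace <- heuristicSelect(filtered, yTr, kMax = config$hm$kMax,
                             stopDelta = config$hm$stopDelta,
                             collinearityCap = config$hm$collinearityCap)
    subset <- trace@subsets[[trace@recommended]]
    model <- fitMlr(m[trainIdx, subset, drop = FALSE], yTr,
                    provenance = "pipeline heuristic selection")
    predTest <- evaluateLinear(model, m[heldIdx, subset, drop = FALSE])
    list(trace = trace, model = model, trainIdx = trainIdx,
         testIdx = heldIdx,
         testR2 = squaredCorrelation(preset$activity[heldIdx], predTest),
         predTest = predTest)
  })

  runStage("gep", function() {
    preset <- res$simulate$preset
    trainIdx <- res$hm$trainIdx; testIdx <- res$hm$testIdx
    m <- descriptorMatrix(preset$table)[, preset$trueSubset, drop = FALSE]
    # trees carry no numeric constants, so the response is standardized to
    # put it on the scale expression trees can reach
    yTr <- preset$activity[trainIdx]
    z <- (preset$activity - mean(yTr)) / stats::sd(yTr)
    cfg <- gepConfig(populationSize = config$gep$populationSize,
                     generations = config$gep$generations,
                     headLength = config$gep$headLength,
                     nGenes = config$gep$nGenes,
                     fitnessTarget = config$gep$fitnessTarget,
                     seed = seeds[["gep"]])
    evolveGep(m[trainIdx, , drop = FALSE], z[trainIdx], cfg,
              Xtest = m[testIdx, , drop = FALSE], ytest = z[testIdx])
  })

  runStage("comsia", function() {
    field <- res$simulate$field
    n <- length(field$molecules)
    frac <- config$split$ratio3d[1] / sum(config$split$ratio3d)
    valIdx <- withSeed(seeds[["split"]] + 1L,
                       sort(sample.int(n, round(n * frac))))
    trainIdx <- setdiff(seq_len(n), valIdx)
    fmAll <- field$truth$fieldMatrix
    fmTrain <- new("FieldMatrix",
                   values = fmAll@values[trainIdx, , drop = FALSE],
                   field = fmAll@field, pointIndex = fmAll@pointIndex,
                   active = fmAll@active, grid = fmAll@grid)
    model <- fitPls(fmTrain, field$activity[trainIdx],
                    maxComponents = config$comsia$maxComponents)
    predVal <- predict(model,
                       fmAll@values[valIdx, model@columnIndex, drop = FALSE])
    contours <- contourMaps(model)
    list(model = model, contours = contours, trainIdx = trainIdx,
         valIdx = valIdx, predVal = predVal)
  })

  runStage("validate", function() {
    field <- res$simulate$field
    cm <- res$comsia
    trainY <- field$activity[cm$trainIdx]
    onc <- cm$model@ncomp
    fmAll <- field$truth$fieldMatrix
    Xtr <- fmAll@values[cm$trainIdx, fmAll@active, drop = FALSE]
    fitFn <- function(X, y) {   # structure (ONC) held fixed, per protocol
      Xc <- sweep(X, 2L, colMeans(X)); yc <- y - mean(y)
      B <- .pls1(Xc, yc, onc)$B[, onc]
      rSquared(y, drop(Xc %*% B) + mean(y))
    }
    validationReport(field$activity[cm$valIdx], cm$predVal, mean(trainY),
                     fitFn = fitFn, XTrain = Xtr, yTrain = trainY,
                     nIter = config$validate$nIter, seed = seeds[["yrand"]])
  })

  runStage("design", function() {
    preset <- res$simulate$preset
    field <- res$simulate$field
    bestIdx <- which.max(field$activity)
    tmplMol <- field$molecules[[bestIdx]]
    tmplDesc <- descriptorMatrix(preset$table)[which.max(preset$activity), ]
    template <- list(id = "T", descriptors = tmplDesc, molecule = tmplMol)
    nCand <- config$design$n
    library <- withSeed(seeds[["design"]], lapply(seq_len(nCand), function(k) {
      delta <- stats::setNames(rnorm(length(preset$trueSubset), 0, 0.5),
                               preset$trueSubset)
      mol <- tmplMol
      jitter <- matrix(rnorm(3L * nrow(mol@atoms), 0, 0.4), ncol = 3L)
      jitter[mol@scaffoldMap, ] <- 0          # scaffold stays put
      list(label = sprintf("perturb%03d", k), descriptorDelta = delta,
           atomEdit = local({
             j <- jitter
             function(m) {
               m@atoms$x <- m@atoms$x + j[, 1L]
               m@atoms$y <- m@atoms$y + j[, 2L]
               m@atoms$z <- m@atoms$z + j[, 3L]
               m
             }
           }))
    }))
    candidates <- enumerateCandidates(template, library, n = nCand,
                                      seed = seeds[["design"]])
    models <- list(comsia = res$comsia$model, gep = res$gep@bestTree,
                   hm = res$hm$model)
    suppressWarnings(
      predictAndRank(candidates, models, primaryModel = "comsia",
                     template = "T", seed = seeds[["design"]]))
  })

  res$status <- status
  res$config <- config
  if (!is.null(config$out)) .writePipelineArtifacts(res, config)
  res
}

.writePipelineArtifacts <- function(res, config) {
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(out, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "out")], cfgPath,
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("gbmQSAR")),
    seeds = as.list(res$seeds),
    config_md5 = unname(tools::md5sum(cfgPath)),
    status = stats::setNames(res$status$status, res$status$stage))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$hm)) {
    utils::write.csv(res$hm$trace@steps, file.path(out, "hm_trace.csv"),
                     row.names = FALSE)
    writeLinearModel(res$hm$model, file.path(out, "hm_model.txt"))
  }
  if (!is.null(res$gep))
    writeLines(deparseTree(res$gep@bestTree), file.path(out, "gep_best.txt"))
  if (!is.null(res$comsia))
    exportContours(res$comsia$contours, res$comsia$model,
                   file.path(out, "contours"))
  if (!is.null(res$design))
    utils::write.csv(res$design@table, file.path(out, "design_ranking.csv"),
                     row.names = FALSE)
  invisible(out)
}
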