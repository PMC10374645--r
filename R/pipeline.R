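## Pipeline orchestration: a validated configuration with complete defaults,
## stage-by-stage execution (deconvolution -> per-type state discovery ->
## ecotype discovery -> clinical screens -> enrichment, plus recovery when a
## validation cohort is configured), structured log lines and a reproducible
## manifest. Rerunning with the same configuration yields byte-identical
## outputs.

#' Default pipeline configuration
#'
#' Every stage parameter has a default, so a minimal configuration runs
#' end-to-end. When no bulk path is given the synthetic generator supplies
#' the cohort (and its clinical tables); the synthetic block mirrors the
#' generator's arguments.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    logLevel = "info",
    paths = list(bulk = NULL, signature = NULL, clinical = NULL,
                 response = NULL, geneSets = NULL, validationBulk = NULL,
                 outputDir = "ecostates_output"),
    synthetic = list(enabled = TRUE, nGenes = 600,
                     cellTypes = c("B.cells", "Fibroblasts",
                                   "Epithelial.cells"),
                     kPerType = c(2, 3, 4), nMarkersPerState = 30,
                     effectSizeLog2 = 2, nCommunities = 3,
                     communityNoiseRate = 0.1, nSamples = 200,
                     noiseSdLog2 = 0.5, nValidationSamples = 100,
                     baselineHazard = 0.1, censoringRate = 0.2,
                     benefitHazardReduction = 0.5),
    deconvolution = list(minSharedGenes = 50, minMeanFraction = 0.005,
                         minExpression = 1e-6),
    discovery = list(maxRank = 6, nRestarts = 20, maxIter = 500,
                     tol = 1e-5, copheneticTarget = 0.95, minLog2FC = 1,
                     minMarkers = 10, afiThreshold = 0.4,
                     applyAFIFilter = FALSE, nTopGenes = 150,
                     subsampleRate = 0.35, consensusReplicates = 3),
    recovery = list(nPerm = 500, minCoverage = 0.5),
    ecotypes = list(alpha = 0.01, gate = "standard", minStates = 3),
    clinical = list(minGroup = 10, adjust = "none"),
    enrichment = list(minSetSize = 15, maxSetSize = 500, runGSEA = FALSE,
                      gseaPerm = 1000, gseaWeight = 1)
  )
}

# Merge a user configuration over the defaults, rejecting unknown keys.
mergeConfig <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste0(path, unknown, collapse = ", ")))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- mergeConfig(user[[nm]], defaults[[nm]],
                                    paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' YAML file merged over \code{\link{defaultPipelineConfig}}; unknown keys
#' are rejected.
#'
#' @param path YAML configuration path (NULL for pure defaults).
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- mergeConfig(user, defaultPipelineConfig())
  if (!isTRUE(cfg$synthetic$enabled) && is.null(cfg$paths$bulk))
    stop("configuration needs either a bulk path or the synthetic block")
  if (!isTRUE(cfg$synthetic$enabled) && is.null(cfg$paths$signature))
    stop("deconvolution of a real cohort needs a signature path")
  cfg
}

pipeLog <- function(cfg, stage, fmt, ...) {
  if (identical(cfg$logLevel, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Deterministic TSV writer for result data.frames.
writeTableTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes deconvolution, per-type consensus-NMF state discovery, ecotype
#' discovery, survival and therapy-benefit screens, optional enrichment and
#' (when a validation cohort is available) reference-based state recovery;
#' writes every stage artifact plus a manifest under the output directory.
#' Stage failures abort with the failing stage named and a FAILED marker
#' retained next to any partial outputs.
#'
#' @param config a configuration list (see
#'   \code{\link{defaultPipelineConfig}}), or a YAML path.
#' @param outputDir overrides the configured output directory.
#' @return invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(config = NULL, outputDir = NULL) {
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else mergeConfig(config, defaultPipelineConfig())
  if (!is.null(outputDir)) cfg$paths$outputDir <- outputDir
  out <- cfg$paths$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  result <- tryCatch(
    runPipelineStages(cfg, out, function(s) stage <<- s),
    error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop(sprintf("pipeline aborted in stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  if (file.exists(file.path(out, "FAILED")))
    unlink(file.path(out, "FAILED"))
  invisible(result)
}

runPipelineStages <- function(cfg, out, setStage) {
  seed <- as.integer(cfg$seed)
  inputChecksums <- list()

  setStage("inputs")
  if (isTRUE(cfg$synthetic$enabled)) {
    sy <- cfg$synthetic
    truth <- generateTruth(
      nGenes = sy$nGenes, cellTypes = sy$cellTypes,
      kPerType = as.integer(sy$kPerType),
      nMarkersPerState = sy$nMarkersPerState,
      effectSizeLog2 = sy$effectSizeLog2, nCommunities = sy$nCommunities,
      communityNoiseRate = sy$communityNoiseRate, nSamples = sy$nSamples,
      seed = seed)
    bulk <- simulateBulk(truth, noiseSdLog2 = sy$noiseSdLog2,
                         seed = subSeed(seed, 2L))
    signature <- signatureFromTruth(truth)
    clinical <- simulateSurvival(truth, baselineHazard = sy$baselineHazard,
                                 censoringRate = sy$censoringRate,
                                 seed = subSeed(seed, 3L))
    response <- simulateResponse(
      truth, baselineHazard = sy$baselineHazard,
      benefitHazardReduction = sy$benefitHazardReduction,
      seed = subSeed(seed, 4L))
    validation <- if (sy$nValidationSamples > 0) {
      simulateValidationCohort(truth, sy$nValidationSamples,
                               seed = subSeed(seed, 5L),
                               noiseSdLog2 = sy$noiseSdLog2)
    } else NULL
    writeExpressionTSV(bulk, file.path(out, "bulk.tsv"))
    writeTruthJSON(truth, file.path(out, "truth.json"))
    writeClinicalTSV(clinical, file.path(out, "clinical.tsv"))
    writeClinicalTSV(response, file.path(out, "response.tsv"))
    inputChecksums$synthetic <- "generated"
    pipeLog(cfg, "inputs", "synthetic cohort: %d genes, %d samples",
            length(geneIDs(bulk)), length(sampleIDs(bulk)))
  } else {
    bulk <- readExpressionTSV(cfg$paths$bulk)
    signature <- SignatureMatrix(as.matrix(
      exprs(readExpressionTSV(cfg$paths$signature, scaleHint = "linear"))))
    clinical <- if (!is.null(cfg$paths$clinical))
      readClinicalTSV(cfg$paths$clinical) else NULL
    response <- if (!is.null(cfg$paths$response))
      readClinicalTSV(cfg$paths$response) else NULL
    validation <- if (!is.null(cfg$paths$validationBulk))
      list(expression = readExpressionTSV(cfg$paths$validationBulk),
           truth = NULL) else NULL
    truth <- NULL
    for (p in Filter(Negate(is.null), cfg$paths[c(
      "bulk", "signature", "clinical", "response", "validationBulk")])) {
      inputChecksums[[basename(p)]] <- unname(tools::md5sum(p))
    }
    pipeLog(cfg, "inputs", "bulk cohort: %d genes, %d samples",
            length(geneIDs(bulk)), length(sampleIDs(bulk)))
  }
  geneSets <- if (!is.null(cfg$paths$geneSets)) {
    inputChecksums[[basename(cfg$paths$geneSets)]] <-
      unname(tools::md5sum(cfg$paths$geneSets))
    readGMT(cfg$paths$geneSets)
  } else NULL

  setStage("deconvolution")
  fractions <- estimateFractions(bulk, signature,
                                 minSharedGenes =
                                   cfg$deconvolution$minSharedGenes)
  writeTableTSV(data.frame(sample = sampleIDs(fractions), exprs(fractions),
                           check.names = FALSE),
                file.path(out, "fractions.tsv"))
  pipeLog(cfg, "deconvolution", "%d samples x %d cell types",
          nrow(exprs(fractions)), ncol(exprs(fractions)))

  setStage("state_discovery")
  dc <- cfg$discovery
  models <- list()
  purifiedList <- list()
  for (ct in cellTypes(signature)) {
    model <- tryCatch({
      pur <- purifyExpression(bulk, fractions, ct,
                              minMeanFraction =
                                cfg$deconvolution$minMeanFraction,
                              minExpression =
                                cfg$deconvolution$minExpression)
      purifiedList[[ct]] <- pur
      discoverStates(pur, ranks = 2:dc$maxRank, nRestarts = dc$nRestarts,
                     seed = subSeed(seed, 10L + match(ct,
                                                      cellTypes(signature))),
                     maxIter = dc$maxIter, tol = dc$tol,
                     copheneticTarget = dc$copheneticTarget,
                     minLog2FC = dc$minLog2FC, minMarkers = dc$minMarkers,
                     afiThreshold = dc$afiThreshold,
                     applyAFIFilter = dc$applyAFIFilter,
                     nTopGenes = dc$nTopGenes,
                     subsampleRate = dc$subsampleRate,
                     consensusReplicates = dc$consensusReplicates)
    }, error = function(e) {
      pipeLog(cfg, "state_discovery", "cell type %s excluded: %s", ct,
              conditionMessage(e))
      NULL
    })
    if (is.null(model)) next
    models[[ct]] <- model
    writeStateModel(model, out, prefix = ct)
    a <- assignStates(model)
    writeTableTSV(data.frame(sample = names(a@state),
                             state = sprintf("S%02d", a@state)),
                  file.path(out, paste0(ct, "_assignments.tsv")))
    pipeLog(cfg, "state_discovery", "%s: K = %d, %d samples", ct,
            model@K, ncol(model@H))
  }
  if (length(models) < 2)
    stop("fewer than 2 cell types with retained states")

  setStage("ecotype_discovery")
  eco <- discoverEcotypes(models, alpha = cfg$ecotypes$alpha,
                          gate = cfg$ecotypes$gate,
                          minStates = cfg$ecotypes$minStates)
  writeTableTSV(data.frame(state = names(eco@ecotypeMap),
                           ecotype = ifelse(is.na(eco@ecotypeMap), "NA",
                                            paste0("E", eco@ecotypeMap))),
                file.path(out, "ecotype_membership.tsv"))
  writeTableTSV(data.frame(sample = rownames(eco@abundance),
                           eco@abundance, dominant = eco@dominant,
                           check.names = FALSE),
                file.path(out, "ecotype_abundance.tsv"))
  gj <- eco@gatedJaccard
  writeTableTSV(data.frame(state = rownames(gj), gj, check.names = FALSE),
                file.path(out, "gated_jaccard.tsv"))
  writeTableTSV(ecotypeEdgeList(eco), file.path(out, "ecotype_edges.tsv"))
  pipeLog(cfg, "ecotype_discovery", "chosen k = %d (%d retained ecotypes)",
          eco@chosenK, length(unique(stats::na.omit(eco@ecotypeMap))))

  setStage("clinical_association")
  screens <- list()
  if (!is.null(clinical)) {
    for (ct in names(models)) {
      a <- assignStates(models[[ct]])
      units <- setNames(sprintf("S%02d", a@state), names(a@state))
      screens[[paste0("states_", ct)]] <-
        stateSurvivalScreen(units, clinical,
                            minGroup = cfg$clinical$minGroup,
                            adjust = cfg$clinical$adjust)
    }
    screens$ecotypes <- stateSurvivalScreen(eco@dominant, clinical,
                                            minGroup = cfg$clinical$minGroup,
                                            adjust = cfg$clinical$adjust)
    for (nm in names(screens))
      writeTableTSV(screens[[nm]],
                    file.path(out, paste0("survival_", nm, ".tsv")))
    pipeLog(cfg, "clinical_association", "%d screens written",
            length(screens))
  }
  benefit <- NULL
  if (!is.null(response) && !is.null(response@response)) {
    benefit <- therapyBenefit(eco@dominant, response)
    writeTableTSV(benefit, file.path(out, "therapy_benefit_ecotypes.tsv"))
    for (ct in names(models)) {
      a <- assignStates(models[[ct]])
      units <- setNames(sprintf("S%02d", a@state), names(a@state))
      writeTableTSV(therapyBenefit(units, response),
                    file.path(out, paste0("therapy_benefit_", ct, ".tsv")))
    }
  }

  setStage("enrichment")
  enrichTabs <- list()
  if (!is.null(geneSets)) {
    universe <- geneIDs(bulk)
    for (ct in names(models)) {
      mk <- stateMarkers(models[[ct]])
      for (s in names(mk)) {
        if (!nrow(mk[[s]])) next
        tab <- hypergeometricEnrichment(
          mk[[s]]$gene, geneSets, universe,
          setSizeRange = c(cfg$enrichment$minSetSize,
                           cfg$enrichment$maxSetSize))
        enrichTabs[[paste(ct, s, sep = "|")]] <- tab
        writeTableTSV(tab, file.path(out, paste0(
          "enrichment_", ct, "_", s, ".tsv")))
      }
    }
    pipeLog(cfg, "enrichment", "%d marker sets tested", length(enrichTabs))
  }

  setStage("state_recovery")
  recoveries <- list()
  if (!is.null(validation)) {
    vFrac <- estimateFractions(validation$expression, signature,
                               minSharedGenes =
                                 cfg$deconvolution$minSharedGenes)
    for (ct in names(models)) {
      rec <- tryCatch({
        vPur <- purifyExpression(validation$expression, vFrac, ct,
                                 minMeanFraction =
                                   cfg$deconvolution$minMeanFraction)
        recoverStates(vPur, models[[ct]], nPerm = cfg$recovery$nPerm,
                      seed = subSeed(seed, 20L + match(ct, names(models))),
                      minCoverage = cfg$recovery$minCoverage)
      }, error = function(e) {
        pipeLog(cfg, "state_recovery", "%s not recovered: %s", ct,
                conditionMessage(e))
        NULL
      })
      if (is.null(rec)) next
      recoveries[[ct]] <- rec
      writeTableTSV(rec@table,
                    file.path(out, paste0(ct, "_recovery.tsv")))
      writeTableTSV(data.frame(sample = names(rec@assignments),
                               state = sprintf("S%02d", rec@assignments)),
                    file.path(out, paste0(ct, "_recovery_assignments.tsv")))
      pipeLog(cfg, "state_recovery", "%s: recovery rate %.2f", ct,
              recoveryRate(rec))
    }
  }

  setStage("manifest")
  manifest <- list(
    package = "EcoStates",
    version = as.character(utils::packageVersion("EcoStates")),
    seed = seed,
    parameters = cfg,
    inputChecksums = inputChecksums,
    outputs = sort(setdiff(list.files(out), c("manifest.json", "FAILED"))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  pipeLog(cfg, "manifest", "written to %s", file.path(out, "manifest.json"))

  invisible(list(config = cfg, truth = truth, bulk = bulk,
                 fractions = fractions, purified = purifiedList,
                 models = models, ecotypes = eco, screens = screens,
                 benefit = benefit, recoveries = recoveries,
                 enrichment = enrichTabs))
}
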