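# Shared fixtures for the test suite. Heavy end-to-end objects are built
# once per test run and cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# A small, fast discovery cohort: 3 cell types, planted K = 2/3/4 states,
# 4 communities so every planted state is populated.
smallCohort <- function(seed = 105) {
  cached(paste0("cohort", seed), {
    truth <- generateTruth(nCommunities = 4, seed = seed)
    bulk <- simulateBulk(truth, noiseSdLog2 = 0.5, seed = seed + 1)
    signature <- signatureFromTruth(truth)
    fractions <- estimateFractions(bulk, signature)
    list(truth = truth, bulk = bulk, signature = signature,
         fractions = fractions)
  })
}

# A noiseless cohort with zero marker effect: exactly identifiable mixtures.
noiselessCohort <- function(seed = 202) {
  cached(paste0("noiseless", seed), {
    truth <- generateTruth(effectSizeLog2 = 0, nCommunities = 4, seed = seed)
    bulk <- simulateBulk(truth, noiseSdLog2 = 0, seed = seed + 1)
    list(truth = truth, bulk = bulk, signature = signatureFromTruth(truth))
  })
}

# Fitted state models for the small cohort (used by ecotype/recovery tests).
smallModels <- function(seed = 105) {
  cached(paste0("models", seed), {
    co <- smallCohort(seed)
    models <- list()
    for (ct in cellTypes(co$truth)) {
      pur <- purifyExpression(co$bulk, co$fractions, ct)
      models[[ct]] <- discoverStates(pur, ranks = 2:6, nRestarts = 12,
                                     seed = seed, maxIter = 400, tol = 1e-5,
                                     nTopGenes = 150,
                                     consensusReplicates = 2)
    }
    models
  })
}

# Hand-rolled toy StateAssignment.
toyAssignment <- function(cellType, states, samples = NULL) {
  if (is.null(samples)) samples <- paste0("P", seq_along(states))
  new("StateAssignment", cellType = cellType,
      state = setNames(as.integer(states), samples),
      abundance = setNames(rep(1, length(states)), samples))
}
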