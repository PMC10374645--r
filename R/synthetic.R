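## Synthetic bulk-tumor cohorts with planted cell states, co-occurrence
## communities, survival and therapy-response structure. The generator is the
## ground-truth oracle for every downstream module: it plants discrete states
## per cell type (marker up-shifts on a log-normal baseline), groups states
## across cell types into multicellular communities, mixes the per-type
## profiles by Dirichlet fractions, and attaches community-dependent hazards.

#' Generate the planted ground truth of a synthetic cohort
#'
#' Lays out the gene universe, per-type baseline expression profiles
#' (log-normal: log2 mean 3, sd 1.5 — microarray-like dynamic range),
#' disjoint marker genes per (cell type, state) with a common log2 effect
#' size, cross-cell-type state communities, per-sample community and state
#' labels (with an independent per-(sample, type) reassignment noise), and
#' Dirichlet cell-type fractions.
#'
#' Community \code{j} is defined by one state per cell type
#' (\code{((j - 1) mod K_t) + 1}), so every community spans all cell types
#' and distinct communities differ in at least one type whenever
#' \code{nCommunities <= max(kPerType)}.
#'
#' @param nGenes gene universe size; must be at least 50 per planted state.
#' @param cellTypes cell-type labels (at least 3 when communities are
#'   requested).
#' @param kPerType states per cell type; scalar or one value per type
#'   (each at least 2).
#' @param nMarkersPerState marker genes planted per state.
#' @param effectSizeLog2 log2 up-shift of marker genes in their state.
#' @param nCommunities number of multicellular communities.
#' @param communityNoiseRate probability that a (sample, type) state is
#'   reassigned away from its community's state; in [0, 0.5].
#' @param nSamples cohort size.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param dirichletConcentration Dirichlet concentration for cell-type
#'   fractions (scalar or per type).
#' @param hazardMultipliers positive hazard multiplier per community;
#'   default log2-evenly spaced from 1 to 2.
#' @param baselineLog2Mean,baselineLog2SD baseline log2 expression
#'   distribution parameters.
#' @param benefitStates data.frame (cellType, state) of states whose
#'   responders benefit from therapy; default the first community's state
#'   of the first cell type.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
generateTruth <- function(nGenes = 600,
                          cellTypes = c("B.cells", "Fibroblasts",
                                        "Epithelial.cells"),
                          kPerType = c(2L, 3L, 4L),
                          nMarkersPerState = 30,
                          effectSizeLog2 = 2,
                          nCommunities = 3,
                          communityNoiseRate = 0.1,
                          nSamples = 200,
                          seed = 1L,
                          dirichletConcentration = 2,
                          hazardMultipliers = NULL,
                          baselineLog2Mean = 3,
                          baselineLog2SD = 1.5,
                          benefitStates = NULL) {
  nTypes <- length(cellTypes)
  if (anyDuplicated(cellTypes)) stop("cell-type labels must be unique")
  kPerType <- as.integer(rep(kPerType, length.out = nTypes))
  names(kPerType) <- cellTypes
  if (any(kPerType < 2)) stop("each cell type needs at least 2 states")
  if (communityNoiseRate < 0 || communityNoiseRate > 0.5)
    stop("communityNoiseRate must lie in [0, 0.5]")
  totalStates <- sum(kPerType)
  if (nGenes < 50 * totalStates)
    stop(sprintf(
      "insufficient genes: %d provided, %d required (50 per state, %d states); deficit %d",
      nGenes, 50 * totalStates, totalStates, 50 * totalStates - nGenes))
  if (nCommunities >= 1 && nTypes < 3)
    stop("communities require at least 3 cell types")
  needMarkers <- totalStates * nMarkersPerState
  if (needMarkers > nGenes)
    stop(sprintf("insufficient genes for requested markers: need %d, have %d",
                 needMarkers, nGenes))
  if (is.null(hazardMultipliers))
    hazardMultipliers <- 2^seq(0, 1, length.out = nCommunities)
  hazardMultipliers <- rep(hazardMultipliers, length.out = nCommunities)

  withSeed(seed, {
    genes <- sprintf("G%05d", seq_len(nGenes))
    baseline <- matrix(
      2^rnorm(nGenes * nTypes, baselineLog2Mean, baselineLog2SD),
      nrow = nGenes, dimnames = list(genes, cellTypes))

    # disjoint marker blocks across all (type, state) pairs
    pool <- sample.int(nGenes, needMarkers)
    markerMap <- list()
    off <- 0L
    for (ct in cellTypes) {
      markerMap[[ct]] <- list()
      for (k in seq_len(kPerType[[ct]])) {
        idx <- pool[(off + 1L):(off + nMarkersPerState)]
        off <- off + nMarkersPerState
        markerMap[[ct]][[k]] <- data.frame(
          gene = genes[idx], effectLog2 = effectSizeLog2,
          stringsAsFactors = FALSE)
      }
    }

    communityDefs <- lapply(seq_len(nCommunities), function(j) {
      setNames(((j - 1L) %% kPerType) + 1L, cellTypes)
    })

    samples <- sprintf("S%04d", seq_len(nSamples))
    sampleCommunity <- setNames(
      sample.int(nCommunities, nSamples, replace = TRUE), samples)
    sampleStates <- matrix(0L, nSamples, nTypes,
                           dimnames = list(samples, cellTypes))
    for (ct in cellTypes) {
      st <- vapply(communityDefs, `[[`, 1L, ct)[sampleCommunity]
      flip <- runif(nSamples) < communityNoiseRate
      if (any(flip)) {
        st[flip] <- vapply(st[flip], function(s) {
          others <- setdiff(seq_len(kPerType[[ct]]), s)
          others[sample.int(length(others), 1L)]
        }, 1L)
      }
      sampleStates[, ct] <- st
    }

    fractions <- dirichletRows(
      nSamples, rep(dirichletConcentration, length.out = nTypes))
    dimnames(fractions) <- list(samples, cellTypes)

    if (is.null(benefitStates))
      benefitStates <- data.frame(cellType = cellTypes[1L],
                                  state = communityDefs[[1L]][[1L]],
                                  stringsAsFactors = FALSE)

    new("SyntheticTruth", geneIDs = genes, cellTypes = cellTypes,
        statesPerType = kPerType, baseline = baseline,
        markerMap = markerMap, communityDefs = communityDefs,
        sampleCommunity = sampleCommunity, sampleStates = sampleStates,
        fractions = fractions, hazardMultipliers = hazardMultipliers,
        responseBenefitStates = benefitStates,
        noiseRate = communityNoiseRate, seed = as.integer(seed))
  })
}

# Dirichlet rows via normalized gamma draws.
dirichletRows <- function(n, alpha) {
  if (any(alpha <= 0)) stop("Dirichlet concentration entries must be > 0")
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Draw per-sample cell-type fractions on the simplex
#'
#' @param truth a \linkS4class{SyntheticTruth} (defines samples and types).
#' @param concentration Dirichlet concentration, scalar or one per type.
#' @param seed integer seed.
#' @return samples x types matrix with non-negative rows summing to 1.
#' @export
simulateFractions <- function(truth, concentration = 2, seed = 1L) {
  ct <- cellTypes(truth)
  alpha <- rep(concentration, length.out = length(ct))
  if (any(alpha <= 0)) stop("Dirichlet concentration entries must be > 0")
  withSeed(seed, {
    f <- dirichletRows(nrow(truth@sampleStates), alpha)
    dimnames(f) <- dimnames(truth@sampleStates)
    f
  })
}

# Per-(type, state) expression profile: baseline with marker up-shifts.
stateProfile <- function(truth, cellType, state) {
  p <- truth@baseline[, cellType]
  mm <- truth@markerMap[[cellType]][[state]]
  if (!is.null(mm) && nrow(mm))
    p[mm$gene] <- p[mm$gene] * 2^mm$effectLog2
  p
}

#' Mix planted per-type profiles into a bulk expression matrix
#'
#' The bulk value for gene g in sample s is
#' \code{sum_c f_sc * x_gc(state of s in type c)}, where marker genes are
#' up-shifted by their planted log2 effect in their state, followed by
#' multiplicative log-normal noise of the given log2 sd. With zero noise
#' the output is the exact mixture.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param fractions samples x types simplex matrix; defaults to the
#'   fractions planted in \code{truth}.
#' @param noiseSdLog2 sd of the multiplicative log2-normal noise.
#' @param seed integer seed (noise only).
#' @return a linear-scale \linkS4class{ExpressionMatrix}.
#' @export
simulateBulk <- function(truth, fractions = NULL, noiseSdLog2 = 0.5,
                         seed = 1L) {
  if (is.null(fractions)) fractions <- truth@fractions
  samples <- rownames(truth@sampleStates)
  if (!identical(rownames(fractions), samples))
    stop("fractions rows do not align with the truth's samples")
  genes <- truth@geneIDs
  n <- length(samples)
  bulk <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  for (ct in cellTypes(truth)) {
    profiles <- vapply(seq_len(truth@statesPerType[[ct]]),
                       function(k) stateProfile(truth, ct, k),
                       numeric(length(genes)))
    st <- truth@sampleStates[, ct]
    bulk <- bulk + profiles[, st, drop = FALSE] *
      rep(fractions[, ct], each = length(genes))
  }
  if (noiseSdLog2 > 0) {
    withSeed(seed, {
      bulk <- bulk * 2^matrix(rnorm(length(bulk), 0, noiseSdLog2),
                              nrow = nrow(bulk))
    })
  }
  ExpressionMatrix(bulk, scale = "linear")
}

#' Simulate a validation cohort from the same generative truth
#'
#' New samples are drawn from the identical generative process (same genes,
#' baselines, markers and communities) with disjoint sample ids prefixed
#' "V", so discovery-cohort models can be recovered on held-out data.
#'
#' @param truth the discovery \linkS4class{SyntheticTruth}.
#' @param nSamples validation cohort size (0 gives an empty matrix over the
#'   full gene list).
#' @param seed integer seed.
#' @param noiseSdLog2 multiplicative noise sd (log2).
#' @param concentration Dirichlet concentration for the new fractions.
#' @return list with elements \code{expression} (ExpressionMatrix) and
#'   \code{truth} (a SyntheticTruth describing the validation samples).
#' @export
simulateValidationCohort <- function(truth, nSamples, seed = 1L,
                                     noiseSdLog2 = 0.5,
                                     concentration = 2) {
  ct <- cellTypes(truth)
  genes <- truth@geneIDs
  vt <- truth
  withSeed(seed, {
    samples <- if (nSamples > 0) sprintf("V%04d", seq_len(nSamples))
               else character(0)
    nCommunities <- length(truth@communityDefs)
    sampleCommunity <- setNames(
      if (nSamples > 0) sample.int(nCommunities, nSamples, replace = TRUE)
      else integer(0), samples)
    sampleStates <- matrix(0L, nSamples, length(ct),
                           dimnames = list(samples, ct))
    for (tt in ct) {
      if (nSamples == 0) break
      st <- vapply(truth@communityDefs, `[[`, 1L, tt)[sampleCommunity]
      flip <- runif(nSamples) < truth@noiseRate
      if (any(flip)) {
        st[flip] <- vapply(st[flip], function(s) {
          others <- setdiff(seq_len(truth@statesPerType[[tt]]), s)
          others[sample.int(length(others), 1L)]
        }, 1L)
      }
      sampleStates[, tt] <- st
    }
    fractions <- if (nSamples > 0) {
      f <- dirichletRows(nSamples, rep(concentration, length.out = length(ct)))
      dimnames(f) <- list(samples, ct)
      f
    } else {
      matrix(numeric(0), 0, length(ct),
             dimnames = list(character(0), ct))
    }
    vt@sampleCommunity <- sampleCommunity
    vt@sampleStates <- sampleStates
    vt@fractions <- fractions
    vt@seed <- as.integer(seed)
  })
  expr <- if (nSamples > 0) {
    simulateBulk(vt, noiseSdLog2 = noiseSdLog2, seed = subSeed(seed, 1L))
  } else {
    ExpressionMatrix(matrix(numeric(0), length(genes), 0,
                            dimnames = list(genes, character(0))))
  }
  list(expression = expr, truth = vt)
}

# Hazard per sample: baseline x community multiplier.
sampleHazards <- function(truth, baselineHazard) {
  baselineHazard * truth@hazardMultipliers[truth@sampleCommunity]
}

# Exponential censoring rate giving the requested marginal censoring
# fraction for heterogeneous exponential event hazards h.
solveCensoringRate <- function(h, target) {
  if (target <= 0) return(0)
  f <- function(logc) mean(exp(logc) / (exp(logc) + h)) - target
  exp(uniroot(f, lower = log(min(h)) - 20, upper = log(max(h)) + 20,
              tol = 1e-12)$root)
}

#' Simulate right-censored survival with community-dependent hazards
#'
#' Event times are exponential with hazard \code{baselineHazard} times the
#' planted hazard multiplier of the sample's community; censoring is an
#' independent exponential whose rate is solved numerically so that the
#' expected marginal censoring fraction equals \code{censoringRate}.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param baselineHazard baseline exponential event rate (> 0).
#' @param censoringRate target marginal censoring fraction in [0, 1).
#' @param seed integer seed.
#' @return a \linkS4class{SurvivalData}.
#' @export
simulateSurvival <- function(truth, baselineHazard = 0.1,
                             censoringRate = 0.3, seed = 1L) {
  if (baselineHazard <= 0) stop("baselineHazard must be > 0")
  if (censoringRate < 0 || censoringRate >= 1)
    stop("censoringRate must lie in [0, 1)")
  h <- sampleHazards(truth, baselineHazard)
  n <- length(h)
  withSeed(seed, {
    tEvent <- rexp(n, h)
    if (censoringRate == 0) {
      SurvivalData(names(truth@sampleCommunity), tEvent, rep(1L, n))
    } else {
      cRate <- solveCensoringRate(h, censoringRate)
      tCens <- rexp(n, cRate)
      SurvivalData(names(truth@sampleCommunity), pmin(tEvent, tCens),
                   as.integer(tEvent <= tCens))
    }
  })
}

# TRUE for samples whose planted state matches any benefit (type, state).
inBenefitState <- function(truth) {
  bs <- truth@responseBenefitStates
  hit <- rep(FALSE, nrow(truth@sampleStates))
  for (i in seq_len(nrow(bs)))
    hit <- hit | truth@sampleStates[, bs$cellType[i]] == bs$state[i]
  hit
}

#' Simulate therapy response with state-dependent benefit
#'
#' Response labels are assigned 50/50 independently of states (no
#' confounding). Responders whose planted state is in the truth's benefit
#' set have their event hazard multiplied by
#' \code{benefitHazardReduction}; everyone else is unchanged, so any
#' responder/non-responder survival difference is attributable to the
#' state-by-response interaction alone.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param baselineHazard baseline exponential event rate.
#' @param benefitHazardReduction multiplicative hazard reduction in (0, 1]
#'   applied to responders inside benefit states.
#' @param censoringRate marginal censoring fraction in [0, 1).
#' @param seed integer seed.
#' @return a \linkS4class{SurvivalData} with response labels.
#' @export
simulateResponse <- function(truth, baselineHazard = 0.1,
                             benefitHazardReduction = 0.5,
                             censoringRate = 0, seed = 1L) {
  if (benefitHazardReduction <= 0 || benefitHazardReduction > 1)
    stop("benefitHazardReduction must lie in (0, 1]")
  h <- sampleHazards(truth, baselineHazard)
  n <- length(h)
  withSeed(seed, {
    responder <- rbinom(n, 1L, 0.5) == 1L
    h[responder & inBenefitState(truth)] <-
      h[responder & inBenefitState(truth)] * benefitHazardReduction
    tEvent <- rexp(n, h)
    if (censoringRate > 0) {
      cRate <- solveCensoringRate(h, censoringRate)
      tCens <- rexp(n, cRate)
      time <- pmin(tEvent, tCens)
      event <- as.integer(tEvent <= tCens)
    } else {
      time <- tEvent
      event <- rep(1L, n)
    }
    SurvivalData(names(truth@sampleCommunity), time, event,
                 ifelse(responder, "responder", "non_responder"))
  })
}

#' True per-type mean expression profiles as a signature matrix
#'
#' Averages each cell type's per-state profiles (unweighted across states);
#' with zero marker effect this is exactly the planted baseline, making
#' noiseless mixtures exactly identifiable.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return a \linkS4class{SignatureMatrix}.
#' @export
signatureFromTruth <- function(truth) {
  sig <- vapply(cellTypes(truth), function(ct) {
    rowMeans(vapply(seq_len(truth@statesPerType[[ct]]),
                    function(k) stateProfile(truth, ct, k),
                    numeric(length(truth@geneIDs))))
  }, numeric(length(truth@geneIDs)))
  rownames(sig) <- truth@geneIDs
  SignatureMatrix(sig)
}
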