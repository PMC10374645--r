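# Synthetic-cohort generator: determinism, planted structure, calibration.

test_that("generateTruth is deterministic and respects its invariants", {
  t1 <- generateTruth(seed = 7)
  t2 <- generateTruth(seed = 7)
  expect_identical(t1@sampleStates, t2@sampleStates)
  expect_identical(t1@baseline, t2@baseline)
  expect_identical(t1@fractions, t2@fractions)

  # fractions are simplex rows
  expect_true(all(t1@fractions >= 0))
  expect_true(all(abs(rowSums(t1@fractions) - 1) < 1e-9))

  # marker sets disjoint within (and here, across) types
  genes <- unlist(lapply(t1@markerMap, function(l)
    lapply(l, function(d) d$gene)))
  expect_false(anyDuplicated(genes) > 0)

  # every community spans >= 3 states from >= 3 types
  for (cd in t1@communityDefs) {
    expect_gte(length(cd), 3)
    expect_gte(length(unique(names(cd))), 3)
  }
})

test_that("generateTruth validates its sizing preconditions", {
  expect_error(generateTruth(nGenes = 100, seed = 1), "insufficient genes")
  expect_error(generateTruth(communityNoiseRate = 0.7, seed = 1),
               "communityNoiseRate")
  expect_error(generateTruth(kPerType = c(1, 2, 2), seed = 1),
               "at least 2 states")
})

test_that("zero community noise makes states fully community-determined", {
  tr <- generateTruth(communityNoiseRate = 0, nCommunities = 1, seed = 3)
  # single community, zero noise: all samples share one state vector
  expect_equal(nrow(unique(tr@sampleStates)), 1L)

  tr2 <- generateTruth(communityNoiseRate = 0, nCommunities = 2, seed = 3)
  for (ct in cellTypes(tr2)) {
    predicted <- vapply(tr2@communityDefs, `[[`, 1L, ct)[tr2@sampleCommunity]
    expect_identical(unname(tr2@sampleStates[, ct]), unname(predicted))
  }
})

test_that("community noise rate is realized to within binomial error", {
  tr <- generateTruth(nSamples = 1000, communityNoiseRate = 0.2, seed = 11)
  expected <- t(vapply(seq_len(nrow(tr@sampleStates)), function(i) {
    vapply(tr@communityDefs[[tr@sampleCommunity[i]]], identity, 1L)
  }, tr@sampleStates[1, ]))
  disagree <- mean(expected != tr@sampleStates)
  # a flip can land back on the community state only when K allows;
  # here all other states differ, so disagreement tracks the rate
  expect_lt(abs(disagree - 0.2), 0.03)
})

test_that("simulateFractions draws calibrated Dirichlet rows", {
  tr <- generateTruth(nSamples = 10000, seed = 5)
  f <- simulateFractions(tr, concentration = 1, seed = 9)
  expect_true(all(abs(rowSums(f) - 1) < 1e-9))
  expect_true(all(f >= 0))
  expect_true(all(abs(colMeans(f) - 1 / 3) < 0.01))

  # concentrated Dirichlet pins every row near the uniform composition
  fu <- simulateFractions(tr, concentration = 1e6, seed = 9)
  expect_true(all(abs(fu - 1 / 3) < 1e-2))

  expect_error(simulateFractions(tr, concentration = 0), "concentration")
})

test_that("noiseless bulk equals the exact planted mixture", {
  tr <- generateTruth(nSamples = 30, seed = 13)
  bulk <- simulateBulk(tr, noiseSdLog2 = 0, seed = 1)
  # reconstruct the mixture by hand from truth
  expected <- matrix(0, length(tr@geneIDs), 30)
  for (ci in seq_along(cellTypes(tr))) {
    ct <- cellTypes(tr)[ci]
    for (s in seq_len(30)) {
      p <- EcoStates:::stateProfile(tr, ct, tr@sampleStates[s, ct])
      expected[, s] <- expected[, s] + tr@fractions[s, ct] * p
    }
  }
  expect_lt(max(abs(exprs(bulk) - expected)), 1e-9)
})

test_that("planted marker fold change is realized in noiseless bulk of a
           single dominating type", {
  # one type at fraction ~1: marker ratio in its state = 2^effect
  tr <- generateTruth(effectSizeLog2 = 3, nCommunities = 4, seed = 17)
  f <- tr@fractions
  f[] <- 0
  f[, 1] <- 1
  bulk <- exprs(simulateBulk(tr, fractions = f, noiseSdLog2 = 0, seed = 1))
  ct <- cellTypes(tr)[1]
  mk <- tr@markerMap[[ct]][[1]]$gene
  inS <- tr@sampleStates[, ct] == 1
  ratio <- rowMeans(bulk[mk, inS, drop = FALSE]) /
    rowMeans(bulk[mk, !inS, drop = FALSE])
  expect_true(all(abs(ratio - 2^3) < 1e-9))
})

test_that("validation cohorts share the generative process", {
  tr <- generateTruth(seed = 23)
  v <- simulateValidationCohort(tr, 150, seed = 31, noiseSdLog2 = 0)
  expect_identical(geneIDs(v$expression), tr@geneIDs)
  expect_false(any(sampleIDs(v$expression) %in% sampleIDs(tr)))

  # determinism
  v2 <- simulateValidationCohort(tr, 150, seed = 31, noiseSdLog2 = 0)
  expect_identical(exprs(v$expression), exprs(v2$expression))

  # degenerate size keeps the gene list
  v0 <- simulateValidationCohort(tr, 0, seed = 31)
  expect_identical(geneIDs(v0$expression), tr@geneIDs)
  expect_identical(ncol(exprs(v0$expression)), 0L)

  # marker fold-changes agree between discovery and validation cohorts
  ct <- cellTypes(tr)[2]
  mk <- tr@markerMap[[ct]][[1]]$gene
  lfc <- function(tt, X) {
    inS <- tt@sampleStates[, ct] == 1
    log2((rowMeans(X[mk, inS]) + 1) / (rowMeans(X[mk, !inS]) + 1))
  }
  d <- lfc(tr, exprs(simulateBulk(tr, noiseSdLog2 = 0, seed = 1)))
  vv <- lfc(v$truth, exprs(v$expression))
  expect_lt(median(abs(d - vv)), 0.2)
})

test_that("survival simulation matches exponential theory", {
  tr <- generateTruth(nSamples = 5000, hazardMultipliers = c(1, 1, 1),
                      seed = 41)
  sv <- simulateSurvival(tr, baselineHazard = 0.2, censoringRate = 0,
                         seed = 43)
  expect_true(all(sv@event == 1L))
  expect_lt(abs(mean(sv@time) - 1 / 0.2) / (1 / 0.2), 0.05)

  # Kaplan-Meier medians scale inversely with the hazard multiplier
  tr2 <- generateTruth(nSamples = 2000, nCommunities = 3,
                       hazardMultipliers = c(1, 2, 1), seed = 47)
  sv2 <- simulateSurvival(tr2, baselineHazard = 0.1, censoringRate = 0,
                          seed = 49)
  med <- tapply(sv2@time, tr2@sampleCommunity, median)
  expect_lt(abs(med[["2"]] / med[["1"]] - 0.5), 0.1)

  expect_error(simulateSurvival(tr, censoringRate = 1), "censoringRate")
})

test_that("censoring rate is calibrated", {
  tr <- generateTruth(nSamples = 5000, seed = 53)
  sv <- simulateSurvival(tr, baselineHazard = 0.1, censoringRate = 0.3,
                         seed = 59)
  expect_lt(abs(mean(sv@event == 0L) - 0.3), 0.03)
})

test_that("response benefit scales survival only inside benefit states", {
  tr <- generateTruth(nSamples = 2000, hazardMultipliers = c(1, 1, 1),
                      seed = 61)
  rs <- simulateResponse(tr, baselineHazard = 0.1,
                         benefitHazardReduction = 0.5, seed = 67)
  benefit <- EcoStates:::inBenefitState(tr)
  resp <- rs@response == "responder"
  medR <- median(rs@time[benefit & resp])
  medN <- median(rs@time[benefit & !resp])
  expect_lt(abs(medR / medN - 2), 0.3)
  # outside benefit states responders and non-responders are exchangeable
  outR <- median(rs@time[!benefit & resp])
  outN <- median(rs@time[!benefit & !resp])
  expect_lt(abs(outR / outN - 1), 0.25)
})
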