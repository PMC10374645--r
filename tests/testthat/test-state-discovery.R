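# Consensus-NMF state discovery: transform identities, NMF properties,
# consensus/cophenetic oracles, rank selection, markers and filtering.

test_that("nonnegTransform splits z-scores losslessly", {
  set.seed(1)
  X <- matrix(2^rnorm(300, 5, 1), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  X["g05", ] <- 7  # constant gene
  pur <- new("PurifiedExpression", cellType = "T", values = X,
             fittedLevel = rowMeans(X), typeScore = rep(NA_real_, 30),
             reliable = rep(TRUE, 30))
  expect_warning(tr <- nonnegTransform(pur), "zero-variance")
  expect_false("g05" %in% tr$genes)
  expect_true(all(tr$features >= 0))
  # positive minus negative part reconstructs the z-score exactly
  g <- length(tr$genes)
  Z <- tr$features[1:g, ] - tr$features[(g + 1):(2 * g), ]
  expected <- (log2(X[tr$genes, ] + 1) - tr$center) / tr$scale
  expect_lt(max(abs(Z - expected)), 1e-12)
  # the definition on a +1/-1 row
  zrow <- Z[1, ]
  expect_equal(pmax(zrow, 0) - pmax(-zrow, 0), zrow)
})

test_that("NMF objective is monotone and representable inputs are exact", {
  set.seed(2)
  w <- matrix(runif(30), 30, 1)
  h <- matrix(runif(8), 1, 8)
  V <- w %*% h
  dimnames(V) <- list(sprintf("f%02d", 1:30), sprintf("s%d", 1:8))
  fits <- runNMF(V, 1, nRestarts = 3, seed = 5)
  for (f in fits) {
    expect_true(all(diff(f$objective) <= 1e-8))
    relErr <- tail(f$objective, 1) / norm(V, "F")
    expect_lt(relErr, 1e-5)
  }
  # identical seed, identical result
  fits2 <- runNMF(V, 1, nRestarts = 3, seed = 5)
  expect_identical(fits[[2]]$H, fits2[[2]]$H)
})

test_that("block-diagonal structure is recovered at the true rank", {
  b1 <- matrix(runif(25, 1, 2), 5, 5)
  V <- rbind(cbind(b1, matrix(0, 5, 5)),
             cbind(matrix(0, 5, 5), matrix(runif(25, 1, 2), 5, 5)))
  dimnames(V) <- list(sprintf("f%02d", 1:10), sprintf("s%02d", 1:10))
  fits <- runNMF(V, 2, nRestarts = 5, seed = 3)
  best <- which.min(vapply(fits, function(f) tail(f$objective, 1), 1))
  cl <- apply(fits[[best]]$H, 2, which.max)
  expect_equal(adjustedRandIndex(cl, rep(1:2, each = 5)), 1)
})

test_that("runNMF validates rank and restart preconditions", {
  V <- matrix(runif(20), 4, 5)
  expect_error(runNMF(V, 4, seed = 1), "rank")
  expect_error(runNMF(V, 2, nRestarts = 0, seed = 1), "nRestarts")
})

test_that("consensus matrix equals hand-counted co-clustering fractions", {
  a <- list(c(1, 1, 2, 2), c(1, 2, 2, 2), c(1, 1, 1, 2))
  cm <- consensusMatrix(a)
  expect_equal(cm[1, 2], 2 / 3)
  expect_equal(cm[2, 3], 2 / 3)
  expect_equal(cm[3, 4], 2 / 3)
  expect_equal(cm[1, 4], 0)
  expect_true(all(diag(cm) == 1))
  expect_identical(cm, t(cm))
  # identical assignments give a binary consensus
  cid <- consensusMatrix(list(c(1, 1, 2), c(1, 1, 2)))
  expect_true(all(cid %in% c(0, 1)))
  expect_error(consensusMatrix(list(c(1, 2))), "at least 2 restarts")
})

test_that("subsampled consensus counts co-present restarts only", {
  a <- list(c(1, 1, NA), c(1, 2, 2), c(NA, 1, 1))
  cm <- consensusMatrix(a)
  expect_equal(cm[1, 2], 1 / 2)  # present together in restarts 1, 2
  expect_equal(cm[2, 3], 1)      # co-present in restarts 2, 3; same both
  expect_equal(cm[1, 3], 0)      # co-present only in restart 2, different
})

# the brute-force cophenetic oracle lives in helper-oracles.R

test_that("cophenetic coefficient matches a brute-force oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    M <- matrix(runif(n * n), n)
    cons <- (M + t(M)) / 2
    diag(cons) <- 1
    D <- 1 - cons
    cd <- bruteCophenetic(D)
    oracle <- cor(as.dist(D), as.dist(cd))
    expect_equal(copheneticCoefficient(cons), oracle, tolerance = 1e-12)
  }
})

test_that("cophenetic conventions: ultrametric and constant input", {
  cons <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(copheneticCoefficient(cons), 1)
  flat <- matrix(0.4, 3, 3)
  diag(flat) <- 1
  expect_warning(v <- copheneticCoefficient(flat), "constant")
  expect_equal(v, 1)
})

test_that("selectRank picks the value nearest the target with ties down", {
  expect_equal(selectRank(c(`2` = 0.99, `3` = 0.96, `4` = 0.80)), 3)
  expect_equal(selectRank(c(`2` = 0.93, `3` = 0.97)), 2)  # tie -> smaller
  expect_error(selectRank(numeric(0)), "empty")
  # exhaustive scan property on random maps
  set.seed(4)
  for (rep in 1:20) {
    v <- setNames(runif(6, 0.5, 1), 2:7)
    k <- selectRank(v)
    expect_equal(abs(v[as.character(k)] - 0.95), min(abs(v - 0.95)),
                 ignore_attr = TRUE)
  }
})

test_that("planted states are recovered end to end on one cell type", {
  co <- smallCohort()
  models <- smallModels()
  ct <- "Fibroblasts"
  a <- assignStates(models[[ct]])
  ari <- adjustedRandIndex(a@state,
                           co$truth@sampleStates[names(a@state), ct])
  expect_gte(ari, 0.7)
  # marker lists are disjoint across states by the argmax rule
  mk <- stateMarkers(models[[ct]])
  expect_false(anyDuplicated(unlist(lapply(mk, function(d) d$gene))) > 0)
  # planted markers dominate the discovered marker lists
  planted <- unlist(lapply(co$truth@markerMap[[ct]], function(d) d$gene))
  found <- unlist(lapply(mk, function(d) d$gene))
  expect_gt(mean(found %in% planted), 0.6)
})

test_that("assignStates takes the most abundant state with low-index ties", {
  H <- rbind(c(0.7, 0.5, 0.2), c(0.2, 0.5, 0.3), c(0.1, 0.0, 0.5))
  dimnames(H) <- list(c("S01", "S02", "S03"), c("p1", "p2", "p3"))
  m <- new("StateModel", cellType = "T", K = 3L,
           W = matrix(0.1, 4, 3,
                      dimnames = list(paste0("g", 1:4), rownames(H))),
           H = H, copheneticByRank = c(`3` = 0.95), markers = list(),
           droppedStates = character(0), featureGenes = character(0),
           featureCenter = numeric(0), featureScale = numeric(0),
           restarts = 1L, seed = 1L)
  a <- assignStates(m)
  expect_identical(unname(a@state), c(1L, 1L, 3L))
  expect_equal(unname(a@abundance), c(0.7, 0.5, 0.5))
})

test_that("filterStates drops marker-poor states and renormalizes H", {
  co <- smallCohort()
  ct <- "B.cells"
  pur <- purifyExpression(co$bulk, co$fractions, ct)
  model <- smallModels()[[ct]]
  # retained-state abundances sum to 1 per sample
  expect_true(all(abs(colSums(abundanceMatrix(model)) - 1) < 1e-8))
  # force an absurd marker threshold: every state is dropped
  expect_error(
    filterStates(model, pur, minMarkers = 1e6),
    "cell type excluded")
  # a state tracking total signal is removed when the proxy filter is on
  pur2 <- pur
  total <- colSums(exprs(pur)[, colnames(model@H)])
  m2 <- model
  m2@H[1, ] <- rank(total)
  dropped <- filterStates(m2, pur, minMarkers = 0, afiThreshold = 0.4,
                          applyAFIFilter = TRUE)
  expect_lt(dropped@K, m2@K)
  expect_true(any(grepl("false-positive", dropped@droppedStates)))
})
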