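# Ecotype discovery: assignment matrix, Jaccard, hypergeometric gating,
# silhouette-selected clustering, abundance and dominance.

test_that("binary assignment matrix matches a hand-written instance", {
  a1 <- toyAssignment("A", c(1, 2, 1))
  a2 <- toyAssignment("B", c(2, 2, 1))
  bam <- buildAssignmentMatrix(list(a1, a2))
  A <- bam@A
  expect_identical(rownames(A),
                   c("A|S01", "A|S02", "B|S01", "B|S02"))
  expect_equal(unname(A["A|S01", ]), c(1, 0, 1))
  expect_equal(unname(A["B|S02", ]), c(1, 1, 0))
  # column sums = number of cell types with an assignment per sample
  expect_equal(unname(colSums(A)), c(2, 2, 2))
  # row sums = per-state tallies
  expect_equal(unname(rowSums(A)),
               c(sum(a1@state == 1), sum(a1@state == 2),
                 sum(a2@state == 1), sum(a2@state == 2)))
  expect_error(buildAssignmentMatrix(list(a1)), "at least 2")
})

test_that("samples missing a type's assignment get all-zero rows", {
  a1 <- toyAssignment("A", c(1, 2, 1), c("p1", "p2", "p3"))
  a2 <- toyAssignment("B", c(1, 2), c("p1", "p2"))
  bam <- buildAssignmentMatrix(list(a1, a2))
  expect_equal(sum(bam@A[c("B|S01", "B|S02"), "p3"]), 0)
})

test_that("Jaccard matrix agrees with hand counts and conventions", {
  A <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0),
             c = c(1, 1, 0, 0), d = c(0, 0, 0, 0))
  J <- jaccardMatrix(A)
  expect_equal(J["a", "b"], 1 / 3)
  expect_equal(J["a", "c"], 1)      # identical rows
  expect_equal(J["b", "d"], 0)      # empty union -> 0 by convention
  expect_true(all(diag(J) == 1))
  expect_identical(J, t(J))
})

# exact enumeration oracle for the upper-tail hypergeometric p-value
enumHyper <- function(N, ni, nk, ov) {
  counts <- vapply(0:min(ni, nk), function(x) {
    choose(nk, x) * choose(N - nk, ni - x)
  }, 1)
  sum(counts[(0:min(ni, nk)) >= ov]) / choose(N, ni)
}

test_that("hypergeometric overlap p equals exact enumeration", {
  # the worked instance: N = 10, both states cover 5, full overlap
  a1 <- toyAssignment("A", c(rep(1, 5), rep(2, 5)))
  a2 <- toyAssignment("B", c(rep(1, 5), rep(2, 5)))
  bam <- buildAssignmentMatrix(list(a1, a2))
  P <- overlapSignificance(bam)
  expect_equal(P["A|S01", "B|S01"], 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(P["A|S01", "B|S01"], enumHyper(10, 5, 5, 5),
               tolerance = 1e-12)
  # zero overlap: upper-tail P(X >= 0) = 1
  expect_equal(P["A|S01", "B|S02"], 1, tolerance = 1e-12)
  # same-type pairs are not tested
  expect_true(is.na(P["A|S01", "A|S02"]))
})

test_that("hypergeometric p matches enumeration on random instances", {
  set.seed(33)
  for (rep in 1:25) {
    N <- sample(6:20, 1)
    s1 <- sample(1:2, N, replace = TRUE)
    s2 <- sample(1:2, N, replace = TRUE)
    bam <- buildAssignmentMatrix(list(toyAssignment("A", s1),
                                      toyAssignment("B", s2)))
    P <- overlapSignificance(bam)
    for (i in 1:2) {
      for (k in 1:2) {
        ni <- sum(s1 == i)
        nk <- sum(s2 == k)
        ov <- sum(s1 == i & s2 == k)
        if (ni == 0 || nk == 0) next
        expect_equal(P[paste0("A|S0", i), paste0("B|S0", k)],
                     enumHyper(N, ni, nk, ov), tolerance = 1e-12)
      }
    }
  }
})

test_that("the significance gate zeroes weak pairs and keeps strong ones", {
  J <- matrix(c(1, 0.4, 0.4, 1), 2,
              dimnames = list(c("A|S01", "B|S01"), c("A|S01", "B|S01")))
  P <- matrix(c(NA, 1e-6, 1e-6, NA), 2, dimnames = dimnames(J))
  info <- data.frame(cellType = c("A", "B"), state = c(1, 1))
  G <- filterJaccard(J, P, info)
  expect_equal(G["A|S01", "B|S01"], 0.4)
  P2 <- P; P2[1, 2] <- P2[2, 1] <- 0.5
  G2 <- filterJaccard(J, P2, info)
  expect_equal(G2["A|S01", "B|S01"], 0)
  # alpha = 1 keeps everything off the same-type mask
  G3 <- filterJaccard(J, P2, info, alpha = 1)
  expect_equal(G3["A|S01", "B|S01"], 0.4)
  # the literal gate direction is available but inverted
  G4 <- filterJaccard(J, P2, info, gate = "literal")
  expect_equal(G4["A|S01", "B|S01"], 1)
})

# the silhouette oracle lives in helper-oracles.R

test_that("silhouette-based clustering matches the brute-force oracle", {
  set.seed(44)
  M <- matrix(runif(36), 6)
  G <- (M + t(M)) / 2
  diag(G) <- 1
  rownames(G) <- colnames(G) <- paste0("T", 1:6, "|S01")
  cl <- clusterStates(G, kRange = 2:5)
  D <- 1 - G
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "average")
  for (k in 2:5) {
    expect_equal(cl$silhouetteByK[[as.character(k)]],
                 bruteSilhouette(cutree(hc, k), D), tolerance = 1e-12)
  }
  # chosen k attains the maximum (smaller k on ties)
  expect_equal(cl$chosenK,
               as.integer(names(which.max(cl$silhouetteByK))[1]))
})

test_that("two perfect blocks give k = 2 with silhouette 1", {
  G <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  rownames(G) <- colnames(G) <- paste0("T", 1:4, "|S01")
  cl <- clusterStates(G, kRange = 2:3)
  expect_equal(cl$chosenK, 2L)
  expect_equal(unname(cl$silhouetteByK["2"]), 1)
  expect_error(clusterStates(G[1:3, 1:3]), "at least 4 states")
})

test_that("ecotype abundance rows sum to 1 and dominance is deterministic", {
  models <- smallModels()
  eco <- discoverEcotypes(models)
  expect_true(all(abs(rowSums(eco@abundance) - 1) < 1e-8))
  expect_true(all(diag(eco@jaccard) == 1))
  # gated entries never exceed the raw Jaccard off-diagonal
  off <- upper.tri(eco@jaccard)
  expect_true(all(eco@gatedJaccard[off] <= eco@jaccard[off] + 1e-12))
  # every retained ecotype has >= 3 member states
  sizes <- table(na.omit(eco@ecotypeMap))
  expect_true(all(sizes >= 3))
  # dominance invariant under sample reordering (recompute from pieces)
  expect_identical(names(eco@dominant), rownames(eco@abundance))
  idx <- apply(eco@abundance, 1, function(r) which(r == max(r))[1])
  expect_identical(unname(eco@dominant),
                   colnames(eco@abundance)[idx])
})

test_that("planted communities are recovered as ecotypes", {
  # each community owns a distinct state in every type (K = communities)
  res <- cached("ecoRecovery", {
    truth <- generateTruth(kPerType = c(3, 3, 3), seed = 3)
    bulk <- simulateBulk(truth, noiseSdLog2 = 0.5, seed = 5003)
    fractions <- estimateFractions(bulk, signatureFromTruth(truth))
    models <- list()
    for (ct in cellTypes(truth)) {
      pur <- purifyExpression(bulk, fractions, ct)
      models[[ct]] <- discoverStates(pur, ranks = 2:6, nRestarts = 20,
                                     seed = 51, maxIter = 500, tol = 1e-5,
                                     nTopGenes = 150)
    }
    list(truth = truth, eco = discoverEcotypes(models))
  })
  expect_equal(res$eco@chosenK, 3L)
  ari <- adjustedRandIndex(
    res$eco@dominant, res$truth@sampleCommunity[names(res$eco@dominant)])
  expect_gte(ari, 0.7)
})

test_that("single retained ecotype renormalizes to abundance 1", {
  # build a degenerate clustering result by hand
  models <- smallModels()
  Hs <- lapply(models, abundanceMatrix)
  map <- unlist(lapply(names(models), function(ct) {
    setNames(rep(1L, nrow(Hs[[ct]])),
             paste(ct, rownames(Hs[[ct]]), sep = "|"))
  }))
  J <- diag(length(map))
  dimnames(J) <- list(names(map), names(map))
  cl <- list(ecotypeMap = map, silhouetteByK = c(`2` = 0.5), chosenK = 2L)
  eco <- assignEcotypes(cl, models, J, J, J, minStates = 3)
  expect_true(all(eco@abundance == 1))
  expect_true(all(eco@dominant == "E1"))
})
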