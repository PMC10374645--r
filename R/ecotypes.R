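## Multicellular community ("ecotype") discovery from cross-cell-type state
## co-occurrence: binary state-assignment matrix, pairwise Jaccard similarity
## gated by hypergeometric co-occurrence significance, average-linkage
## clustering with silhouette-width model selection, and per-sample ecotype
## abundance/dominance.

#' Build the binary state-assignment matrix
#'
#' Rows are states (named \code{cellType|state}), columns samples; entry 1
#' when the state is assigned to the sample. Samples lacking an assignment
#' for some cell type get all-zero rows for that type.
#'
#' @param assignments list of \linkS4class{StateAssignment} objects (>= 2
#'   cell types) over a shared sample universe.
#' @return a \linkS4class{BinaryAssignmentMatrix}.
#' @export
buildAssignmentMatrix <- function(assignments) {
  if (length(assignments) < 2)
    stop("need assignments for at least 2 cell types")
  samples <- Reduce(union, lapply(assignments, function(a) names(a@state)))
  if (!length(Reduce(intersect,
                     lapply(assignments, function(a) names(a@state)))))
    stop("assignments share no samples")
  rows <- list()
  info <- list()
  for (a in assignments) {
    ct <- a@cellType
    K <- max(a@state)
    for (s in seq_len(K)) {
      r <- setNames(rep(0, length(samples)), samples)
      hit <- names(a@state)[a@state == s]
      r[hit] <- 1
      rows[[paste(ct, sprintf("S%02d", s), sep = "|")]] <- r
      info[[length(info) + 1L]] <- data.frame(cellType = ct, state = s,
                                              stringsAsFactors = FALSE)
    }
  }
  A <- do.call(rbind, rows)
  new("BinaryAssignmentMatrix", A = A, stateInfo = do.call(rbind, info))
}

#' Pairwise Jaccard similarity of state sample sets
#'
#' \code{J[i, k] = |both| / |either|}; the diagonal is 1 and an empty union
#' gives 0 by convention.
#'
#' @param A binary states x samples matrix (or a
#'   \linkS4class{BinaryAssignmentMatrix}).
#' @return symmetric states x states matrix in [0, 1].
#' @export
jaccardMatrix <- function(A) {
  if (is(A, "BinaryAssignmentMatrix")) A <- A@A
  if (!all(A %in% c(0, 1))) stop("A must be binary")
  inter <- A %*% t(A)
  rs <- rowSums(A)
  uni <- outer(rs, rs, "+") - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  diag(J) <- 1
  dimnames(J) <- list(rownames(A), rownames(A))
  J
}

#' Hypergeometric co-occurrence significance per state pair
#'
#' For each pair of states from different cell types, tests the null of no
#' overlap between the two states' sample sets: with population the samples
#' assigned in both cell types, one state's count as draws and the other's
#' as successes, the one-sided upper-tail hypergeometric p of the observed
#' co-assignment count. Same-cell-type pairs get NA (states of one type are
#' mutually exclusive by construction); a zero population gives p = 1 with
#' a warning.
#'
#' @param bam a \linkS4class{BinaryAssignmentMatrix}.
#' @return symmetric states x states matrix of p-values (diagonal NA).
#' @export
overlapSignificance <- function(bam) {
  stopifnot(is(bam, "BinaryAssignmentMatrix"))
  A <- bam@A
  info <- bam@stateInfo
  nS <- nrow(A)
  # per cell type: which samples carry any assignment
  typeHas <- lapply(split(seq_len(nS), info$cellType), function(rows) {
    colSums(A[rows, , drop = FALSE]) > 0
  })
  P <- matrix(NA_real_, nS, nS, dimnames = list(rownames(A), rownames(A)))
  warned <- FALSE
  for (i in seq_len(nS - 1L)) {
    for (k in (i + 1L):nS) {
      if (info$cellType[i] == info$cellType[k]) next
      pop <- typeHas[[info$cellType[i]]] & typeHas[[info$cellType[k]]]
      N <- sum(pop)
      if (N == 0) {
        if (!warned) {
          warning("state pair with empty population; p set to 1")
          warned <- TRUE
        }
        P[i, k] <- P[k, i] <- 1
        next
      }
      ni <- sum(A[i, pop])
      nk <- sum(A[k, pop])
      ov <- sum(A[i, pop] * A[k, pop])
      P[i, k] <- P[k, i] <- phyper(ov - 1, nk, N - nk, ni,
                                   lower.tail = FALSE)
    }
  }
  P
}

#' Gate the Jaccard matrix by co-occurrence significance
#'
#' Default ("standard") gate: pairs with p > alpha are zeroed and
#' significant pairs keep their computed Jaccard value. The "literal" gate
#' implements the alternative reading in which non-significant pairs are
#' set to 1 and all others to 0; it is provided for comparison only, since
#' it rewards avoidance rather than co-occurrence. Same-cell-type pairs are
#' always zeroed and the diagonal forced to 1.
#'
#' @param J Jaccard matrix from \code{\link{jaccardMatrix}}.
#' @param pairP p-value matrix from \code{\link{overlapSignificance}}.
#' @param stateInfo data.frame (cellType, state) describing the rows, or a
#'   \linkS4class{BinaryAssignmentMatrix}.
#' @param alpha significance cutoff (default 0.01).
#' @param gate "standard" or "literal".
#' @return the gated Jaccard matrix.
#' @export
filterJaccard <- function(J, pairP, stateInfo, alpha = 0.01,
                          gate = c("standard", "literal")) {
  gate <- match.arg(gate)
  if (is(stateInfo, "BinaryAssignmentMatrix")) stateInfo <- stateInfo@stateInfo
  stopifnot(all(dim(J) == dim(pairP)))
  G <- J
  if (gate == "standard") {
    G[!is.na(pairP) & pairP > alpha] <- 0
  } else {
    G[] <- ifelse(!is.na(pairP) & pairP > alpha, 1, 0)
  }
  sameType <- outer(stateInfo$cellType, stateInfo$cellType, "==")
  G[sameType] <- 0
  diag(G) <- 1
  G
}

# Mean silhouette width of a labeling on a distance matrix.
meanSilhouette <- function(labels, D) {
  sil <- cluster::silhouette(labels, dmatrix = D)
  if (length(sil) == 1 && is.na(sil)) return(NA_real_)
  mean(sil[, "sil_width"])
}

#' Cluster states into candidate ecotypes
#'
#' Average-linkage hierarchical clustering on distance
#' \code{1 - gatedJaccard}; for each candidate cluster count k the mean
#' silhouette width on that distance is computed and the k maximizing it is
#' chosen (ties toward smaller k).
#'
#' @param gatedJ gated Jaccard matrix.
#' @param kRange candidate cluster counts (default 2 to
#'   \code{min(20, nStates - 1)}).
#' @return list with \code{ecotypeMap} (integer cluster per state),
#'   \code{silhouetteByK} and \code{chosenK}.
#' @export
clusterStates <- function(gatedJ, kRange = NULL) {
  nS <- nrow(gatedJ)
  if (nS < 4) stop("need at least 4 states to cluster")
  if (is.null(kRange)) kRange <- 2:min(20L, nS - 1L)
  kRange <- kRange[kRange >= 2 & kRange <= nS - 1L]
  if (!length(kRange)) stop("no admissible cluster counts")
  D <- 1 - gatedJ
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "average")
  silByK <- setNames(vapply(kRange, function(k) {
    meanSilhouette(cutree(hc, k = k), D)
  }, 1), kRange)
  ord <- order(-silByK, kRange)
  chosenK <- as.integer(kRange[ord][1L])
  map <- cutree(hc, k = chosenK)
  names(map) <- rownames(gatedJ)
  list(ecotypeMap = map, silhouetteByK = silByK, chosenK = chosenK)
}

#' Per-sample ecotype abundance and dominant ecotype
#'
#' Ecotypes with fewer than \code{minStates} member states are dismissed
#' (their states left unassigned). A sample's abundance for an ecotype is
#' the mean of the member states' normalized abundances, renormalized
#' across retained ecotypes to sum 1 (uniform when all are zero); the
#' dominant ecotype is the argmax with lowest-index ties.
#'
#' @param clustering result of \code{\link{clusterStates}}.
#' @param models list of filtered \linkS4class{StateModel}s (their H rows
#'   supply the state abundances; row keys \code{cellType|state}).
#' @param jaccard,pairP,gatedJ the matrices to store in the model.
#' @param minStates minimum member states per retained ecotype.
#' @return an \linkS4class{EcotypeModel}.
#' @export
assignEcotypes <- function(clustering, models, jaccard, pairP, gatedJ,
                           minStates = 3) {
  map <- clustering$ecotypeMap
  sizes <- table(map)
  retained <- as.integer(names(sizes)[sizes >= minStates])
  if (!length(retained))
    stop("all candidate ecotypes have fewer than the minimum member states")
  map[!(map %in% retained)] <- NA_integer_
  # relabel retained ecotypes consecutively as E1, E2, ...
  relabel <- setNames(seq_along(retained), retained)
  map[!is.na(map)] <- relabel[as.character(map[!is.na(map)])]
  eLabels <- paste0("E", seq_along(retained))

  # state abundance rows keyed cellType|state
  Hall <- do.call(rbind, lapply(models, function(m) {
    H <- m@H
    rownames(H) <- paste(m@cellType, rownames(H), sep = "|")
    H
  }))
  samples <- colnames(Hall)
  ab <- vapply(seq_along(retained), function(e) {
    member <- names(map)[!is.na(map) & map == e]
    colMeans(Hall[member, , drop = FALSE])
  }, numeric(length(samples)))
  ab <- matrix(ab, nrow = length(samples),
               dimnames = list(samples, eLabels))
  tot <- rowSums(ab)
  zero <- tot == 0
  if (any(zero)) ab[zero, ] <- 1 / length(eLabels)
  ab[!zero, ] <- ab[!zero, , drop = FALSE] / tot[!zero]
  domIdx <- apply(ab, 1L, function(r) which(r == max(r))[1L])
  new("EcotypeModel", jaccard = jaccard, pairP = pairP,
      gatedJaccard = gatedJ, ecotypeMap = setNames(as.integer(map),
                                                   names(map)),
      silhouetteByK = clustering$silhouetteByK,
      chosenK = clustering$chosenK, abundance = ab,
      dominant = setNames(eLabels[domIdx], samples))
}

#' Discover ecotypes from per-type state models
#'
#' Full co-occurrence pipeline: state assignments, binary matrix, Jaccard
#' similarity, hypergeometric gating, silhouette-selected clustering and
#' per-sample ecotype abundance.
#'
#' @param models list of filtered \linkS4class{StateModel}s (>= 2 types).
#' @param alpha gate significance cutoff.
#' @param gate gate direction (see \code{\link{filterJaccard}}).
#' @param kRange candidate ecotype counts.
#' @param minStates minimum states per retained ecotype.
#' @return an \linkS4class{EcotypeModel}.
#' @export
discoverEcotypes <- function(models, alpha = 0.01,
                             gate = c("standard", "literal"),
                             kRange = NULL, minStates = 3) {
  gate <- match.arg(gate)
  assignments <- lapply(models, assignStates)
  bam <- buildAssignmentMatrix(assignments)
  J <- jaccardMatrix(bam)
  P <- overlapSignificance(bam)
  G <- filterJaccard(J, P, bam, alpha = alpha, gate = gate)
  cl <- clusterStates(G, kRange = kRange)
  assignEcotypes(cl, models, J, P, G, minStates = minStates)
}

#' Ecotype network edge list
#'
#' Off-diagonal cross-type state pairs with their Jaccard index and
#' co-occurrence p-value, suitable for network viewers.
#'
#' @param model an \linkS4class{EcotypeModel}.
#' @return data.frame with columns stateA, stateB, jaccard, p.
#' @export
ecotypeEdgeList <- function(model) {
  J <- model@jaccard
  P <- model@pairP
  idx <- which(upper.tri(J) & !is.na(P), arr.ind = TRUE)
  data.frame(stateA = rownames(J)[idx[, 1]], stateB = colnames(J)[idx[, 2]],
             jaccard = J[idx], p = P[idx], stringsAsFactors = FALSE)
}
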