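## Consensus-NMF discovery of transcriptional cell states within one cell
## type. Purified expression is z-scored per gene and split into positive and
## negative parts (NMF needs non-negative input), factorized with
## multiplicative updates over a range of ranks with random restarts, and the
## rank whose consensus matrix has cophenetic coefficient closest to 0.95 is
## selected. States are characterized by marker genes (argmax basis loading
## plus log2 fold-change) and filtered by marker count and an
## abundance-false-positive proxy.

#' Non-negativize purified expression for NMF
#'
#' Standardizes each reliable gene across samples (mean 0, sd 1, computed
#' on the log2(x + 1) scale where multiplicative noise is homoscedastic)
#' and splits the z-scores into positive-part and negative-part feature
#' rows (suffixes \code{.pos} / \code{.neg}), so the signed structure is
#' representable in a non-negative factorization. Zero-variance genes are
#' dropped with a warning. Optionally restricts to the most variable genes
#' first.
#'
#' @param purified a \linkS4class{PurifiedExpression} with >= 2 samples and
#'   >= 10 reliable genes.
#' @param nTopGenes keep only this many reliable genes, ranked by the
#'   purification's type-specificity score (variance as fallback and tie
#'   break); default all.
#' @return list with \code{features} (non-negative 2g x samples matrix),
#'   \code{genes}, \code{center}, \code{scale}.
#' @export
nonnegTransform <- function(purified, nTopGenes = Inf) {
  stopifnot(is(purified, "PurifiedExpression"))
  X <- exprs(purified)[purified@reliable, , drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 samples")
  if (nrow(X) < 10) stop("need at least 10 reliable genes")
  X <- log2(X + 1)
  ctr <- rowMeans(X)
  scl <- apply(X, 1L, sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(!keep)))
    if (!any(keep)) stop("all genes have zero variance")
  }
  if (is.finite(nTopGenes) && sum(keep) > nTopGenes) {
    score <- purified@typeScore[purified@reliable]
    score[is.na(score)] <- -Inf
    ord <- order(-ifelse(keep, score, -Inf), -scl * keep)
    keep <- seq_len(nrow(X)) %in% ord[seq_len(nTopGenes)] & keep
  }
  X <- X[keep, , drop = FALSE]
  ctr <- ctr[keep]
  scl <- scl[keep]
  Z <- (X - ctr) / scl
  feats <- rbind(pmax(Z, 0), pmax(-Z, 0))
  rownames(feats) <- c(paste0(rownames(X), ".pos"),
                       paste0(rownames(X), ".neg"))
  list(features = feats, genes = rownames(X), center = ctr, scale = scl)
}

# Resolve NMF scaling indeterminacy: scale W columns to sum 1 and push the
# scale into H, so H rows are comparable across states.
normalizeWH <- function(W, H) {
  s <- colSums(W)
  s[s == 0] <- 1
  list(W = sweep(W, 2L, s, "/"), H = H * s)
}

#' Multiplicative-update NMF with random restarts
#'
#' Factorizes a non-negative matrix as W H under the Frobenius loss using
#' Lee-Seung multiplicative updates; the objective is non-increasing across
#' iterations. Restarts use deterministic sub-seeds derived from
#' \code{seed}, with uniform random initial factors.
#'
#' @param features non-negative matrix (features x samples).
#' @param rank factorization rank; must be smaller than both dimensions.
#' @param nRestarts number of random restarts (>= 1).
#' @param seed master seed.
#' @param maxIter iteration cap.
#' @param tol relative-change convergence tolerance on the Frobenius error.
#' @return list of per-restart fits, each with elements \code{W}, \code{H}
#'   (column-normalized basis), \code{objective} (error trace) and
#'   \code{iterations}.
#' @export
runNMF <- function(features, rank, nRestarts = 20, seed = 1L,
                   maxIter = 2000, tol = 1e-6) {
  m <- nrow(features)
  n <- ncol(features)
  if (rank >= min(m, n))
    stop(sprintf("rank %d must be < min(features, samples) = %d",
                 rank, min(m, n)))
  if (nRestarts < 1) stop("nRestarts must be >= 1")
  if (min(features) < 0) stop("features must be non-negative")
  a <- sqrt(mean(features) / rank)
  lapply(seq_len(nRestarts), function(r) {
    withSeed(subSeed(seed, r), {
      W0 <- matrix(runif(m * rank, 0, 2 * a), m, rank)
      H0 <- matrix(runif(rank * n, 0, 2 * a), rank, n)
      fit <- .nmf_mu(features, W0, H0, as.integer(maxIter), tol, TRUE, 10L)
      nw <- normalizeWH(fit$W, fit$H)
      rownames(nw$W) <- rownames(features)
      colnames(nw$H) <- colnames(features)
      list(W = nw$W, H = nw$H, objective = fit$objective,
           iterations = fit$iterations)
    })
  })
}

#' Consensus matrix across NMF restarts
#'
#' Entry (i, j) is the fraction of restarts in which samples i and j share
#' an argmax(H) cluster. Restarts may cover only a subsample of the cohort
#' (NA labels for the samples a restart did not see); the fraction is then
#' taken over the restarts in which both samples were present, the standard
#' consensus-clustering construction. With full-cohort restarts this
#' reduces to the plain co-clustering fraction.
#'
#' @param restartAssignments list (one per restart) of integer cluster
#'   labels per sample (argmax of H), NA for samples absent from that
#'   restart.
#' @return symmetric samples x samples matrix in [0, 1] with unit diagonal
#'   (pairs never co-present get 0).
#' @export
consensusMatrix <- function(restartAssignments) {
  if (length(restartAssignments) < 2)
    stop("consensus requires at least 2 restarts")
  n <- length(restartAssignments[[1L]])
  co <- matrix(0, n, n)
  present <- matrix(0, n, n)
  for (a in restartAssignments) {
    stopifnot(length(a) == n)
    p <- !is.na(a)
    present <- present + outer(p, p, "&")
    aa <- a
    aa[is.na(aa)] <- -1L
    co <- co + (outer(aa, aa, "==") & outer(p, p, "&"))
  }
  cm <- ifelse(present > 0, co / present, 0)
  diag(cm) <- 1
  cm
}

#' Cophenetic coefficient of a consensus matrix
#'
#' Pearson correlation between the original dissimilarities
#' \code{1 - consensus} and the cophenetic distances induced by their
#' average-linkage hierarchical clustering. Constant dissimilarities give 1
#' by convention (with a warning): a perfectly flat consensus carries no
#' evidence against stability.
#'
#' @param consensus symmetric matrix with unit diagonal.
#' @return a value in [0, 1] (up to sign: anti-correlated trees can in
#'   principle go negative, which never occurs for consensus input).
#' @export
copheneticCoefficient <- function(consensus) {
  if (nrow(consensus) != ncol(consensus) ||
      max(abs(consensus - t(consensus))) > 1e-8)
    stop("consensus must be symmetric")
  if (any(abs(diag(consensus) - 1) > 1e-8))
    stop("consensus diagonal must be 1")
  d <- as.dist(1 - consensus)
  if (sd(d) == 0) {
    warning("constant consensus dissimilarities; cophenetic defined as 1")
    return(1)
  }
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (sd(cd) == 0) {
    warning("degenerate cophenetic distances; coefficient defined as 1")
    return(1)
  }
  cor(d, cd)
}

#' Select the factorization rank closest to the cophenetic target
#'
#' Returns the rank whose cophenetic coefficient is nearest to
#' \code{target} (default 0.95); ties are broken toward the smaller rank.
#'
#' @param copheneticByRank named numeric (names are the ranks).
#' @param target target cophenetic coefficient.
#' @return the selected rank (integer).
#' @export
selectRank <- function(copheneticByRank, target = 0.95) {
  if (!length(copheneticByRank)) stop("empty cophenetic map")
  ranks <- as.integer(names(copheneticByRank))
  dev <- abs(copheneticByRank - target)
  ranks[order(dev, ranks)][1L]
}

#' Marker genes per state
#'
#' A gene is a marker of state s when its positive-part basis loading,
#' row-normalized across states, is maximal in s (lowest-index ties) and
#' its log2 fold-change — mean purified linear expression in samples of s
#' versus samples of all other states, with pseudocount 1 — is at least
#' \code{minLog2FC}. Marker lists are disjoint across states by the argmax
#' rule. States with no assigned samples are excluded with a warning.
#'
#' @param model a \linkS4class{StateModel} (markers may be empty).
#' @param purified the \linkS4class{PurifiedExpression} used for discovery.
#' @param assignment a \linkS4class{StateAssignment} for the same samples.
#' @param minLog2FC marker fold-change threshold (log2).
#' @return named list: one data.frame (gene, log2FC) per state.
#' @export
extractMarkers <- function(model, purified, assignment, minLog2FC = 1) {
  W <- model@W
  genes <- model@featureGenes
  Wpos <- W[paste0(genes, ".pos"), , drop = FALSE]
  rs <- rowSums(Wpos)
  rs[rs == 0] <- 1
  Wn <- Wpos / rs
  argmax <- apply(Wn, 1L, function(r) which(r == max(r))[1L])
  st <- assignment@state
  X <- exprs(purified)[genes, names(st), drop = FALSE]
  K <- model@K
  markers <- vector("list", K)
  names(markers) <- colnames(W)
  for (s in seq_len(K)) {
    inS <- st == s
    if (!any(inS)) {
      warning(sprintf("state %d has no assigned samples; excluded", s))
      markers[[s]] <- data.frame(gene = character(0), log2FC = numeric(0))
      next
    }
    cand <- which(argmax == s)
    if (!length(cand)) {
      markers[[s]] <- data.frame(gene = character(0), log2FC = numeric(0))
      next
    }
    mIn <- rowMeans(X[cand, inS, drop = FALSE])
    mOut <- rowMeans(X[cand, !inS, drop = FALSE])
    if (!any(!inS)) mOut <- mIn  # single-state edge: flat fold change
    lfc <- log2((mIn + 1) / (mOut + 1))
    sel <- lfc >= minLog2FC
    markers[[s]] <- data.frame(gene = genes[cand][sel],
                               log2FC = unname(lfc[sel]),
                               stringsAsFactors = FALSE)[
                                 order(-lfc[sel], genes[cand][sel]), ,
                                 drop = FALSE]
    rownames(markers[[s]]) <- NULL
  }
  markers
}

#' Filter spurious states and renormalize abundances
#'
#' Drops states with fewer than \code{minMarkers} marker genes, and (when
#' the abundance-false-positive filter is on) states whose abundance row
#' tracks the per-sample total purified background signal too closely —
#' absolute Spearman correlation above \code{afiThreshold}, where the
#' background excludes every state's marker genes so that genuine
#' transcriptional programs do not trip the filter — a proxy for
#' components that capture depth rather than a program. Remaining
#' abundance rows are renormalized so each sample's retained-state
#' abundances sum to 1; retained states are relabeled consecutively and the
#' dropped ones recorded with reasons.
#'
#' @param model a \linkS4class{StateModel} with markers computed.
#' @param purified the discovery \linkS4class{PurifiedExpression}.
#' @param minMarkers minimum marker count per retained state.
#' @param afiThreshold absolute Spearman correlation cutoff.
#' @param applyAFIFilter logical switch for the proxy filter.
#' @return the filtered \linkS4class{StateModel}.
#' @export
filterStates <- function(model, purified, minMarkers = 10,
                         afiThreshold = 0.4, applyAFIFilter = FALSE) {
  if (!length(model@markers)) stop("markers must be computed first")
  K <- model@K
  X <- exprs(purified)[, colnames(model@H), drop = FALSE]
  allMarkers <- unique(unlist(lapply(model@markers, function(d) d$gene)))
  background <- setdiff(rownames(X), allMarkers)
  total <- colSums(X[background, , drop = FALSE])
  reasons <- character(0)
  keep <- logical(K)
  for (s in seq_len(K)) {
    nm <- nrow(model@markers[[s]])
    if (nm < minMarkers) {
      reasons[colnames(model@W)[s]] <-
        sprintf("only %d marker genes (< %d)", nm, minMarkers)
      next
    }
    if (applyAFIFilter && length(background) >= 10) {
      afi <- abs(cor(model@H[s, ], total, method = "spearman"))
      if (!is.na(afi) && afi > afiThreshold) {
        reasons[colnames(model@W)[s]] <-
          sprintf("abundance-false-positive proxy %.2f > %.2f",
                  afi, afiThreshold)
        next
      }
    }
    keep[s] <- TRUE
  }
  if (!any(keep))
    stop(sprintf("all %d states of '%s' were dropped (%s): cell type excluded",
                 K, model@cellType,
                 paste(unique(reasons), collapse = "; ")))
  W <- model@W[, keep, drop = FALSE]
  H <- model@H[keep, , drop = FALSE]
  cs <- colSums(H)
  cs[cs == 0] <- 1
  H <- sweep(H, 2L, cs, "/")
  labs <- sprintf("S%02d", seq_len(sum(keep)))
  colnames(W) <- labs
  rownames(H) <- labs
  model@W <- W
  model@H <- H
  model@K <- sum(keep)
  model@markers <- setNames(model@markers[keep], labs)
  model@droppedStates <- c(model@droppedStates, reasons)
  model
}

#' Discrete state assignment by most-abundant state
#'
#' Each sample is assigned the state with the largest abundance in its H
#' column; ties break to the lowest state index.
#'
#' @param model a (filtered) \linkS4class{StateModel}.
#' @return a \linkS4class{StateAssignment}.
#' @export
assignStates <- function(model) {
  H <- model@H
  idx <- argmaxByColumn(H)
  new("StateAssignment", cellType = model@cellType,
      state = setNames(as.integer(idx), colnames(H)),
      abundance = setNames(H[cbind(idx, seq_len(ncol(H)))], colnames(H)))
}

#' Discover cell states for one cell type by consensus NMF
#'
#' Runs the full per-type discovery: non-negative feature transform, NMF
#' with \code{nRestarts} restarts at every rank in \code{ranks}, consensus
#' clustering of the restart argmax assignments, cophenetic-coefficient
#' rank selection (closest to \code{copheneticTarget}), refit selection
#' (best-objective restart at the chosen rank), marker extraction and
#' state filtering.
#'
#' @param purified a \linkS4class{PurifiedExpression}.
#' @param ranks candidate ranks; capped at \code{nSamples - 1}.
#' @param nRestarts NMF restarts per rank.
#' @param seed master seed; all restart sub-seeds derive from it.
#' @param maxIter,tol NMF iteration controls.
#' @param copheneticTarget rank-selection target (0.95).
#' @param minLog2FC marker log2 fold-change threshold.
#' @param minMarkers minimum markers per retained state.
#' @param afiThreshold,applyAFIFilter state-filter controls
#'   (see \code{\link{filterStates}}).
#' @param nTopGenes restrict discovery to this many genes (by
#'   type-specificity score).
#' @param subsampleRate fraction of samples drawn per consensus restart;
#'   subsampling perturbs the clustering so that over-fitted ranks reveal
#'   their instability in the cophenetic trace.
#' @param consensusReplicates independent consensus replicates per rank;
#'   the cophenetic coefficient is averaged over them to reduce the
#'   variance of the stability estimate.
#' @return a filtered \linkS4class{StateModel}.
#' @export
discoverStates <- function(purified, ranks = 2:20, nRestarts = 20,
                           seed = 1L, maxIter = 2000, tol = 1e-6,
                           copheneticTarget = 0.95, minLog2FC = 1,
                           minMarkers = 10, afiThreshold = 0.4,
                           applyAFIFilter = FALSE, nTopGenes = Inf,
                           subsampleRate = 0.35,
                           consensusReplicates = 3) {
  stopifnot(subsampleRate > 0, subsampleRate <= 1)
  tr <- nonnegTransform(purified, nTopGenes = nTopGenes)
  V <- tr$features
  n <- ncol(V)
  ranks <- ranks[ranks >= 2 & ranks <= min(n - 1L, nrow(V) - 1L)]
  if (!length(ranks)) stop("no admissible ranks for this input size")
  nSub <- max(2L, round(subsampleRate * n))
  coph <- setNames(numeric(length(ranks)), ranks)
  for (i in seq_along(ranks)) {
    k <- ranks[i]
    vals <- vapply(seq_len(consensusReplicates), function(rep) {
      assigns <- lapply(seq_len(nRestarts), function(r) {
        rs <- subSeed(seed, 100000L * rep + 1000L * k + r)
        idx <- if (nSub < n) {
          withSeed(rs, sort(sample.int(n, nSub)))
        } else seq_len(n)
        fit <- runNMF(V[, idx, drop = FALSE], k, nRestarts = 1, seed = rs,
                      maxIter = maxIter, tol = tol)[[1L]]
        a <- rep(NA_integer_, n)
        a[idx] <- unname(argmaxByColumn(fit$H))
        a
      })
      if (nRestarts >= 2) {
        suppressWarnings(copheneticCoefficient(consensusMatrix(assigns)))
      } else NA_real_
    }, 1)
    coph[i] <- mean(vals)
  }
  K <- selectRank(coph[!is.na(coph)], target = copheneticTarget)
  # refit on the full cohort at the selected rank; keep the best restart.
  # the single refit is cheap, so it always runs to full convergence even
  # when the rank scan uses a looser budget
  fits <- runNMF(V, K, nRestarts = nRestarts, seed = subSeed(seed, K),
                 maxIter = max(maxIter, 2000), tol = min(tol, 1e-6))
  best <- which.min(vapply(fits, function(f) tail(f$objective, 1L), 1))
  W <- fits[[best]]$W
  H <- fits[[best]]$H
  labs <- sprintf("S%02d", seq_len(K))
  colnames(W) <- labs
  rownames(H) <- labs
  model <- new("StateModel", cellType = purified@cellType, K = as.integer(K),
               W = W, H = H, copheneticByRank = coph,
               markers = list(), droppedStates = character(0),
               featureGenes = tr$genes, featureCenter = tr$center,
               featureScale = tr$scale, restarts = as.integer(nRestarts),
               seed = as.integer(seed))
  assignment <- assignStates(model)
  model@markers <- extractMarkers(model, purified, assignment,
                                  minLog2FC = minLog2FC)
  filterStates(model, purified, minMarkers = minMarkers,
               afiThreshold = afiThreshold,
               applyAFIFilter = applyAFIFilter)
}
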