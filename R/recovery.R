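## Reference-based recovery of discovery-cohort cell states in new cohorts:
## the learned basis W is held fixed and the abundance matrix H' is re-solved
## jointly on all new samples with multiplicative updates; per-state recovery
## is scored by the correlation between discovery marker fold-changes and the
## fold-changes recomputed in the new cohort, against a marker-label
## permutation null.

# Extract a linear-scale matrix from any expression-bearing object.
linearMatrix <- function(x) {
  if (is(x, "PurifiedExpression")) return(exprs(x))
  if (is(x, "ExpressionMatrix")) return(linearize(x))
  if (is.matrix(x)) return(x)
  stop("expected a PurifiedExpression, ExpressionMatrix or matrix")
}

# Project a new cohort onto the model's feature space using the stored
# standardization parameters; returns the feature matrix and the matching
# rows of W.
projectFeatures <- function(X, model, minCoverage = 0.5) {
  shared <- intersect(model@featureGenes, rownames(X))
  coverage <- length(shared) / length(model@featureGenes)
  if (coverage < minCoverage)
    stop(sprintf(
      "recovery refused: only %.0f%% of the %d model genes present (need %.0f%%)",
      100 * coverage, length(model@featureGenes), 100 * minCoverage))
  Z <- (log2(X[shared, , drop = FALSE] + 1) - model@featureCenter[shared]) /
    model@featureScale[shared]
  V <- rbind(pmax(Z, 0), pmax(-Z, 0))
  rownames(V) <- c(paste0(shared, ".pos"), paste0(shared, ".neg"))
  list(V = V, W = model@W[rownames(V), , drop = FALSE],
       coverage = coverage)
}

#' Recover state abundances in a new cohort with the basis fixed
#'
#' The new cohort is standardized with the discovery transform parameters,
#' split into positive/negative features over the genes shared with the
#' model, and the abundance matrix H' is solved jointly on all samples by
#' multiplicative updates with W held fixed (constant initialization, hence
#' fully deterministic). Columns of H' are renormalized to sum 1.
#'
#' @param newMatrix a \linkS4class{PurifiedExpression},
#'   \linkS4class{ExpressionMatrix} or plain linear-scale matrix for the
#'   new cohort.
#' @param model the discovery \linkS4class{StateModel}.
#' @param maxIter,tol multiplicative-update controls.
#' @param minCoverage minimum fraction of model genes that must be present.
#' @return H' (states x new samples), columns summing to 1.
#' @export
recoverAbundances <- function(newMatrix, model, maxIter = 2000, tol = 1e-6,
                              minCoverage = 0.5) {
  X <- linearMatrix(newMatrix)
  pr <- projectFeatures(X, model, minCoverage)
  k <- ncol(pr$W)
  H0 <- matrix(mean(pr$V) / max(k, 1), k, ncol(pr$V))
  fit <- .nmf_mu(pr$V, pr$W, H0, as.integer(maxIter), tol, FALSE, 10L)
  H <- fit$H
  cs <- colSums(H)
  cs[cs == 0] <- 1
  H <- sweep(H, 2L, cs, "/")
  dimnames(H) <- list(colnames(model@W), colnames(X))
  H
}

# Marker log2 fold-changes for a gene set under given group labels.
groupLog2FC <- function(X, genes, inGroup) {
  mIn <- rowMeans(X[genes, inGroup, drop = FALSE])
  mOut <- rowMeans(X[genes, !inGroup, drop = FALSE])
  log2((mIn + 1) / (mOut + 1))
}

#' Permutation significance of state recovery
#'
#' For each state s, the recovery score R_s is the Pearson correlation
#' between the discovery marker log2 fold-change vector and the
#' fold-changes of the same marker genes recomputed in the new cohort under
#' the recovered assignments. The null distribution replaces the marker
#' genes by random gene sets of the same size from the new cohort
#' (\code{nPerm} draws); \code{z = (R - nullMean)/nullSd} and the one-sided
#' empirical p is \code{(count(null >= R) + 1)/(nPerm + 1)}. A state is
#' significantly recovered when z > 1.65 and p < 0.05. States with fewer
#' than 2 assigned samples, too few usable markers, or a degenerate null
#' are reported unrecovered with a reason.
#'
#' @param newMatrix the new cohort (as in \code{\link{recoverAbundances}}).
#' @param model the discovery \linkS4class{StateModel}.
#' @param Hprime recovered abundances from \code{\link{recoverAbundances}}.
#' @param nPerm number of permutations.
#' @param seed integer seed for the permutation draws.
#' @return a \linkS4class{RecoveryResult}.
#' @export
recoverySignificance <- function(newMatrix, model, Hprime, nPerm = 1000,
                                 seed = 1L) {
  X <- linearMatrix(newMatrix)
  idx <- argmaxByColumn(Hprime)
  assignments <- setNames(as.integer(idx), colnames(Hprime))
  K <- nrow(Hprime)
  allGenes <- rownames(X)
  tab <- data.frame(state = rownames(Hprime), R = NA_real_,
                    nullMean = NA_real_, nullSd = NA_real_, z = NA_real_,
                    p = NA_real_, significant = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  withSeed(seed, {
    for (s in seq_len(K)) {
      inS <- assignments == s
      if (sum(inS) < 2) {
        tab$reason[s] <- "fewer than 2 assigned samples"
        next
      }
      if (sum(!inS) < 1) {
        tab$reason[s] <- "no out-of-state samples"
        next
      }
      mk <- model@markers[[s]]
      genes <- intersect(mk$gene, allGenes)
      if (length(genes) < 3) {
        tab$reason[s] <- "fewer than 3 marker genes present in new cohort"
        next
      }
      ref <- mk$log2FC[match(genes, mk$gene)]
      if (sd(ref) == 0) {
        tab$reason[s] <- "degenerate discovery fold-change vector"
        next
      }
      obs <- suppressWarnings(cor(ref, groupLog2FC(X, genes, inS)))
      if (is.na(obs)) {
        tab$reason[s] <- "undefined recovery correlation"
        next
      }
      null <- vapply(seq_len(nPerm), function(b) {
        g <- allGenes[sample.int(length(allGenes), length(genes))]
        suppressWarnings(cor(ref, groupLog2FC(X, g, inS)))
      }, 1)
      null[is.na(null)] <- 0
      ns <- sd(null)
      if (ns == 0) {
        tab$reason[s] <- "zero-variance permutation null"
        next
      }
      tab$R[s] <- obs
      tab$nullMean[s] <- mean(null)
      tab$nullSd[s] <- ns
      tab$z[s] <- (obs - mean(null)) / ns
      tab$p[s] <- (sum(null >= obs) + 1) / (nPerm + 1)
      tab$significant[s] <- tab$z[s] > 1.65 && tab$p[s] < 0.05
    }
  })
  new("RecoveryResult", cellType = model@cellType, Hprime = Hprime,
      table = tab, assignments = assignments)
}

#' Recover and test discovery states in a new cohort
#'
#' Convenience wrapper: \code{\link{recoverAbundances}} followed by
#' \code{\link{recoverySignificance}}.
#'
#' @inheritParams recoverySignificance
#' @inheritParams recoverAbundances
#' @return a \linkS4class{RecoveryResult}.
#' @export
recoverStates <- function(newMatrix, model, nPerm = 1000, seed = 1L,
                          maxIter = 2000, tol = 1e-6, minCoverage = 0.5) {
  H <- recoverAbundances(newMatrix, model, maxIter = maxIter, tol = tol,
                         minCoverage = minCoverage)
  recoverySignificance(newMatrix, model, H, nPerm = nPerm, seed = seed)
}

#' Fraction of new-cohort samples assigned to a significant state
#'
#' @param recovery a \linkS4class{RecoveryResult}.
#' @return a fraction in [0, 1].
#' @export
recoveryRate <- function(recovery) {
  sig <- recovery@table$significant
  if (!length(recovery@assignments)) return(0)
  mean(sig[recovery@assignments])
}
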