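## Functional characterization of marker genes: hypergeometric over-
## representation against user-supplied gene-set collections (GMT), a
## Wilcoxon/fold-change rank score, and preranked GSEA with a weighted
## running-sum enrichment score and a gene-label permutation null.

#' Hypergeometric gene-set over-representation of marker genes
#'
#' Gene sets are intersected with the universe, filtered to the size range,
#' and tested one-sided (upper tail) for over-representation of the markers;
#' p-values are Benjamini-Hochberg adjusted across the tested sets.
#' Significance uses the dual rule p < 0.01 and adjusted p < 0.05. The
#' table is sorted by overlap count (descending) and the top 10 sets by
#' gene count are flagged.
#'
#' @param markers character vector of marker genes (subset of universe).
#' @param collection named list of gene-id vectors.
#' @param universe the gene universe.
#' @param setSizeRange inclusive (min, max) post-intersection set sizes.
#' @return data.frame: set, setSize, overlap, p, adjustedP, significant,
#'   topTen.
#' @export
hypergeometricEnrichment <- function(markers, collection, universe,
                                     setSizeRange = c(15, 500)) {
  if (!length(universe)) stop("empty universe")
  if (!length(markers)) stop("empty marker list")
  markers <- unique(markers)
  if (!all(markers %in% universe))
    stop("markers must be contained in the universe")
  sets <- lapply(collection, function(g) intersect(unique(g), universe))
  size <- vapply(sets, length, 1L)
  keep <- size >= setSizeRange[1] & size <= setSizeRange[2]
  sets <- sets[keep]
  if (!length(sets)) {
    return(data.frame(set = character(0), setSize = integer(0),
                      overlap = integer(0), p = numeric(0),
                      adjustedP = numeric(0), significant = logical(0),
                      topTen = logical(0)))
  }
  U <- length(universe)
  k <- length(markers)
  overlap <- vapply(sets, function(g) length(intersect(g, markers)), 1L)
  m <- vapply(sets, length, 1L)
  p <- phyper(overlap - 1, m, U - m, k, lower.tail = FALSE)
  tab <- data.frame(set = names(sets), setSize = m, overlap = overlap,
                    p = p, adjustedP = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  tab$significant <- tab$p < 0.01 & tab$adjustedP < 0.05
  tab <- tab[order(-tab$overlap, tab$p, tab$set), , drop = FALSE]
  tab$topTen <- seq_len(nrow(tab)) <= 10
  rownames(tab) <- NULL
  tab
}

#' Signed Wilcoxon rank score per gene
#'
#' For each gene, a two-group Wilcoxon rank-sum test (exact when sample
#' sizes permit and there are no ties, otherwise the normal approximation
#' with tie and continuity corrections) and a linear-scale fold change with
#' pseudocount 1; the score is \code{S = -log10(p) * sign(log(FC))}, so a
#' unit fold change gives S = 0. Genes constant across both groups get
#' p = 1 and S = 0 by convention. The table is sorted by S descending with
#' a deterministic gene-id tie break.
#'
#' @param expression linear-scale matrix (genes x samples), an
#'   \linkS4class{ExpressionMatrix} or \linkS4class{PurifiedExpression}.
#' @param inGroup,outGroup sample ids of the two groups (>= 2 each).
#' @return data.frame: gene, p, fc, S (sorted by S descending).
#' @export
rankScores <- function(expression, inGroup, outGroup) {
  X <- linearMatrix(expression)
  if (length(inGroup) < 2 || length(outGroup) < 2)
    stop("both groups need at least 2 samples")
  stopifnot(all(c(inGroup, outGroup) %in% colnames(X)))
  A <- X[, inGroup, drop = FALSE]
  B <- X[, outGroup, drop = FALSE]
  p <- vapply(seq_len(nrow(X)), function(g) {
    a <- A[g, ]
    b <- B[g, ]
    if (sd(c(a, b)) == 0) return(1)
    suppressWarnings(wilcox.test(a, b, correct = TRUE)$p.value)
  }, 1)
  fc <- (rowMeans(A) + 1) / (rowMeans(B) + 1)
  S <- -log10(p) * sign(log(fc))
  S[fc == 1] <- 0
  tab <- data.frame(gene = rownames(X), p = p, fc = unname(fc),
                    S = unname(S), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$S, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score: hit increments
# proportional to |S|^weight, uniform miss decrements; ES is the extremum.
runningSumES <- function(ranked, inSet, weight = 1) {
  hit <- ranked$gene %in% inSet
  if (!any(hit)) return(NA_real_)
  w <- abs(ranked$S)^weight
  wHit <- w * hit
  sHit <- sum(wHit)
  inc <- if (sHit > 0) wHit / sHit else hit / sum(hit)
  dec <- (!hit) / sum(!hit)
  rs <- cumsum(inc - dec)
  rs[which.max(abs(rs))]
}

#' Preranked gene-set enrichment analysis (GSEA)
#'
#' Weighted running-sum enrichment score over the ranked gene list (hit
#' increments proportional to |S|^weight, uniform miss decrements); the
#' null is built by relabeling the set as random gene draws of the same
#' size, NES is the ES divided by the mean |null ES| of matching sign, and
#' the empirical p counts same-sign null scores at least as extreme
#' (add-one correction). Sets are size-filtered after intersection with the
#' ranked list; sets with no gene in the list are skipped with a reason.
#'
#' @param ranked data.frame from \code{\link{rankScores}} (gene, S).
#' @param collection named list of gene-id vectors.
#' @param nPerm permutation count.
#' @param weight running-sum weight exponent (default 1).
#' @param seed integer seed.
#' @param setSizeRange inclusive set-size filter after intersection.
#' @return data.frame: set, setSize, ES, NES, p, reason.
#' @export
runGSEA <- function(ranked, collection, nPerm = 1000, weight = 1,
                    seed = 1L, setSizeRange = c(15, 500)) {
  stopifnot(all(c("gene", "S") %in% names(ranked)))
  genes <- ranked$gene
  rows <- withSeed(seed, lapply(names(collection), function(nm) {
    inSet <- intersect(unique(collection[[nm]]), genes)
    out <- data.frame(set = nm, setSize = length(inSet), ES = NA_real_,
                      NES = NA_real_, p = NA_real_, reason = "",
                      stringsAsFactors = FALSE)
    if (!length(inSet)) {
      out$reason <- "no set genes in the ranked list"
      return(out)
    }
    if (length(inSet) < setSizeRange[1] || length(inSet) > setSizeRange[2]) {
      out$reason <- sprintf("set size %d outside [%d, %d]", length(inSet),
                            setSizeRange[1], setSizeRange[2])
      return(out)
    }
    es <- runningSumES(ranked, inSet, weight)
    null <- vapply(seq_len(nPerm), function(b) {
      runningSumES(ranked, genes[sample.int(length(genes), length(inSet))],
                   weight)
    }, 1)
    same <- null[sign(null) == sign(es) & !is.na(null)]
    out$ES <- es
    out$NES <- if (length(same)) es / mean(abs(same)) else NA_real_
    out$p <- (sum(!is.na(null) & sign(null) == sign(es) &
                    abs(null) >= abs(es)) + 1) / (nPerm + 1)
    out
  }))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}
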