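## Reference-based deconvolution: cell-type fractions by per-sample
## non-negative least squares against a signature matrix, and "purified"
## cell-type-specific expression by per-gene constrained regression on the
## fractions with residual redistribution. Log2 inputs are linearized as
## 2^x - 1 (microarray convention) before any fitting.

#' Estimate per-sample cell-type fractions
#'
#' For each sample, solves a non-negative least squares of the (linearized)
#' bulk profile on the signature over the shared genes and renormalizes the
#' coefficients to sum 1. All-zero solutions are replaced by the uniform
#' composition with a warning.
#'
#' @param bulk an \linkS4class{ExpressionMatrix}.
#' @param signature a \linkS4class{SignatureMatrix}.
#' @param minSharedGenes minimum genes shared between bulk and signature.
#' @return a \linkS4class{CellFractions}.
#' @export
estimateFractions <- function(bulk, signature, minSharedGenes = 50) {
  stopifnot(is(bulk, "ExpressionMatrix"), is(signature, "SignatureMatrix"))
  shared <- intersect(geneIDs(bulk), geneIDs(signature))
  if (length(shared) < minSharedGenes)
    stop(sprintf("only %d genes shared between bulk and signature (need %d)",
                 length(shared), minSharedGenes))
  S <- exprs(signature)[shared, , drop = FALSE]
  if (qr(S)$rank < ncol(S))
    warning("signature matrix is rank-deficient over the shared genes; ",
            "fraction estimates may be poorly conditioned")
  B <- linearize(bulk)[shared, , drop = FALSE]
  nTypes <- ncol(S)
  fr <- matrix(0, ncol(B), nTypes,
               dimnames = list(colnames(B), colnames(S)))
  zero <- logical(ncol(B))
  for (j in seq_len(ncol(B))) {
    beta <- pracma::lsqnonneg(S, B[, j])$x
    tot <- sum(beta)
    if (tot <= 0) {
      zero[j] <- TRUE
      fr[j, ] <- 1 / nTypes
    } else {
      fr[j, ] <- beta / tot
    }
  }
  if (any(zero))
    warning(sprintf("%d sample(s) had an all-zero solution; set to uniform",
                    sum(zero)))
  new("CellFractions", values = fr)
}

# Per-gene NNLS of bulk on the fractions design: returns the fitted
# per-type levels x_gc (genes x types) and the residual matrix.
fitGeneLevels <- function(B, FR) {
  X <- matrix(0, nrow(B), ncol(FR),
              dimnames = list(rownames(B), colnames(FR)))
  for (g in seq_len(nrow(B)))
    X[g, ] <- pracma::lsqnonneg(FR, B[g, ])$x
  list(levels = X, residuals = B - X %*% t(FR))
}

#' Impute cell-type-specific ("purified") expression
#'
#' Per gene, the bulk profile is regressed on the cell-type fractions with
#' non-negativity constraints, giving one fitted level per cell type
#' (x_gc). The per-sample purified value for the target type is x_gc scaled
#' by the sample's standardized residual share — the ratio of the observed
#' bulk value to its fitted mixture value, with the log-share standardized
#' by the type's mean fraction (a deviation of one type's expression is
#' diluted in the bulk by that fraction), rescaled per gene so the purified
#' sample mean equals x_gc exactly. The cross-sample regression is what
#' separates the types: a gene whose variation tracks a type's fraction is
#' attributed to that type, so state-driven deviations land in the right
#' purified matrix in expectation.
#' Genes absent from the signature are still purified — the regression uses
#' only the fractions — so downstream state discovery sees the whole
#' transcriptome.
#'
#' @param bulk an \linkS4class{ExpressionMatrix}.
#' @param fractions a \linkS4class{CellFractions} aligned with the bulk
#'   samples.
#' @param cellType the target cell type.
#' @param minMeanFraction reliability threshold on the target type's mean
#'   fraction (see \code{\link{reliabilityMask}}).
#' @param minExpression reliability threshold on the fitted level.
#' @return a \linkS4class{PurifiedExpression}.
#' @export
purifyExpression <- function(bulk, fractions, cellType,
                             minMeanFraction = 0.005, minExpression = 1e-6) {
  stopifnot(is(bulk, "ExpressionMatrix"), is(fractions, "CellFractions"))
  FR <- exprs(fractions)
  if (!identical(rownames(FR), sampleIDs(bulk)))
    stop("fraction rows do not align with the bulk samples")
  if (!cellType %in% colnames(FR))
    stop(sprintf("unknown cell type '%s'", cellType))
  mf <- mean(FR[, cellType])
  if (mf < 0.005)
    stop(sprintf(
      "mean fraction of '%s' is %.4f (< 0.5%%): abundance too low to purify",
      cellType, mf))
  B <- linearize(bulk)
  if (ncol(FR) == 1L) {
    # single cell type: no mixing, the bulk is the purified matrix
    pur <- B
    lev <- rowMeans(B)
    score <- rep(NA_real_, nrow(B))
  } else {
    fit <- fitGeneLevels(B, FR)
    lev <- fit$levels[, cellType]
    fitted <- fit$levels %*% t(FR)
    # multiplicative residual share: how far each sample's bulk value sits
    # above or below its fitted mixture value; genes with a (near-)zero fit
    # get a flat share of 1. A deviation of the target type's expression is
    # diluted in the bulk by the type's fraction, so the log-share is
    # standardized by the type's mean fraction (exponent capped at 20) to
    # put purified deviations back on the cell-type scale.
    share <- ifelse(fitted > 1e-9, B / pmax(fitted, 1e-9), 1)
    undilute <- min(1 / mean(FR[, cellType]), 20)
    pur <- lev * share^undilute
    # standardize rows so the purified sample mean equals the fitted level
    rm0 <- rowMeans(pur)
    fixable <- rm0 > 0 & lev > 0
    pur[fixable, ] <- pur[fixable, , drop = FALSE] * (lev[fixable] / rm0[fixable])
    pur[lev == 0, ] <- 0
    # type specificity: a gene whose unexplained relative variation grows
    # with this type's abundance carries state signal of this type; the
    # contrast against the best competing type suppresses genes whose
    # variation belongs to another cell type's states
    rel <- abs(fit$residuals / pmax(fitted, 1e-9))
    typeCors <- suppressWarnings(
      vapply(colnames(FR), function(tc) {
        apply(rel, 1L, function(x) cor(x, FR[, tc], method = "spearman"))
      }, numeric(nrow(rel))))
    own <- typeCors[, cellType]
    other <- apply(typeCors[, setdiff(colnames(FR), cellType),
                            drop = FALSE], 1L, max)
    score <- own - other
  }
  obj <- new("PurifiedExpression", cellType = cellType, values = pur,
             fittedLevel = lev, typeScore = score,
             reliable = rep(TRUE, nrow(pur)))
  obj@reliable <- reliabilityMask(obj, fractions, minMeanFraction,
                                  minExpression)
  obj
}

#' Flag genes whose purified values are unreliable
#'
#' A gene is unreliable in the target cell type when its fitted level is
#' below \code{minExpression}, or when the target type's mean fraction is
#' below \code{minMeanFraction} (which flags every gene). Unreliable genes
#' are flagged, never silently dropped.
#'
#' @param purified a \linkS4class{PurifiedExpression}.
#' @param fractions a \linkS4class{CellFractions}.
#' @param minMeanFraction,minExpression non-negative thresholds.
#' @return a logical vector, TRUE = reliable.
#' @export
reliabilityMask <- function(purified, fractions, minMeanFraction = 0.005,
                            minExpression = 1e-6) {
  stopifnot(minMeanFraction >= 0, minExpression >= 0)
  mf <- mean(exprs(fractions)[, purified@cellType])
  ok <- purified@fittedLevel >= minExpression
  if (mf < minMeanFraction) ok[] <- FALSE
  ok
}
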