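#' @import methods
#' @importFrom stats cor cutree hclust as.dist cophenetic sd quantile rnorm
#'   runif rgamma rbinom rexp uniroot phyper pchisq p.adjust wilcox.test
#'   setNames aggregate complete.cases na.omit coef
#' @importFrom utils read.delim write.table head tail packageVersion
#' @useDynLib EcoStates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' ExpressionMatrix: genes x samples expression values with a declared scale
#'
#' The universal exchange object of the pipeline. Row names are gene ids,
#' column names are sample ids; \code{scale} declares whether values are on
#' the linear or log2 scale. Linear-scale matrices must be non-negative.
#'
#' @slot values numeric matrix, genes x samples, dimnames required.
#' @slot scale either \code{"linear"} or \code{"log2"}.
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", scale = "character"),
  prototype(scale = "linear")
)

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if ((nrow(v) > 0 && is.null(rownames(v))) ||
      (ncol(v) > 0 && is.null(colnames(v))))
    return("values must have gene row names and sample column names")
  if (anyDuplicated(rownames(v))) return("gene ids must be unique")
  if (anyDuplicated(colnames(v))) return("sample ids must be unique")
  if (anyNA(v)) return("missing values are not allowed")
  if (!object@scale %in% c("linear", "log2"))
    return("scale must be 'linear' or 'log2'")
  if (object@scale == "linear" && ncol(v) > 0 && nrow(v) > 0 && min(v) < 0)
    return("linear-scale values must be non-negative")
  TRUE
})

#' SignatureMatrix: reference expression profiles of purified cell types
#'
#' @slot values non-negative numeric matrix, genes x cell types.
#' @export
setClass("SignatureMatrix", representation(values = "matrix"))

setValidity("SignatureMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry gene and cell-type dimnames")
  if (ncol(v) < 2) return("a signature needs at least 2 cell types")
  if (anyDuplicated(colnames(v))) return("cell-type labels must be unique")
  if (anyNA(v) || min(v) < 0) return("signature values must be non-negative")
  if (any(rowSums(v) == 0)) return("all-zero gene rows are not allowed")
  TRUE
})

#' CellFractions: per-sample cell-type composition on the simplex
#'
#' @slot values numeric matrix, samples x cell types; rows sum to 1.
#' @export
setClass("CellFractions", representation(values = "matrix"))

setValidity("CellFractions", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry sample and cell-type dimnames")
  if (anyNA(v) || min(v) < 0) return("fractions must be non-negative")
  if (any(abs(rowSums(v) - 1) > 1e-8))
    return("fraction rows must sum to 1 (tolerance 1e-8)")
  TRUE
})

#' PurifiedExpression: imputed cell-type-specific expression
#'
#' Genes x samples matrix of expression attributed to one cell type, with
#' the per-gene fitted level (the cross-sample mean of the purified values)
#' and a reliability flag. Unreliable genes are flagged, never dropped.
#'
#' @slot cellType the cell type the matrix refers to.
#' @slot values non-negative genes x samples matrix (linear scale).
#' @slot fittedLevel per-gene fitted expression level in this cell type.
#' @slot typeScore per-gene type-specificity score: rank correlation of the
#'   gene's relative mixture residual with the cell type's fraction (NA
#'   when undefined); used to prioritize genes for state discovery.
#' @slot reliable per-gene logical reliability mask.
#' @export
setClass("PurifiedExpression",
  representation(cellType = "character", values = "matrix",
                 fittedLevel = "numeric", typeScore = "numeric",
                 reliable = "logical")
)

setValidity("PurifiedExpression", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry gene and sample dimnames")
  if (anyNA(v) || min(v) < 0) return("purified values must be non-negative")
  if (length(object@fittedLevel) != nrow(v) ||
      length(object@typeScore) != nrow(v) ||
      length(object@reliable) != nrow(v))
    return("fittedLevel, typeScore and reliable must have one entry per gene")
  TRUE
})

#' StateModel: NMF-defined transcriptional cell states of one cell type
#'
#' Holds the basis \code{W} (split features x states), the abundance matrix
#' \code{H} (states x samples), the cophenetic rank-selection trace, marker
#' genes per state, the feature-transform parameters needed to project new
#' cohorts, and a record of dropped states.
#'
#' @slot cellType cell type label.
#' @slot K number of retained states.
#' @slot W non-negative basis matrix (features x K).
#' @slot H non-negative abundance matrix (K x samples).
#' @slot copheneticByRank named numeric, cophenetic coefficient per rank.
#' @slot markers named list, one data.frame (gene, log2FC) per state.
#' @slot droppedStates named character, dropped state -> reason.
#' @slot featureGenes genes underlying the feature rows of W.
#' @slot featureCenter,featureScale per-gene standardization parameters.
#' @slot restarts number of NMF restarts used per rank.
#' @slot seed master seed of the discovery run.
#' @export
setClass("StateModel",
  representation(cellType = "character", K = "integer", W = "matrix",
                 H = "matrix", copheneticByRank = "numeric",
                 markers = "list", droppedStates = "character",
                 featureGenes = "character", featureCenter = "numeric",
                 featureScale = "numeric", restarts = "integer",
                 seed = "integer")
)

setValidity("StateModel", function(object) {
  if (ncol(object@W) != object@K || nrow(object@H) != object@K)
    return("K must equal the number of columns of W and rows of H")
  if (min(object@W) < 0 || min(object@H) < 0)
    return("W and H must be non-negative")
  if (is.null(colnames(object@H)))
    return("H columns must be indexed by sample ids")
  cp <- object@copheneticByRank
  if (length(cp) && (min(cp) < -1e-9 || max(cp) > 1 + 1e-9))
    return("cophenetic coefficients must lie in [0, 1]")
  TRUE
})

#' StateAssignment: discrete per-sample state labels for one cell type
#'
#' @slot cellType cell type label.
#' @slot state integer state index per sample (named by sample id).
#' @slot abundance the H value that won the argmax, per sample.
#' @export
setClass("StateAssignment",
  representation(cellType = "character", state = "integer",
                 abundance = "numeric")
)

setValidity("StateAssignment", function(object) {
  if (is.null(names(object@state))) return("states must be named by sample")
  if (length(object@state) != length(object@abundance))
    return("state and abundance must be parallel vectors")
  TRUE
})

#' RecoveryResult: reference-based state recovery in a new cohort
#'
#' @slot cellType cell type label.
#' @slot Hprime recovered abundance matrix (states x new samples),
#'   columns renormalized to sum 1.
#' @slot table per-state data.frame with columns state, R, nullMean,
#'   nullSd, z, p, significant, reason.
#' @slot assignments integer state per new sample (named).
#' @export
setClass("RecoveryResult",
  representation(cellType = "character", Hprime = "matrix",
                 table = "data.frame", assignments = "integer")
)

setValidity("RecoveryResult", function(object) {
  tb <- object@table
  need <- c("state", "R", "z", "p", "significant")
  if (!all(need %in% names(tb)))
    return("table must carry state, R, z, p, significant columns")
  ok <- stats::complete.cases(tb[, c("z", "p")])
  bad <- tb$significant[ok] != (tb$z[ok] > 1.65 & tb$p[ok] < 0.05)
  if (any(bad))
    return("significance must equal (z > 1.65 AND p < 0.05)")
  TRUE
})

#' BinaryAssignmentMatrix: states x samples 0/1 co-occurrence input
#'
#' Row names are "cellType|state"; for each (cell type, sample) with a
#' retained assignment exactly one of that type's rows carries a 1.
#'
#' @slot A binary matrix, states x samples.
#' @slot stateInfo data.frame with columns cellType and state, one row per
#'   row of A.
#' @export
setClass("BinaryAssignmentMatrix",
  representation(A = "matrix", stateInfo = "data.frame")
)

setValidity("BinaryAssignmentMatrix", function(object) {
  A <- object@A
  if (!all(A %in% c(0, 1))) return("entries must be 0/1")
  if (nrow(A) != nrow(object@stateInfo))
    return("stateInfo must have one row per state row")
  for (ct in unique(object@stateInfo$cellType)) {
    rows <- which(object@stateInfo$cellType == ct)
    cs <- colSums(A[rows, , drop = FALSE])
    if (any(cs > 1))
      return("at most one state per cell type may be assigned per sample")
  }
  TRUE
})

#' EcotypeModel: multicellular communities of co-occurring cell states
#'
#' @slot jaccard raw states x states Jaccard matrix.
#' @slot pairP hypergeometric co-occurrence p-value per state pair.
#' @slot gatedJaccard significance-gated Jaccard matrix used for clustering.
#' @slot ecotypeMap integer ecotype per state (NA = unassigned), named by
#'   state id.
#' @slot silhouetteByK mean silhouette width per candidate cluster count.
#' @slot chosenK selected number of ecotypes.
#' @slot abundance samples x ecotypes matrix, rows sum to 1.
#' @slot dominant dominant ecotype label per sample.
#' @export
setClass("EcotypeModel",
  representation(jaccard = "matrix", pairP = "matrix",
                 gatedJaccard = "matrix", ecotypeMap = "integer",
                 silhouetteByK = "numeric", chosenK = "integer",
                 abundance = "matrix", dominant = "character")
)

setValidity("EcotypeModel", function(object) {
  J <- object@jaccard
  if (nrow(J) != ncol(J) || max(abs(J - t(J))) > 1e-12)
    return("jaccard matrix must be symmetric")
  if (any(abs(diag(J) - 1) > 1e-12)) return("jaccard diagonal must be 1")
  ab <- object@abundance
  if (length(ab) && any(abs(rowSums(ab) - 1) > 1e-8))
    return("ecotype abundance rows must sum to 1")
  TRUE
})

#' SurvivalData: right-censored times with optional response labels
#'
#' @slot sampleIDs unique sample ids.
#' @slot time positive follow-up times (arbitrary units).
#' @slot event 0/1 event indicator (0 = censored).
#' @slot response optional per-sample labels, "responder" /
#'   "non_responder" (NA allowed), or NULL.
#' @export
setClass("SurvivalData",
  representation(sampleIDs = "character", time = "numeric",
                 event = "integer", response = "characterOrNULL")
)

setValidity("SurvivalData", function(object) {
  n <- length(object@sampleIDs)
  if (anyDuplicated(object@sampleIDs)) return("sample ids must be unique")
  if (length(object@time) != n || length(object@event) != n)
    return("time and event must be parallel to sampleIDs")
  if (any(object@time <= 0)) return("times must be positive")
  if (!all(object@event %in% c(0L, 1L))) return("event must be 0/1")
  r <- object@response
  if (!is.null(r)) {
    if (length(r) != n) return("response must be parallel to sampleIDs")
    if (!all(r %in% c("responder", "non_responder", NA)))
      return("response labels must be responder/non_responder")
  }
  TRUE
})

#' SyntheticTruth: planted ground truth of a simulated cohort
#'
#' Records everything the generator planted: the baseline per-type
#' expression profiles, marker genes and effect sizes per (cell type,
#' state), the community definitions and per-sample community labels, the
#' realized per-sample states (community states plus recorded noise
#' flips), cell-type fractions, community hazard multipliers, and the
#' states that carry a therapy benefit.
#'
#' @slot geneIDs gene universe of the cohort.
#' @slot cellTypes cell-type labels.
#' @slot statesPerType named integer, states per cell type.
#' @slot baseline genes x cell types baseline expression (linear scale).
#' @slot markerMap nested list: markerMap[[type]][[state]] is a data.frame
#'   with columns gene and effectLog2.
#' @slot communityDefs list: one named integer vector (type -> state) per
#'   community.
#' @slot sampleCommunity integer community per sample (named).
#' @slot sampleStates samples x cell types integer state matrix.
#' @slot fractions samples x cell types simplex matrix.
#' @slot hazardMultipliers positive scalar per community.
#' @slot responseBenefitStates data.frame with columns cellType and state.
#' @slot noiseRate the community noise rate used.
#' @slot seed generator seed.
#' @export
setClass("SyntheticTruth",
  representation(geneIDs = "character", cellTypes = "character",
                 statesPerType = "integer", baseline = "matrix",
                 markerMap = "list", communityDefs = "list",
                 sampleCommunity = "integer", sampleStates = "matrix",
                 fractions = "matrix", hazardMultipliers = "numeric",
                 responseBenefitStates = "data.frame",
                 noiseRate = "numeric", seed = "integer")
)

setValidity("SyntheticTruth", function(object) {
  fr <- object@fractions
  if (nrow(fr) && (min(fr) < 0 || any(abs(rowSums(fr) - 1) > 1e-9)))
    return("fraction rows must be non-negative and sum to 1 (1e-9)")
  for (cd in object@communityDefs) {
    if (length(cd) < 3 || length(unique(names(cd))) < 3)
      return("each community needs >= 3 states from >= 3 distinct types")
  }
  for (ct in object@cellTypes) {
    mm <- object@markerMap[[ct]]
    genes <- unlist(lapply(mm, function(d) d$gene))
    if (anyDuplicated(genes))
      return("marker sets must be disjoint across states within a type")
  }
  if (any(object@hazardMultipliers <= 0))
    return("hazard multipliers must be positive")
  TRUE
})
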