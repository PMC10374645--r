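#' Accessors for pipeline objects
#'
#' Small generic accessor family: \code{exprs} returns the numeric matrix
#' of an object, \code{geneIDs} and \code{sampleIDs} its row/column
#' identities, \code{exprScale} the declared scale of an
#' \linkS4class{ExpressionMatrix}, \code{cellTypes} the cell-type labels.
#'
#' @param object a pipeline object.
#' @return the requested component.
#' @name accessors
#' @aliases exprs geneIDs sampleIDs exprScale cellTypes
NULL

#' @rdname accessors
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))
#' @rdname accessors
#' @export
setGeneric("geneIDs", function(object) standardGeneric("geneIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("exprScale", function(object) standardGeneric("exprScale"))
#' @rdname accessors
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))

#' @rdname accessors
setMethod("exprs", "ExpressionMatrix", function(object) object@values)
#' @rdname accessors
setMethod("geneIDs", "ExpressionMatrix",
          function(object) rownames(object@values))
#' @rdname accessors
setMethod("sampleIDs", "ExpressionMatrix",
          function(object) colnames(object@values))
#' @rdname accessors
setMethod("exprScale", "ExpressionMatrix", function(object) object@scale)

#' @rdname accessors
setMethod("exprs", "SignatureMatrix", function(object) object@values)
#' @rdname accessors
setMethod("geneIDs", "SignatureMatrix",
          function(object) rownames(object@values))
#' @rdname accessors
setMethod("cellTypes", "SignatureMatrix",
          function(object) colnames(object@values))

#' @rdname accessors
setMethod("exprs", "CellFractions", function(object) object@values)
#' @rdname accessors
setMethod("sampleIDs", "CellFractions",
          function(object) rownames(object@values))
#' @rdname accessors
setMethod("cellTypes", "CellFractions",
          function(object) colnames(object@values))

#' @rdname accessors
setMethod("exprs", "PurifiedExpression", function(object) object@values)
#' @rdname accessors
setMethod("geneIDs", "PurifiedExpression",
          function(object) rownames(object@values))
#' @rdname accessors
setMethod("sampleIDs", "PurifiedExpression",
          function(object) colnames(object@values))
#' @rdname accessors
setMethod("cellTypes", "PurifiedExpression",
          function(object) object@cellType)

#' @rdname accessors
setMethod("cellTypes", "SyntheticTruth", function(object) object@cellTypes)
#' @rdname accessors
setMethod("geneIDs", "SyntheticTruth", function(object) object@geneIDs)
#' @rdname accessors
setMethod("sampleIDs", "SyntheticTruth",
          function(object) rownames(object@sampleStates))

#' StateModel component accessors
#'
#' @param object a \linkS4class{StateModel}.
#' @return \code{basisMatrix}: the features x states basis W;
#'   \code{abundanceMatrix}: the states x samples abundance H;
#'   \code{stateMarkers}: the per-state marker list;
#'   \code{copheneticTrace}: the rank -> cophenetic coefficient map;
#'   \code{nStates}: the number of retained states.
#' @name statemodel-accessors
NULL

#' @rdname statemodel-accessors
#' @export
setGeneric("basisMatrix", function(object) standardGeneric("basisMatrix"))
#' @rdname statemodel-accessors
#' @export
setGeneric("abundanceMatrix",
           function(object) standardGeneric("abundanceMatrix"))
#' @rdname statemodel-accessors
#' @export
setGeneric("stateMarkers", function(object) standardGeneric("stateMarkers"))
#' @rdname statemodel-accessors
#' @export
setGeneric("copheneticTrace",
           function(object) standardGeneric("copheneticTrace"))
#' @rdname statemodel-accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @rdname statemodel-accessors
setMethod("basisMatrix", "StateModel", function(object) object@W)
#' @rdname statemodel-accessors
setMethod("abundanceMatrix", "StateModel", function(object) object@H)
#' @rdname statemodel-accessors
setMethod("abundanceMatrix", "RecoveryResult",
          function(object) object@Hprime)
#' @rdname statemodel-accessors
setMethod("stateMarkers", "StateModel", function(object) object@markers)
#' @rdname statemodel-accessors
setMethod("copheneticTrace", "StateModel",
          function(object) object@copheneticByRank)
#' @rdname statemodel-accessors
setMethod("nStates", "StateModel", function(object) object@K)
#' @rdname statemodel-accessors
setMethod("cellTypes", "StateModel", function(object) object@cellType)
#' @rdname statemodel-accessors
setMethod("sampleIDs", "StateModel", function(object) colnames(object@H))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(object@values), ncol(object@values), object@scale))
})

setMethod("show", "SignatureMatrix", function(object) {
  cat(sprintf("SignatureMatrix: %d genes x %d cell types\n",
              nrow(object@values), ncol(object@values)))
  cat(" cell types:", paste(colnames(object@values), collapse = ", "), "\n")
})

setMethod("show", "CellFractions", function(object) {
  cat(sprintf("CellFractions: %d samples x %d cell types (simplex rows)\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "PurifiedExpression", function(object) {
  cat(sprintf(
    "PurifiedExpression [%s]: %d genes x %d samples, %d reliable genes\n",
    object@cellType, nrow(object@values), ncol(object@values),
    sum(object@reliable)))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel [%s]: %d states, %d samples\n",
              object@cellType, object@K, ncol(object@H)))
  if (length(object@copheneticByRank)) {
    cat(" cophenetic trace:",
        paste(sprintf("%s:%.3f", names(object@copheneticByRank),
                      object@copheneticByRank), collapse = " "), "\n")
  }
  nm <- vapply(object@markers, nrow, 1L)
  if (length(nm)) cat(" markers per state:", paste(nm, collapse = ", "), "\n")
  if (length(object@droppedStates))
    cat(" dropped states:", length(object@droppedStates), "\n")
})

setMethod("show", "RecoveryResult", function(object) {
  cat(sprintf("RecoveryResult [%s]: %d states, %d samples, %d significant\n",
              object@cellType, nrow(object@Hprime), ncol(object@Hprime),
              sum(object@table$significant, na.rm = TRUE)))
})

setMethod("show", "BinaryAssignmentMatrix", function(object) {
  cat(sprintf("BinaryAssignmentMatrix: %d states x %d samples\n",
              nrow(object@A), ncol(object@A)))
})

setMethod("show", "EcotypeModel", function(object) {
  k <- object@chosenK
  tab <- table(object@ecotypeMap, useNA = "no")
  cat(sprintf("EcotypeModel: %d ecotypes over %d states (%d assigned)\n",
              length(unique(stats::na.omit(object@ecotypeMap))),
              length(object@ecotypeMap),
              sum(!is.na(object@ecotypeMap))))
  cat(sprintf(" chosen k = %d; states per ecotype: %s\n", k,
              paste(tab, collapse = ", ")))
})

setMethod("show", "SurvivalData", function(object) {
  cat(sprintf("SurvivalData: %d samples, %d events (%.0f%% censored)%s\n",
              length(object@sampleIDs), sum(object@event),
              100 * mean(object@event == 0L),
              if (is.null(object@response)) "" else ", with response labels"))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d genes, %d cell types, %d samples, %d communities\n",
    length(object@geneIDs), length(object@cellTypes),
    nrow(object@sampleStates), length(object@communityDefs)))
  cat(" states per type:",
      paste(sprintf("%s:%d", names(object@statesPerType),
                    object@statesPerType), collapse = " "), "\n")
})
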