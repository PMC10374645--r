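#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @param scale "linear" or "log2".
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  new("ExpressionMatrix", values = as.matrix(values), scale = scale)
}

#' Construct a SignatureMatrix
#'
#' @param values non-negative matrix, genes x cell types, with dimnames.
#' @return a \linkS4class{SignatureMatrix}.
#' @export
SignatureMatrix <- function(values) {
  new("SignatureMatrix", values = as.matrix(values))
}

#' Construct a SurvivalData object
#'
#' @param sampleIDs unique sample ids.
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @param response optional "responder"/"non_responder" labels.
#' @return a \linkS4class{SurvivalData}.
#' @export
SurvivalData <- function(sampleIDs, time, event, response = NULL) {
  new("SurvivalData", sampleIDs = as.character(sampleIDs),
      time = as.numeric(time), event = as.integer(event),
      response = response)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: keeps derived seeds in 32-bit range.
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

# Convert a declared-scale matrix to the linear scale (2^x - 1, floored at 0).
linearize <- function(em) {
  stopifnot(is(em, "ExpressionMatrix"))
  if (em@scale == "linear") return(em@values)
  pmax(2^em@values - 1, 0)
}

# argmax with lowest-index tie break, per column of a matrix.
argmaxByColumn <- function(m) {
  apply(m, 2L, function(col) which(col == max(col))[1L])
}

# Adjusted Rand index between two label vectors (used for recovery checks).
#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}
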