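## Readers and writers for the pipeline's plain-text formats: expression
## TSV (first column gene id, header of sample ids), GMT gene sets, clinical
## TSV (sample_id, time, event, optional response) and JSON serializations.

#' Read an expression matrix from TSV
#'
#' First column gene ids, header row sample ids. Duplicate gene ids are
#' collapsed (maximum by default — robust to multiple probes per gene — or
#' mean); duplicate sample ids are rejected. Scale is auto-detected (max
#' value < 30 means log2) unless hinted.
#'
#' @param path TSV file path.
#' @param scaleHint NULL (auto), "linear" or "log2".
#' @param collapse "max" or "mean" for duplicate gene rows.
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
readExpressionTSV <- function(path, scaleHint = NULL,
                              collapse = c("max", "mean")) {
  collapse <- match.arg(collapse)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed expression file")
  genes <- as.character(df[[1]])
  # data.frame subsetting uniquifies names; check the original header
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample ids in header")
  vals <- df[, -1, drop = FALSE]
  colnames(vals) <- colnames(df)[-1]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric value at row %d, column '%s'", bad,
                   colnames(vals)[j]))
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    fun <- if (collapse == "max") max else mean
    groups <- split(seq_along(genes), genes)[unique(genes)]
    m <- do.call(rbind, lapply(groups, function(i) {
      apply(m[i, , drop = FALSE], 2L, fun)
    }))
  }
  scale <- if (!is.null(scaleHint)) match.arg(scaleHint, c("linear", "log2"))
           else if (max(m) < 30) "log2" else "linear"
  if (scale == "linear" && min(m) < 0)
    stop("negative values in a linear-scale matrix")
  ExpressionMatrix(m, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' @param em an \linkS4class{ExpressionMatrix}.
#' @param path output path.
#' @export
writeExpressionTSV <- function(em, path) {
  df <- data.frame(gene = geneIDs(em), exprs(em), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard dialect: per line, set name, description (ignored), then gene
#' ids; genes are deduplicated preserving order.
#'
#' @param path GMT file path.
#' @return named list of gene-id vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d fields (need >= 3)", i, length(f)))
    nm <- f[1]
    if (nm %in% names(sets))
      stop(sprintf("duplicate set name '%s' at line %d", nm, i))
    sets[[nm]] <- unique(f[-(1:2)])
  }
  sets
}

#' Read a clinical table from TSV
#'
#' Requires columns sample_id, time, event; an optional response column is
#' mapped from R/NR or 1/0. Rows with non-positive time or non-binary event
#' are rejected with their row index.
#'
#' @param path TSV file path.
#' @return a \linkS4class{SurvivalData}.
#' @export
readClinicalTSV <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("clinical table must have columns sample_id, time, event")
  time <- suppressWarnings(as.numeric(df$time))
  event <- suppressWarnings(as.numeric(df$event))
  bad <- which(is.na(time) | time <= 0)
  if (length(bad))
    stop(sprintf("non-positive or non-numeric time at row %d", bad[1]))
  bad <- which(is.na(event) | !event %in% c(0, 1))
  if (length(bad))
    stop(sprintf("non-binary event at row %d", bad[1]))
  response <- NULL
  if ("response" %in% names(df)) {
    map <- c(R = "responder", NR = "non_responder",
             `1` = "responder", `0` = "non_responder",
             responder = "responder", non_responder = "non_responder")
    response <- unname(map[as.character(df$response)])
    bad <- which(!is.na(df$response) & df$response != "" & is.na(response))
    if (length(bad))
      stop(sprintf("unrecognized response label at row %d", bad[1]))
  }
  SurvivalData(df$sample_id, time, as.integer(event), response)
}

#' Write a clinical table as TSV
#'
#' @param surv a \linkS4class{SurvivalData}.
#' @param path output path.
#' @export
writeClinicalTSV <- function(surv, path) {
  df <- data.frame(sample_id = surv@sampleIDs, time = surv@time,
                   event = surv@event, stringsAsFactors = FALSE)
  if (!is.null(surv@response)) df$response <- surv@response
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a planted truth object as JSON
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output path.
#' @export
writeTruthJSON <- function(truth, path) {
  obj <- list(
    geneIDs = truth@geneIDs, cellTypes = truth@cellTypes,
    statesPerType = as.list(truth@statesPerType),
    markerMap = truth@markerMap,
    communityDefs = lapply(truth@communityDefs, as.list),
    sampleCommunity = as.list(truth@sampleCommunity),
    sampleStates = apply(truth@sampleStates, 1L, as.list),
    hazardMultipliers = truth@hazardMultipliers,
    responseBenefitStates = truth@responseBenefitStates,
    noiseRate = truth@noiseRate, seed = truth@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a state model to disk
#'
#' JSON metadata (markers, cophenetic trace, transform parameters, dropped
#' states) plus TSV matrices for W and H.
#'
#' @param model a \linkS4class{StateModel}.
#' @param dir output directory.
#' @param prefix file-name prefix (defaults to the cell type).
#' @return the paths written, invisibly.
#' @export
writeStateModel <- function(model, dir, prefix = model@cellType) {
  meta <- list(cellType = model@cellType, K = model@K,
               copheneticByRank = as.list(model@copheneticByRank),
               markers = model@markers,
               droppedStates = as.list(model@droppedStates),
               featureGenes = model@featureGenes,
               featureCenter = as.list(model@featureCenter),
               featureScale = as.list(model@featureScale),
               restarts = model@restarts, seed = model@seed)
  pj <- file.path(dir, paste0(prefix, "_state_model.json"))
  jsonlite::write_json(meta, pj, auto_unbox = TRUE, digits = NA)
  pw <- file.path(dir, paste0(prefix, "_W.tsv"))
  ph <- file.path(dir, paste0(prefix, "_H.tsv"))
  write.table(data.frame(feature = rownames(model@W), model@W,
                         check.names = FALSE), pw,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(state = rownames(model@H), model@H,
                         check.names = FALSE), ph,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pj, pw, ph))
}
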