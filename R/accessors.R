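#' Declared scale of the expression values
#'
#' @param x a \linkS4class{KitExperiment}.
#' @return \code{"counts"}, \code{"log2"} or \code{"normalized-log2"}.
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname exprScale
setMethod("exprScale", "KitExperiment", function(x) metadata(x)$scale)

#' Study design table of a KitExperiment
#'
#' @param x a \linkS4class{KitExperiment}.
#' @return data.frame with columns \code{sample_id}, \code{cancer_id},
#'   \code{condition} (factor, reference first) and \code{replicate}, one row
#'   per sample, in assay column order.
#' @export
setGeneric("studyDesign", function(x) standardGeneric("studyDesign"))

#' @rdname studyDesign
setMethod("studyDesign", "KitExperiment", function(x) {
  cd <- colData(x)
  data.frame(sample_id = rownames(cd), cancer_id = cd$cancer_id,
             condition = cd$condition, replicate = cd$replicate,
             stringsAsFactors = FALSE)
})

#' Reference condition and kit labels
#'
#' The reference condition (fresh-frozen arm) is the first level of the
#' condition factor; the kits are the remaining levels.
#'
#' @param x a \linkS4class{KitExperiment}.
#' @return a single label (\code{refCondition}) or a character vector of
#'   non-reference condition labels (\code{kitConditions}).
#' @export
setGeneric("refCondition", function(x) standardGeneric("refCondition"))

#' @rdname refCondition
setMethod("refCondition", "KitExperiment",
          function(x) levels(colData(x)$condition)[1])

#' @rdname refCondition
#' @export
setGeneric("kitConditions", function(x) standardGeneric("kitConditions"))

#' @rdname refCondition
setMethod("kitConditions", "KitExperiment",
          function(x) levels(colData(x)$condition)[-1])

#' Ground truth of a simulated study
#'
#' For objects produced by \code{\link{simulateStudy}}, the per-gene
#' generative parameters (baseline mean, per-kit bias, per-kit slope sd,
#' reference-gene flag) plus the global noise parameters; \code{NULL} for
#' real data.
#'
#' @param x a \linkS4class{KitExperiment}.
#' @return a list with elements \code{genes} (data.frame), \code{sigma_cancer},
#'   \code{replicate_sd}, \code{cell_sd}, \code{seed}, or \code{NULL}.
#' @export
setGeneric("syntheticTruth", function(x) standardGeneric("syntheticTruth"))

#' @rdname syntheticTruth
setMethod("syntheticTruth", "KitExperiment", function(x) metadata(x)$truth)

# internal: cell (cancer x condition) id per sample
.cellId <- function(design)
  paste(design$cancer_id, as.character(design$condition), sep = "_")
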