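#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays colData rowData
NULL

.EXPR_SCALES <- c("counts", "log2", "normalized-log2")

#' Container for a replicated FF/FFPE expression study
#'
#' A \code{KitExperiment} is a \linkS4class{SummarizedExperiment} holding one
#' expression assay (genes x samples) together with the study design that the
#' reliability analysis needs: for every sample the tumor (cancer) it came
#' from, the preservation/extraction condition (fresh-frozen reference or an
#' FFPE RNA extraction kit), and the technical replicate index. The condition
#' column is a factor whose first level is the reference condition; all
#' downstream contrasts (kit bias, concordance, differential analysis) are
#' taken against it.
#'
#' The assay carries a declared scale, one of \code{"counts"}, \code{"log2"}
#' or \code{"normalized-log2"} (log2 after subtraction of the per-sample mean
#' of a reference-gene panel). Operations that change the scale
#' (\code{\link{logNormalize}}) retag it; operations with scale preconditions
#' (\code{\link{filterExpressed}}, \code{\link{stratifyByExpression}}) check
#' the tag.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}; the design
#'   lives in \code{colData} (columns \code{cancer_id}, \code{condition},
#'   \code{replicate}) and the scale tag in \code{metadata(x)$scale}.
#'
#' @seealso \code{\link{KitExperiment}} (constructor),
#'   \code{\link{exprScale}}, \code{\link{studyDesign}},
#'   \code{\link{simulateStudy}}
#' @exportClass KitExperiment
setClass("KitExperiment", contains = "SummarizedExperiment")

setValidity("KitExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("cancer_id", "condition", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  if (!is.factor(cd$condition))
    msg <- c(msg, "condition must be a factor (first level = reference)")
  key <- paste(cd$cancer_id, cd$condition, cd$replicate)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicated (cancer, condition, replicate) combination")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% .EXPR_SCALES)
    msg <- c(msg, sprintf("metadata scale tag must be one of %s",
                          paste(.EXPR_SCALES, collapse = ", ")))
  if (length(assays(object)) < 1L)
    msg <- c(msg, "one expression assay required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct a KitExperiment
#'
#' @param exprs numeric matrix, genes x samples, with row and column names.
#' @param design data.frame with columns \code{sample_id}, \code{cancer_id},
#'   \code{condition}, \code{replicate}; one row per column of \code{exprs}.
#' @param scale declared scale of the values: \code{"counts"}, \code{"log2"}
#'   or \code{"normalized-log2"}.
#' @param reference reference condition label (default \code{"FF"}); made the
#'   first factor level of \code{condition}.
#' @return a \linkS4class{KitExperiment}.
#'
#' An unbalanced design (some cancer missing from some condition) is
#' permitted with a warning; downstream concordance drops missing pairs
#' pairwise.
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample_id = paste0("s", 1:4),
#'                 cancer_id = rep(c("C1", "C2"), each = 2),
#'                 condition = rep(c("FF", "N"), 2), replicate = 1L)
#' ke <- KitExperiment(m, d, scale = "log2")
#' exprScale(ke)
#' @export
KitExperiment <- function(exprs, design, scale = c("counts", "log2",
                                                   "normalized-log2"),
                          reference = "FF") {
  scale <- match.arg(scale)
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("expression matrix needs gene (row) and sample (column) names")
  if (any(!is.finite(exprs)))
    stop("expression matrix contains missing or non-finite values")
  design <- as.data.frame(design)
  need <- c("sample_id", "cancer_id", "condition", "replicate")
  miss <- setdiff(need, colnames(design))
  if (length(miss))
    stop("design lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  if (!setequal(design$sample_id, colnames(exprs)))
    stop("design sample_id set does not match expression column names")
  design <- design[match(colnames(exprs), design$sample_id), , drop = FALSE]
  conds <- unique(as.character(design$condition))
  if (!reference %in% conds)
    stop("reference condition '", reference, "' absent from design")
  design$condition <- factor(design$condition,
                             levels = c(reference, setdiff(conds, reference)))
  design$replicate <- as.integer(design$replicate)
  cd <- DataFrame(cancer_id = as.character(design$cancer_id),
                  condition = design$condition,
                  replicate = design$replicate,
                  row.names = design$sample_id)
  se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
  metadata(se)$scale <- scale
  ke <- new("KitExperiment", se)
  tab <- table(cd$cancer_id, cd$condition)
  if (any(tab == 0L))
    warning("unbalanced design: ", sum(tab == 0L),
            " (cancer, condition) cell(s) have no sample")
  validObject(ke)
  ke
}

#' A two-gene-set expression signature
#'
#' Gene signatures of the EndoPredict / Recurrence Score / SET ER/PR family
#' score a sample as the (optionally weighted) mean log2 expression of a set
#' of informative genes minus the mean of a set of reference (normalizer)
#' genes, making the score invariant to per-sample shifts in overall
#' expression.
#'
#' @slot name signature name.
#' @slot informative character, informative gene ids (non-empty).
#' @slot reference character, reference/normalizer gene ids (may be empty).
#' @slot weights named numeric, optional per-gene weights; genes without an
#'   entry get weight 1.
#' @seealso \code{\link{geneSignature}}, \code{\link{scoreSignature}},
#'   \code{\link{bundledSignature}}
#' @exportClass GeneSignature
setClass("GeneSignature",
         representation(name = "character", informative = "character",
                        reference = "character", weights = "numeric"))

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@informative) == 0L)
    msg <- c(msg, "informative gene set must be non-empty")
  if (length(intersect(object@informative, object@reference)))
    msg <- c(msg, paste("gene(s) in both roles:",
                        paste(intersect(object@informative, object@reference),
                              collapse = ", ")))
  if (anyDuplicated(object@informative) || anyDuplicated(object@reference))
    msg <- c(msg, "duplicated gene ids within a role")
  if (length(object@weights) && is.null(names(object@weights)))
    msg <- c(msg, "weights must be named by gene id")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' @param name signature name.
#' @param informative character vector of informative gene ids.
#' @param reference character vector of reference gene ids.
#' @param weights optional named numeric vector of per-gene weights.
#' @return a \linkS4class{GeneSignature}.
#' @examples
#' geneSignature("toy", c("g1", "g2"), c("g3"))
#' @export
geneSignature <- function(name, informative, reference = character(),
                          weights = NULL) {
  new("GeneSignature", name = as.character(name),
      informative = as.character(informative),
      reference = as.character(reference),
      weights = if (is.null(weights)) numeric() else weights)
}

setMethod("show", "KitExperiment", function(object) {
  cd <- colData(object)
  cat("KitExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  scale:", metadata(object)$scale, "\n")
  cat("  cancers:", length(unique(cd$cancer_id)),
      " conditions:", paste(levels(cd$condition), collapse = ", "),
      "(reference:", levels(cd$condition)[1], ")\n")
  reps <- table(cd$condition)
  cat("  samples per condition:",
      paste(names(reps), reps, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature '", object@name, "': ", length(object@informative),
      " informative + ", length(object@reference), " reference genes",
      if (length(object@weights)) " (weighted)" else "", "\n", sep = "")
})
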