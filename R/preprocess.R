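#' Remove genes not expressed in every sample
#'
#' Keeps exactly the genes whose count is at least \code{minCount} in every
#' sample of every condition group (the global intersection of the
#' per-condition "expressed everywhere" gene sets). Applied to raw counts
#' before log transformation; gene order is preserved.
#'
#' @param ke a \linkS4class{KitExperiment} on the \code{"counts"} scale.
#' @param minCount minimum count to call a gene expressed in a sample
#'   (default 1, i.e. "not expressed" means a zero count).
#' @return the filtered \linkS4class{KitExperiment}.
#' @examples
#' m <- matrix(c(5, 0, 2, 4, 1, 3), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' d <- data.frame(sample_id = c("s1", "s2"), cancer_id = "C1",
#'                 condition = c("FF", "N"), replicate = 1L)
#' filterExpressed(KitExperiment(m, d, scale = "counts"))
#' @export
filterExpressed <- function(ke, minCount = 1) {
  stopifnot(is(ke, "KitExperiment"))
  if (exprScale(ke) != "counts")
    stop("filterExpressed requires the counts scale, got ", exprScale(ke))
  x <- assay(ke)
  keep <- rowSums(x < minCount) == 0L
  if (!any(keep)) {
    cond <- colData(ke)$condition
    per <- vapply(levels(cond), function(k) {
      sum(rowSums(x[, cond == k, drop = FALSE] < minCount) == 0L)
    }, integer(1))
    stop("no gene expressed in every sample; per-condition expressed-",
         "everywhere counts: ",
         paste(names(per), per, sep = "=", collapse = ", "))
  }
  ke[keep, ]
}

#' Log2 transform and reference-panel normalization
#'
#' Counts are transformed to \code{log2(x + pseudo)} (log2 input passes
#' through unchanged); then, per sample, the arithmetic mean (or median) of
#' that sample's reference-gene log2 values is subtracted from every gene,
#' reference genes included. The result is invariant to any per-sample shift
#' of the log2 values, which is what makes a housekeeping panel a
#' normalizer.
#'
#' @param ke a \linkS4class{KitExperiment} on the \code{"counts"} or
#'   \code{"log2"} scale.
#' @param referenceGenes character vector of panel gene ids, all present in
#'   the matrix.
#' @param pseudo offset added to counts before log2 (default 1; irrelevant
#'   for genes that survived the zero filter but kept for robustness).
#' @param center \code{"mean"} (default) or \code{"median"} summary of the
#'   panel.
#' @return a \linkS4class{KitExperiment} tagged \code{"normalized-log2"}.
#' @examples
#' m <- matrix(c(8, 2, 2), 3, 1, dimnames = list(c("g", "r1", "r2"), "s1"))
#' d <- data.frame(sample_id = "s1", cancer_id = "C1", condition = "FF",
#'                 replicate = 1L)
#' ke <- KitExperiment(m, d, scale = "counts")
#' assay(logNormalize(ke, c("r1", "r2"), pseudo = 0))  # g -> 3 - 1 = 2
#' @export
logNormalize <- function(ke, referenceGenes, pseudo = 1,
                         center = c("mean", "median")) {
  stopifnot(is(ke, "KitExperiment"))
  center <- match.arg(center)
  if (exprScale(ke) == "normalized-log2")
    stop("matrix is already reference-normalized")
  missing <- setdiff(referenceGenes, rownames(ke))
  if (length(missing))
    stop("reference gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  if (length(referenceGenes) == 0L)
    stop("empty reference panel")
  x <- assay(ke)
  if (exprScale(ke) == "counts") x <- log2(x + pseudo)
  ref <- x[referenceGenes, , drop = FALSE]
  ctr <- if (center == "mean") colMeans(ref)
         else apply(ref, 2, stats::median)
  x <- sweep(x, 2, ctr, "-")
  out <- ke
  assay(out, withDimnames = FALSE) <- x
  metadata(out)$scale <- "normalized-log2"
  metadata(out)$reference_genes <- referenceGenes
  out
}

#' Average technical replicates
#'
#' Collapses the matrix to one column per (cancer, condition) cell by
#' arithmetic mean over replicates. Column names are
#' \code{<cancer>_<condition>}; columns are ordered by cancer then by
#' condition level. Single-replicate cells pass through.
#'
#' @param ke a \linkS4class{KitExperiment} on a log2 or normalized-log2
#'   scale.
#' @return a \linkS4class{KitExperiment} with \code{replicate = 1} for every
#'   (averaged) column.
#' @export
averageReplicates <- function(ke) {
  stopifnot(is(ke, "KitExperiment"))
  if (exprScale(ke) == "counts")
    stop("average replicates on the log2 scale, not raw counts")
  d <- studyDesign(ke)
  cell <- .cellId(d)
  x <- assay(ke)
  rs <- rowsum(t(x), group = cell)              # rows sorted by cell id
  avg <- t(rs / as.vector(table(cell)[rownames(rs)]))
  # deterministic order: cancer, then condition level
  cells <- unique(data.frame(cell = cell, cancer_id = d$cancer_id,
                             condition = d$condition,
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$cancer_id, as.integer(cells$condition)), ]
  avg <- avg[, cells$cell, drop = FALSE]
  design <- data.frame(sample_id = cells$cell, cancer_id = cells$cancer_id,
                       condition = as.character(cells$condition),
                       replicate = 1L, stringsAsFactors = FALSE)
  out <- KitExperiment(avg, design, scale = exprScale(ke),
                       reference = refCondition(ke))
  metadata(out)$reference_genes <- metadata(ke)$reference_genes
  metadata(out)$truth <- metadata(ke)$truth
  out
}

#' Stratify genes into high and low expression
#'
#' A gene is "high" iff its summary (default mean) normalized expression
#' across all samples is strictly greater than the threshold; a gene exactly
#' at the threshold is "low".
#'
#' @param ke a \linkS4class{KitExperiment} tagged \code{"normalized-log2"}.
#' @param threshold normalized log2 cutoff (default -7.5, roughly the
#'   detection limit of one count under a high-expressed reference panel).
#' @param summary \code{"mean"} (default) or \code{"median"} across samples.
#' @return named character vector, \code{"high"} or \code{"low"} per gene.
#' @export
stratifyByExpression <- function(ke, threshold = -7.5,
                                 summary = c("mean", "median")) {
  stopifnot(is(ke, "KitExperiment"))
  summary <- match.arg(summary)
  if (exprScale(ke) != "normalized-log2")
    stop("stratifyByExpression requires reference-normalized log2 values")
  m <- if (summary == "mean") rowMeans(assay(ke))
       else apply(assay(ke), 1, stats::median)
  stats::setNames(ifelse(m > threshold, "high", "low"), rownames(ke))
}
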