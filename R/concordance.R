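#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' using population (1/n) moments, per Lin's original estimator. The
#' coefficient factors as \code{ccc = pearson_r * bias_term}: the Pearson
#' correlation measures scatter about the best-fit line, the accuracy (bias)
#' term in (0, 1] measures how far that line is from the identity.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @return list with \code{ccc}, \code{pearson_r}, \code{bias_term},
#'   \code{n}, and \code{defined} (FALSE, with NA statistics, when either
#'   vector has zero variance — never silently 0).
#' @examples
#' linCCC(c(1, 2, 3), c(2, 3, 4))  # ccc = 4/7, r = 1
#' @export
linCCC <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0)
    return(list(ccc = NA_real_, pearson_r = NA_real_, bias_term = NA_real_,
                n = n, defined = FALSE))
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  list(ccc = ccc, pearson_r = r,
       bias_term = if (r == 0) NA_real_ else ccc / r,
       n = n, defined = TRUE)
}

#' Per-gene FF-vs-kit concordance table
#'
#' For every gene, pairs the replicate-averaged reference-arm value with the
#' kit value across cancers and evaluates \code{\link{linCCC}}. Cancers
#' missing from either arm are dropped pairwise; the number dropped is
#' attached as attribute \code{"dropped_cancers"}.
#'
#' @param avgKe a replicate-averaged \linkS4class{KitExperiment} (one column
#'   per (cancer, condition) cell; see \code{\link{averageReplicates}}).
#' @param kit a non-reference condition label.
#' @return data.frame with one row per gene: \code{gene_id}, \code{ccc},
#'   \code{pearson_r}, \code{bias_term}, \code{mean_ff}, \code{mean_kit},
#'   \code{n_pairs}, \code{defined}.
#' @export
concordanceTable <- function(avgKe, kit) {
  stopifnot(is(avgKe, "KitExperiment"))
  d <- studyDesign(avgKe)
  ref <- refCondition(avgKe)
  if (!kit %in% kitConditions(avgKe))
    stop("'", kit, "' is not a non-reference condition of this experiment")
  if (any(table(.cellId(d)) > 1L) || any(d$replicate != 1L))
    stop("concordanceTable expects a replicate-averaged matrix; ",
         "run averageReplicates() first")
  dff <- d[d$condition == ref, ]
  dkit <- d[d$condition == kit, ]
  shared <- intersect(dff$cancer_id, dkit$cancer_id)
  dropped <- length(union(dff$cancer_id, dkit$cancer_id)) - length(shared)
  if (length(shared) < 3L)
    stop("fewer than 3 cancers shared between ", ref, " and ", kit)
  xs <- assay(avgKe)[, dff$sample_id[match(shared, dff$cancer_id)],
                     drop = FALSE]
  ys <- assay(avgKe)[, dkit$sample_id[match(shared, dkit$cancer_id)],
                     drop = FALSE]
  n <- length(shared)
  mx <- rowMeans(xs); my <- rowMeans(ys)
  sx2 <- rowMeans((xs - mx)^2); sy2 <- rowMeans((ys - my)^2)
  sxy <- rowMeans((xs - mx) * (ys - my))
  defined <- sx2 > 0 & sy2 > 0
  ccc <- r <- cb <- rep(NA_real_, nrow(avgKe))
  ccc[defined] <- 2 * sxy[defined] /
    (sx2[defined] + sy2[defined] + (mx[defined] - my[defined])^2)
  r[defined] <- sxy[defined] / sqrt(sx2[defined] * sy2[defined])
  cb[defined & r != 0] <- ccc[defined & r != 0] / r[defined & r != 0]
  out <- data.frame(gene_id = rownames(avgKe), ccc = ccc, pearson_r = r,
                    bias_term = cb, mean_ff = mx, mean_kit = my,
                    n_pairs = n, defined = defined,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped_cancers") <- dropped
  attr(out, "kit") <- kit
  out
}

#' Between-replicate expression differences
#'
#' For each gene and condition with at least two replicates, the median over
#' cancers of the absolute replicate difference (mean absolute pairwise
#' difference when more than two replicates), and, across genes, the median
#' and raw median absolute deviation of that statistic per condition.
#'
#' @param ke a \linkS4class{KitExperiment} with replicate columns (log2 or
#'   normalized-log2 scale).
#' @return list with \code{perGene} (genes x conditions matrix; NA for
#'   single-replicate conditions) and \code{summary} (data.frame: condition,
#'   median, mad, n_genes, available).
#' @export
replicateDifference <- function(ke) {
  stopifnot(is(ke, "KitExperiment"))
  if (exprScale(ke) == "counts")
    stop("replicate differences are defined on the log2 scale")
  d <- studyDesign(ke)
  x <- assay(ke)
  conds <- levels(d$condition)
  per <- matrix(NA_real_, nrow(x), length(conds),
                dimnames = list(rownames(x), conds))
  for (k in conds) {
    dk <- d[d$condition == k, ]
    reps <- split(dk$sample_id, dk$cancer_id)
    reps <- reps[lengths(reps) >= 2L]
    if (!length(reps)) next
    absdiff <- vapply(reps, function(ids) {
      xx <- x[, ids, drop = FALSE]
      cmb <- utils::combn(length(ids), 2)
      rowMeans(abs(xx[, cmb[1, ], drop = FALSE] -
                   xx[, cmb[2, ], drop = FALSE]))
    }, numeric(nrow(x)))
    if (is.null(dim(absdiff))) absdiff <- matrix(absdiff, nrow = nrow(x))
    per[, k] <- apply(absdiff, 1, stats::median)
  }
  avail <- colSums(!is.na(per)) > 0
  summ <- data.frame(condition = conds,
                     median = apply(per, 2, stats::median, na.rm = TRUE),
                     mad = apply(per, 2, stats::mad, constant = 1,
                                 na.rm = TRUE),
                     n_genes = colSums(!is.na(per)),
                     available = avail, row.names = NULL,
                     stringsAsFactors = FALSE)
  summ$median[!avail] <- NA_real_
  summ$mad[!avail] <- NA_real_
  list(perGene = per, summary = summ)
}

#' Overlap of high-expression, high-concordance genes across kits
#'
#' Per kit, selects the genes with mean expression above
#' \code{exprThreshold} (mean of the two arm means) and CCC above
#' \code{cccThreshold}; reports the per-kit sets and the percentage of the
#' union of all sets that is shared by every kit.
#'
#' @param tables named list of per-kit data.frames from
#'   \code{\link{concordanceTable}} (same gene universe).
#' @param exprThreshold normalized log2 expression cutoff (default -7.5).
#' @param cccThreshold CCC cutoff (default 0.5).
#' @return list with \code{sets} (per-kit character vectors),
#'   \code{percentShared} (100 * |intersection| / |union|; NA with a message
#'   when the union is empty), \code{nUnion}, \code{nIntersection}.
#' @export
highConcordantOverlap <- function(tables, exprThreshold = -7.5,
                                  cccThreshold = 0.5) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  universe <- tables[[1]]$gene_id
  for (tb in tables) {
    if (!setequal(tb$gene_id, universe))
      stop("concordance tables must share one gene universe")
  }
  sets <- lapply(tables, function(tb) {
    sel <- tb$defined & !is.na(tb$ccc) &
      (tb$mean_ff + tb$mean_kit) / 2 > exprThreshold &
      tb$ccc > cccThreshold
    tb$gene_id[sel]
  })
  uni <- Reduce(union, sets)
  inter <- Reduce(intersect, sets)
  pct <- if (length(uni) == 0L) NA_real_ else 100 * length(inter) / length(uni)
  list(sets = sets, percentShared = pct, nUnion = length(uni),
       nIntersection = length(inter))
}

#' Summarize concordance by gene group
#'
#' Median and raw median absolute deviation of CCC per group label (for
#' example per chromosome or per signature role). Genes absent from the
#' mapping, and undefined CCC values, are excluded and counted.
#'
#' @param table data.frame from \code{\link{concordanceTable}}.
#' @param groups named character vector mapping gene id to a group label.
#' @return data.frame (group, median_ccc, mad_ccc, n) with attributes
#'   \code{"n_ungrouped"} and \code{"n_unknown_ids"} (mapping entries absent
#'   from the table).
#' @export
summarizeByGroup <- function(table, groups) {
  stopifnot(is.character(groups), !is.null(names(groups)))
  known <- names(groups) %in% table$gene_id
  g <- groups[known]
  lab <- g[match(table$gene_id, names(g))]
  usable <- !is.na(lab) & table$defined & !is.na(table$ccc)
  if (!any(usable)) stop("groups cover no gene with a defined CCC")
  sp <- split(table$ccc[usable], lab[usable])
  out <- data.frame(group = names(sp),
                    median_ccc = vapply(sp, stats::median, numeric(1)),
                    mad_ccc = vapply(sp, function(v)
                      stats::mad(v, constant = 1), numeric(1)),
                    n = lengths(sp), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_ungrouped") <- sum(is.na(lab))
  attr(out, "n_unknown_ids") <- sum(!known)
  out
}

#' Bland-Altman agreement of two paired score vectors
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return list with \code{bias} (mean of \code{y - x}), \code{loa_lower}
#'   and \code{loa_upper} (bias -/+ 1.96 sample sd of the differences).
#' @examples
#' blandAltman(c(1, 2, 3), c(2, 3, 4))  # bias 1, zero-width limits
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s)
}
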