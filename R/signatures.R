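#' Score a two-gene-set signature
#'
#' Per sample, the (optionally weighted) mean log2 expression of the
#' informative genes minus that of the reference genes. Because both terms
#' are means over log2 values, the score is invariant to adding a constant
#' to every gene of a sample.
#'
#' @param ke a \linkS4class{KitExperiment} on a log2 or normalized-log2
#'   scale.
#' @param sig a \linkS4class{GeneSignature}.
#' @param missing \code{"error"} (default: stop listing absent gene ids) or
#'   \code{"drop"} (warn and score with the genes present; an empty
#'   informative set after dropping is still an error).
#' @return named numeric vector of per-sample scores.
#' @examples
#' m <- matrix(c(3, 5, 2, 2), 4, 1,
#'             dimnames = list(c("a", "b", "r1", "r2"), "s1"))
#' d <- data.frame(sample_id = "s1", cancer_id = "C1", condition = "FF",
#'                 replicate = 1L)
#' ke <- KitExperiment(m, d, scale = "log2")
#' scoreSignature(ke, geneSignature("toy", c("a", "b"), c("r1", "r2")))  # 2
#' @export
scoreSignature <- function(ke, sig, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  stopifnot(is(ke, "KitExperiment"), is(sig, "GeneSignature"))
  if (exprScale(ke) == "counts")
    stop("score signatures on the log2 scale")
  absent <- setdiff(c(sig@informative, sig@reference), rownames(ke))
  if (length(absent)) {
    if (missing == "error")
      stop("signature gene(s) absent from matrix: ",
           paste(absent, collapse = ", "))
    warning(length(absent), " signature gene(s) dropped: ",
            paste(absent, collapse = ", "))
  }
  inf <- intersect(sig@informative, rownames(ke))
  ref <- intersect(sig@reference, rownames(ke))
  if (!length(inf)) stop("no informative gene left to score")
  wmean <- function(ids) {
    w <- rep(1, length(ids))
    if (length(sig@weights)) {
      hit <- ids %in% names(sig@weights)
      w[hit] <- sig@weights[ids[hit]]
    }
    colSums(assay(ke)[ids, , drop = FALSE] * w) / sum(w)
  }
  s <- wmean(inf)
  if (length(ref)) s <- s - wmean(ref)
  s
}

#' Concordance of signature scores between arms
#'
#' Averages replicate scores per (cancer, condition) cell, then evaluates
#' Lin's CCC between the reference arm and each kit across cancers.
#'
#' @param scores named per-sample scores (names = sample ids), e.g. from
#'   \code{\link{scoreSignature}} on the replicate-level matrix.
#' @param design design data.frame with \code{sample_id}, \code{cancer_id},
#'   \code{condition} (factor, reference first), or a
#'   \linkS4class{KitExperiment}.
#' @return data.frame: \code{kit}, \code{ccc}, \code{pearson_r},
#'   \code{bias_term}, \code{n}, \code{defined}.
#' @export
signatureConcordance <- function(scores, design) {
  if (is(design, "KitExperiment")) design <- studyDesign(design)
  if (is.null(names(scores)) || !all(design$sample_id %in% names(scores)))
    stop("scores must be named by sample id and cover the design")
  scores <- scores[design$sample_id]
  cell <- .cellId(design)
  cm <- tapply(scores, cell, mean)
  cells <- unique(data.frame(cell = cell, cancer_id = design$cancer_id,
                             condition = as.character(design$condition),
                             stringsAsFactors = FALSE))
  ref <- levels(design$condition)[1]
  kits <- levels(design$condition)[-1]
  do.call(rbind, lapply(kits, function(k) {
    cf <- cells[cells$condition == ref, ]
    ck <- cells[cells$condition == k, ]
    shared <- intersect(cf$cancer_id, ck$cancer_id)
    x <- cm[cf$cell[match(shared, cf$cancer_id)]]
    y <- cm[ck$cell[match(shared, ck$cancer_id)]]
    cc <- linCCC(as.numeric(x), as.numeric(y))
    data.frame(kit = k, ccc = cc$ccc, pearson_r = cc$pearson_r,
               bias_term = cc$bias_term, n = cc$n, defined = cc$defined,
               stringsAsFactors = FALSE)
  }))
}

#' Expression-matched random-signature null
#'
#' Compares an observed signature's FF-vs-kit concordance against B random
#' signatures assembled to match it: genes are binned into \code{nBins}
#' quantile bins of mean expression, and each random signature draws, for
#' every informative gene, a random gene from that gene's bin (matching both
#' the gene count and the expression range), without replacement within a
#' draw. Each random signature is scored against the true reference panel,
#' replicates are averaged, and the FF-vs-kit CCC recorded. The observed
#' CCC's percentile is 100 times the fraction of null draws strictly below
#' it.
#'
#' @param ke replicate-level \linkS4class{KitExperiment} (log2 or
#'   normalized-log2).
#' @param sig a \linkS4class{GeneSignature} whose genes are all present.
#' @param kit non-reference condition against which concordance is taken.
#' @param B number of random signatures (default 10000).
#' @param nBins number of expression quantile bins (default 10).
#' @param seed integer seed; draws are deterministic given it.
#' @return object of class \code{"RandomSignatureNull"}: list with
#'   \code{observed}, \code{draws} (length B), \code{percentile}, \code{B},
#'   \code{kit}, \code{n_bins}, \code{seed}.
#' @export
randomSignatureNull <- function(ke, sig, kit, B = 10000, nBins = 10,
                                seed = 1) {
  stopifnot(is(ke, "KitExperiment"), is(sig, "GeneSignature"), B >= 1)
  if (exprScale(ke) == "counts") stop("log2 scale required")
  d <- studyDesign(ke)
  if (!kit %in% kitConditions(ke)) stop("unknown kit: ", kit)
  genes <- rownames(ke)
  if (length(genes) <= length(sig@informative))
    stop("gene universe no larger than the signature")
  absent <- setdiff(c(sig@informative, sig@reference), genes)
  if (length(absent))
    stop("signature gene(s) absent: ", paste(absent, collapse = ", "))

  x <- assay(ke)
  m <- rowMeans(x)
  qs <- stats::quantile(m, probs = seq(0, 1, length.out = nBins + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  bin <- cut(m, breaks = unique(qs), labels = FALSE)
  names(bin) <- genes
  byBin <- split(genes, bin)
  need <- table(bin[sig@informative])
  short <- names(need)[need > lengths(byBin)[names(need)]]
  if (length(short))
    stop("expression bin(s) ", paste(short, collapse = ", "),
         " hold fewer genes than the signature needs from them; ",
         "use fewer bins")

  cell <- .cellId(d)
  ref <- refCondition(ke)
  cells <- unique(data.frame(cell = cell, cancer_id = d$cancer_id,
                             condition = as.character(d$condition),
                             stringsAsFactors = FALSE))
  cf <- cells[cells$condition == ref, ]
  ck <- cells[cells$condition == kit, ]
  shared <- intersect(cf$cancer_id, ck$cancer_id)
  ffCells <- cf$cell[match(shared, cf$cancer_id)]
  kitCells <- ck$cell[match(shared, ck$cancer_id)]

  cellCCC <- function(score) {
    cm <- tapply(score, cell, mean)
    linCCC(as.numeric(cm[ffCells]), as.numeric(cm[kitCells]))$ccc
  }
  refScore <- if (length(sig@reference))
    colMeans(x[sig@reference, , drop = FALSE]) else 0
  observed <- cellCCC(scoreSignature(ke, sig))

  sigBins <- bin[sig@informative]
  draws <- .withSeed(seed, {
    vapply(seq_len(B), function(b) {
      pick <- unlist(lapply(split(names(sigBins), sigBins), function(ids) {
        sample(byBin[[as.character(bin[ids[1]])]], length(ids),
               replace = FALSE)
      }), use.names = FALSE)
      sc <- colMeans(x[pick, , drop = FALSE]) - refScore
      cellCCC(sc)
    }, numeric(1))
  })
  out <- list(observed = observed, draws = draws,
              percentile = 100 * mean(draws < observed, na.rm = FALSE),
              B = as.integer(B), kit = kit, n_bins = as.integer(nBins),
              seed = as.integer(seed))
  class(out) <- "RandomSignatureNull"
  out
}

#' @export
print.RandomSignatureNull <- function(x, ...) {
  cat("RandomSignatureNull: observed CCC =", sprintf("%.4f", x$observed),
      "vs", x$B, "expression-matched random signatures (kit", x$kit, ")\n")
  cat("  percentile:", sprintf("%.1f", x$percentile),
      " (null median", sprintf("%.4f", stats::median(x$draws)), ")\n")
  invisible(x)
}

#' Replicate reproducibility of signature scores, as a percentage
#'
#' Per cancer and condition with at least two replicates, 100 times the
#' absolute replicate score difference (mean pairwise difference beyond
#' duplicates) divided by the range of replicate-averaged scores across all
#' samples — so the percentage is invariant to rescaling all scores.
#'
#' @param scores named per-sample scores.
#' @param design design data.frame or \linkS4class{KitExperiment}.
#' @return list with \code{perCancer} (data.frame: cancer_id, condition,
#'   percent_diff) and \code{summary} (per-condition median), plus
#'   \code{score_range}. A zero score range is flagged with an error.
#' @export
replicatePercentDifference <- function(scores, design) {
  if (is(design, "KitExperiment")) design <- studyDesign(design)
  scores <- scores[design$sample_id]
  cell <- .cellId(design)
  rng <- diff(range(tapply(scores, cell, mean)))
  if (rng == 0)
    stop("replicate-averaged scores have zero range; ",
         "percent difference undefined")
  sp <- split(seq_len(nrow(design)), cell)
  per <- do.call(rbind, lapply(sp, function(ii) {
    if (length(ii) < 2L) return(NULL)
    s <- scores[ii]
    cmb <- utils::combn(length(ii), 2)
    data.frame(cancer_id = design$cancer_id[ii[1]],
               condition = as.character(design$condition[ii[1]]),
               percent_diff = 100 * mean(abs(s[cmb[1, ]] - s[cmb[2, ]])) /
                 rng,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  summ <- stats::aggregate(percent_diff ~ condition, data = per,
                           FUN = stats::median)
  colnames(summ)[2] <- "median_percent_diff"
  list(perCancer = per, summary = summ, score_range = rng)
}

#' Bundled breast-cancer signature definitions
#'
#' Gene lists of three published breast-cancer expression signatures,
#' shipped as two-column TSV files under \code{extdata}: EndoPredict
#' (8 informative + 3 reference genes), the 21-gene Recurrence Score
#' (16 informative + 5 normalizers) and the SET ER/PR index (18 informative
#' + 10 reference genes). Scores here are unweighted two-set means; the
#' commercial coefficient sets are proprietary and not reproduced, but
#' per-gene weights can be supplied via \code{\link{geneSignature}}.
#'
#' @param name one of \code{"endopredict"}, \code{"recurrence_score"},
#'   \code{"set_erpr"}.
#' @return a \linkS4class{GeneSignature}.
#' @examples
#' bundledSignature("set_erpr")
#' @export
bundledSignature <- function(name = c("endopredict", "recurrence_score",
                                      "set_erpr")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "ffpeReliability", mustWork = TRUE)
  readSignature(path, name = name)
}

#' Reference-gene panel used for normalization
#'
#' The 10-gene housekeeping panel of the SET ER/PR index, used by
#' \code{\link{logNormalize}} as the default normalizer panel.
#'
#' @return character vector of 10 gene symbols.
#' @export
referencePanel <- function() bundledSignature("set_erpr")@reference
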