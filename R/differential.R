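#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around \code{stats::p.adjust(method = "BH")}:
#' sorted p-values \eqn{p_{(i)}} become \eqn{\min_{j \ge i} m p_{(j)} / j},
#' capped at 1, returned in input order. NA p-values propagate.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties. The two-sided p-value is
#' exact (full enumeration of labelings, via the null distribution of U)
#' when n + m <= 12 and there are no ties, otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with \code{U} (number of (x, y) pairs with x > y, counting
#'   ties as 1/2) and \code{p} (two-sided).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n + m) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(U), p = unname(wt$p.value))
}

#' Paired two-factor differential analysis
#'
#' Per gene, ordinary least squares on \code{value = Cancer + Kit} over the
#' replicate-averaged cells (the tumor enters as a blocking factor, so each
#' kit coefficient is the within-tumor log2 fold change against the
#' reference arm). Each contrast gets a two-sided t-test on its coefficient
#' with the model's residual degrees of freedom — no empirical-Bayes
#' moderation — and Benjamini-Hochberg adjustment across genes, per
#' contrast. The gene-wise least-squares machinery is \code{limma::lmFit};
#' kit-vs-kit contrasts reuse the one joint fit via
#' \code{limma::contrasts.fit}.
#'
#' Degenerate fits are flagged, never fabricated: with zero residual
#' degrees of freedom p is NA (\code{flag = "no_residual_df"}); with zero
#' residual variance and a non-zero effect p is 0
#' (\code{flag = "boundary"}).
#'
#' @param avgKe a replicate-averaged \linkS4class{KitExperiment}
#'   (normalized log2 scale).
#' @param contrasts \code{"vs_reference"} (default: each kit against the
#'   reference) or \code{"all"} (also every kit-vs-kit pair).
#' @param alpha FDR significance cutoff (default 0.05).
#' @return data.frame with one row per gene per contrast: \code{gene_id},
#'   \code{contrast}, \code{lfc}, \code{t}, \code{df}, \code{p}, \code{fdr},
#'   \code{significant}, \code{flag}.
#' @export
pairedLinearFit <- function(avgKe, contrasts = c("vs_reference", "all"),
                            alpha = 0.05) {
  contrasts <- match.arg(contrasts)
  stopifnot(is(avgKe, "KitExperiment"))
  d <- studyDesign(avgKe)
  if (any(table(.cellId(d)) > 1L))
    stop("average technical replicates first (averageReplicates)")
  if (length(unique(d$cancer_id)) < 2L) stop("need at least 2 cancers")
  ref <- refCondition(avgKe)
  kits <- kitConditions(avgKe)
  if (!length(kits)) stop("no non-reference condition to contrast")
  cancer <- factor(d$cancer_id)
  cond <- droplevels(d$condition)
  X <- stats::model.matrix(~ cancer + cond)
  colnames(X) <- sub("^cond", "", colnames(X))
  fit <- limma::lmFit(assay(avgKe), X)

  cmat <- diag(ncol(X))[, match(kits, colnames(X)), drop = FALSE]
  dimnames(cmat) <- list(colnames(X), paste0(kits, "_vs_", ref))
  if (contrasts == "all" && length(kits) > 1L) {
    prs <- utils::combn(kits, 2)
    extra <- apply(prs, 2, function(pr) {
      v <- numeric(ncol(X)); names(v) <- colnames(X)
      v[pr[2]] <- 1; v[pr[1]] <- -1   # later kit vs earlier kit
      v
    })
    colnames(extra) <- apply(prs, 2, function(pr)
      paste0(pr[2], "_vs_", pr[1]))
    cmat <- cbind(cmat, extra)
  }
  cf <- limma::contrasts.fit(fit, cmat)
  df <- fit$df.residual
  genes <- rownames(assay(avgKe))
  out <- do.call(rbind, lapply(colnames(cmat), function(cn) {
    lfc <- cf$coefficients[, cn]
    se <- cf$stdev.unscaled[, cn] * cf$sigma
    tstat <- lfc / se
    p <- 2 * stats::pt(-abs(tstat), df = df)
    flag <- rep("", length(lfc))
    if (any(df == 0)) {
      p[df == 0] <- NA_real_
      flag[df == 0] <- "no_residual_df"
    }
    # an exact (interpolation-degree) fit: effect either numerically zero
    # or sitting on the p = 0 boundary; flagged, never fabricated
    zero_sigma <- df > 0 & cf$sigma < 1e-12
    near0 <- abs(lfc) < 1e-10 * (1 + max(abs(cf$coefficients)))
    p[zero_sigma & !near0] <- 0
    flag[zero_sigma & !near0] <- "boundary"
    p[zero_sigma & near0] <- NA_real_
    flag[zero_sigma & near0] <- "no_residual_variance"
    data.frame(gene_id = genes, contrast = cn,
               lfc = unname(lfc), t = unname(tstat), df = unname(df),
               p = unname(p), fdr = bhAdjust(unname(p)),
               flag = flag, row.names = NULL, stringsAsFactors = FALSE)
  }))
  out$significant <- !is.na(out$fdr) & out$fdr < alpha
  out
}

#' Count differentially expressed genes at fold-change thresholds
#'
#' Per contrast and |log2 fold change| threshold, the number of genes with
#' FDR below \code{alpha} and |lfc| strictly above the threshold, split into
#' up- and down-regulated.
#'
#' @param results data.frame from \code{\link{pairedLinearFit}}.
#' @param lfcThresholds numeric thresholds (default 0, 0.5, 1, 2).
#' @param alpha FDR cutoff (default 0.05).
#' @return data.frame: \code{contrast}, \code{lfc_threshold}, \code{n},
#'   \code{n_up}, \code{n_down}.
#' @export
countDegs <- function(results, lfcThresholds = c(0, 0.5, 1, 2),
                      alpha = 0.05) {
  stopifnot(all(c("contrast", "lfc", "fdr") %in% colnames(results)))
  do.call(rbind, lapply(split(results, results$contrast), function(rr) {
    sig <- !is.na(rr$fdr) & rr$fdr < alpha
    do.call(rbind, lapply(lfcThresholds, function(t0) {
      up <- sum(sig & rr$lfc > t0)
      dn <- sum(sig & rr$lfc < -t0)
      data.frame(contrast = rr$contrast[1], lfc_threshold = t0,
                 n = up + dn, n_up = up, n_down = dn,
                 stringsAsFactors = FALSE)
    }))
  })) -> out
  rownames(out) <- NULL
  out
}

#' Kit effects on RNA-quality indices
#'
#' For each quality index (RIN, DV200, median TIN), averages the replicate
#' measurements per (cancer, condition) cell and fits the paired two-factor
#' model \code{index = Cancer + Kit}; each kit coefficient is the systematic
#' quality shift of that kit against the reference arm, tested with an
#' ordinary t-test and BH-adjusted across the comparisons of that index.
#'
#' @param quality data.frame with columns \code{sample_id},
#'   \code{cancer_id}, \code{condition}, \code{replicate} and the index
#'   columns (any of RIN, DV200, medTIN); see
#'   \code{\link{simulateQuality}}.
#' @param reference reference condition label (default "FF").
#' @param indices index columns to analyze (default those present).
#' @return data.frame: \code{index}, \code{kit}, \code{effect}, \code{t},
#'   \code{df}, \code{p}, \code{fdr}, \code{flag} ("constant_index" when an
#'   index has no residual variance).
#' @export
qualityIndexEffects <- function(quality, reference = "FF",
                                indices = intersect(c("RIN", "DV200",
                                                      "medTIN"),
                                                    colnames(quality))) {
  need <- c("cancer_id", "condition")
  if (!all(need %in% colnames(quality)))
    stop("quality table lacks design columns")
  if (!length(indices)) stop("no quality index column found")
  conds <- unique(as.character(quality$condition))
  if (!reference %in% conds) stop("reference condition absent")
  cond <- factor(quality$condition,
                 levels = c(reference, setdiff(conds, reference)))
  kits <- levels(cond)[-1]
  out <- do.call(rbind, lapply(indices, function(m) {
    cellmean <- stats::aggregate(quality[[m]],
                                 list(cancer_id = quality$cancer_id,
                                      condition = cond), mean)
    fit <- stats::lm(x ~ factor(cancer_id) + condition, data = cellmean)
    # exact fits (e.g. zero-spread indices) are handled explicitly below
    sm <- suppressWarnings(summary(fit))
    cc <- sm$coefficients
    rows <- paste0("condition", kits)
    eff <- stats::coef(fit)[rows]
    df <- fit$df.residual
    sigma0 <- sm$sigma < 1e-10 * (1 + max(abs(cellmean$x)))
    if (sigma0 || df == 0) {
      p <- rep(NA_real_, length(kits))
      tstat <- rep(NA_real_, length(kits))
      flag <- rep(if (df == 0) "no_residual_df" else "constant_index",
                  length(kits))
      # exact effects still reported (e.g. a constant shift design)
      if (sigma0 && df > 0) p[] <- ifelse(eff != 0, 0, NA_real_)
    } else {
      tstat <- cc[rows, "t value"]
      p <- cc[rows, "Pr(>|t|)"]
      flag <- rep("", length(kits))
    }
    data.frame(index = m, kit = kits, effect = unname(eff),
               t = unname(tstat), df = df, p = unname(p),
               fdr = bhAdjust(unname(p)), flag = flag,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
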