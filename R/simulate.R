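#' Configuration of the synthetic replicated FF/FFPE study
#'
#' Describes the generative model used by \code{\link{simulateStudy}}: for
#' gene g, cancer c, condition k and replicate t, log2 expression is
#' \deqn{Y_{gckt} = \mu_g + a_{gc} + \beta_{gk} + b_{gck} + u_{gck} + \epsilon_{gckt}}
#' with cancer effect \eqn{a_{gc} \sim N(0, \sigma_a^2)}, fixed kit bias
#' \eqn{\beta_{gk}} (0 for the reference condition), cancer-specific bias
#' deviation \eqn{b_{gck} \sim N(0, \tau_{gk}^2)} (0 for the reference), an
#' optional shared cell effect \eqn{u_{gck} \sim N(0, \sigma_u^2)} and
#' replicate noise \eqn{\epsilon \sim N(0, \sigma_{e,k}^2)}. Reference-panel
#' genes are generated with \eqn{\beta = 0} and \eqn{\tau = 0} and a high
#' baseline so that the panel mean mimics a housekeeping normalizer.
#'
#' Defaults emulate the study design the analysis targets: 12 tumors, a
#' fresh-frozen reference plus three FFPE extraction kits (N, Q, R), two
#' replicate extractions per kit, 18,695 genes normalized against a 10-gene
#' reference panel, with kit bias / bias variability / replicate noise chosen
#' per kit to match the reported medians of the decomposition (see the
#' methods vignette).
#'
#' @slot nCancers number of tumors.
#' @slot conditions condition labels, reference first.
#' @slot replicates named integer, replicates per condition (all >= 1).
#' @slot nGenes,nReferenceGenes gene counts (reference < total).
#' @slot muRange,refMuRange log2 range of baseline means for regular and
#'   reference-panel genes (drawn uniformly).
#' @slot sigmaCancer between-tumor sd (log2).
#' @slot kitBiasMean,kitBiasSd per-kit mean and per-gene sd of the fixed
#'   bias beta_gk (log2).
#' @slot slopeSd named per-kit sd tau of the across-tumor bias deviation.
#' @slot replicateSd named per-condition replicate noise sd sigma_e.
#' @slot cellSd optional shared cell-effect sd sigma_u (default 0; weakly
#'   identified with duplicate extractions).
#' @slot countModel,dispersion if TRUE, draw negative-binomial counts with
#'   mean 2^Y and the given dispersion instead of returning log2 values.
#' @slot seed integer seed controlling all randomness.
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateStudy}}
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nCancers = "integer", conditions = "character",
                        replicates = "integer", nGenes = "integer",
                        nReferenceGenes = "integer", muRange = "numeric",
                        refMuRange = "numeric", sigmaCancer = "numeric",
                        kitBiasMean = "numeric", kitBiasSd = "numeric",
                        slopeSd = "numeric", replicateSd = "numeric",
                        cellSd = "numeric", countModel = "logical",
                        dispersion = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  k <- object@conditions
  kits <- k[-1]
  if (length(k) < 1L || anyDuplicated(k))
    msg <- c(msg, "conditions must be unique, reference first")
  if (!identical(sort(names(object@replicates)), sort(k)))
    msg <- c(msg, "replicates must be named by every condition")
  if (any(object@replicates < 1L))
    msg <- c(msg, "invalid design: every condition needs >= 1 replicate")
  if (length(kits)) {
    if (!identical(sort(names(object@kitBiasMean)), sort(kits)) ||
        !identical(sort(names(object@slopeSd)), sort(kits)))
      msg <- c(msg, "kitBiasMean and slopeSd must be named by each kit")
  }
  if (!identical(sort(names(object@replicateSd)), sort(k)))
    msg <- c(msg, "replicateSd must be named by every condition")
  sds <- c(object@sigmaCancer, object@kitBiasSd, object@slopeSd,
           object@replicateSd, object@cellSd)
  if (any(sds < 0)) msg <- c(msg, "all sds must be >= 0")
  if (object@nReferenceGenes >= object@nGenes)
    msg <- c(msg, "nReferenceGenes must be < nGenes")
  if (object@nReferenceGenes < 0L || object@nGenes < 1L)
    msg <- c(msg, "gene counts must be positive")
  if (diff(object@muRange) < 0 || diff(object@refMuRange) < 0)
    msg <- c(msg, "mu ranges must be non-decreasing")
  if (object@countModel && object@dispersion <= 0)
    msg <- c(msg, "dispersion must be > 0 when countModel is on")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' All arguments have study-design defaults (see
#' \linkS4class{SimulationConfig}); per-kit arguments accept a single number,
#' which is recycled across kits/conditions.
#'
#' @param nCancers,conditions,replicates,nGenes,nReferenceGenes design shape.
#' @param muRange,refMuRange baseline log2 ranges.
#' @param sigmaCancer,kitBiasMean,kitBiasSd,slopeSd,replicateSd,cellSd
#'   generative model parameters (log2 scale; see class doc).
#' @param countModel,dispersion negative-binomial count layer (off by
#'   default; the analysis models operate on the log2 scale).
#' @param seed integer seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 100, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nCancers = 12, conditions = c("FF", "N", "Q", "R"),
                             replicates = 2,
                             nGenes = 18695, nReferenceGenes = 10,
                             muRange = c(-4, 9), refMuRange = c(7, 8),
                             sigmaCancer = 1,
                             kitBiasMean = c(N = 0.27, Q = 0.23, R = 0.19),
                             kitBiasSd = 0.6,
                             slopeSd = 0.35,
                             replicateSd = c(FF = 0.14, N = 0.14, Q = 0.19,
                                             R = 0.23),
                             cellSd = 0, countModel = FALSE, dispersion = 0.1,
                             seed = 1) {
  conditions <- as.character(conditions)
  kits <- conditions[-1]
  recycle <- function(x, labels, what) {
    if (is.null(names(x))) {
      if (length(x) == 1L) x <- rep(x, length(labels))
      if (length(x) != length(labels))
        stop(what, " must be length 1 or named per ",
             if (identical(labels, kits)) "kit" else "condition")
      names(x) <- labels
    }
    if (!all(labels %in% names(x)))
      stop(what, " lacks entries for: ",
           paste(setdiff(labels, names(x)), collapse = ", "))
    x[labels]
  }
  new("SimulationConfig",
      nCancers = as.integer(nCancers), conditions = conditions,
      replicates = {
        r <- recycle(replicates, conditions, "replicates")
        setNames(as.integer(r), names(r))
      },
      nGenes = as.integer(nGenes),
      nReferenceGenes = as.integer(nReferenceGenes),
      muRange = as.numeric(muRange), refMuRange = as.numeric(refMuRange),
      sigmaCancer = as.numeric(sigmaCancer),
      kitBiasMean = if (length(kits)) recycle(kitBiasMean, kits, "kitBiasMean")
                    else numeric(),
      kitBiasSd = as.numeric(kitBiasSd),
      slopeSd = if (length(kits)) recycle(slopeSd, kits, "slopeSd")
                else numeric(),
      replicateSd = recycle(replicateSd, conditions, "replicateSd"),
      cellSd = as.numeric(cellSd), countModel = isTRUE(countModel),
      dispersion = as.numeric(dispersion), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes (",
      object@nReferenceGenes, "reference ),", object@nCancers, "cancers x",
      length(object@conditions), "conditions (",
      paste(object@conditions, collapse = ", "), ")\n")
  cat("  replicates:",
      paste(names(object@replicates), object@replicates, sep = "=",
            collapse = ", "), "\n")
  cat("  sigma_cancer =", object@sigmaCancer,
      " cell sd =", object@cellSd,
      " count model:", if (object@countModel) "NB" else "off",
      " seed =", object@seed, "\n")
})

# evaluate expr with a private RNG stream; global RNG state untouched
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a replicated FF/FFPE expression study
#'
#' Draws a gene x sample matrix from the generative model of
#' \linkS4class{SimulationConfig} together with its study design and the full
#' per-gene ground truth (retrievable with \code{\link{syntheticTruth}}).
#' Given the same configuration (including seed) the output is bit-identical
#' across runs.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{KitExperiment} with scale \code{"log2"} (or
#'   \code{"counts"} when the count layer is on).
#' @examples
#' ke <- simulateStudy(simulationConfig(nGenes = 50, nCancers = 4, seed = 1))
#' ke
#' head(syntheticTruth(ke)$genes)
#' @export
simulateStudy <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  G <- config@nGenes
  nref <- config@nReferenceGenes
  conds <- config@conditions
  kits <- conds[-1]
  C <- config@nCancers
  cancers <- sprintf("C%02d", seq_len(C))
  gene_id <- sprintf("G%05d", seq_len(G))
  is_ref <- logical(G)
  if (nref > 0L) {
    ref_idx <- seq_len(nref)          # first genes are the reference panel
    gene_id[ref_idx] <- sprintf("REF%02d", seq_len(nref))
    is_ref[ref_idx] <- TRUE
  }

  design <- do.call(rbind, lapply(cancers, function(cc) {
    do.call(rbind, lapply(conds, function(k) {
      data.frame(sample_id = sprintf("%s_%s_r%d", cc, k,
                                     seq_len(config@replicates[k])),
                 cancer_id = cc, condition = k,
                 replicate = seq_len(config@replicates[k]),
                 stringsAsFactors = FALSE)
    }))
  }))

  out <- .withSeed(config@seed, {
    mu <- runif(G, config@muRange[1], config@muRange[2])
    if (nref > 0L)
      mu[is_ref] <- runif(nref, config@refMuRange[1], config@refMuRange[2])
    beta <- matrix(0, G, length(kits), dimnames = list(gene_id, kits))
    tau <- matrix(0, G, length(kits), dimnames = list(gene_id, kits))
    for (k in kits) {
      beta[!is_ref, k] <- config@kitBiasMean[k] +
        rnorm(sum(!is_ref), 0, config@kitBiasSd)
      tau[!is_ref, k] <- config@slopeSd[k]
    }
    a <- matrix(rnorm(G * C, 0, config@sigmaCancer), G, C,
                dimnames = list(gene_id, cancers))
    b <- array(0, dim = c(G, C, length(kits)),
               dimnames = list(gene_id, cancers, kits))
    for (k in kits)
      b[, , k] <- rnorm(G * C) * tau[, k]   # recycles tau down columns
    u <- NULL
    if (config@cellSd > 0) {
      u <- array(rnorm(G * C * length(conds), 0, config@cellSd),
                 dim = c(G, C, length(conds)),
                 dimnames = list(gene_id, cancers, conds))
    }
    Y <- matrix(0, G, nrow(design),
                dimnames = list(gene_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
      cc <- design$cancer_id[j]; k <- design$condition[j]
      col <- mu + a[, cc]
      if (k %in% kits) col <- col + beta[, k] + b[, cc, k]
      if (!is.null(u)) col <- col + u[, cc, match(k, conds)]
      Y[, j] <- col + rnorm(G, 0, config@replicateSd[k])
    }
    if (config@countModel)
      Y[] <- rnbinom(length(Y), mu = 2^Y, size = 1 / config@dispersion)
    list(Y = Y, mu = mu, beta = beta, tau = tau)
  })

  truth_genes <- data.frame(gene_id = gene_id, is_reference = is_ref,
                            mu = out$mu, stringsAsFactors = FALSE)
  for (k in kits) {
    truth_genes[[paste0("bias_", k)]] <- out$beta[, k]
    truth_genes[[paste0("slope_sd_", k)]] <- out$tau[, k]
  }
  ke <- KitExperiment(out$Y, design,
                      scale = if (config@countModel) "counts" else "log2",
                      reference = conds[1])
  metadata(ke)$truth <- list(genes = truth_genes,
                             sigma_cancer = config@sigmaCancer,
                             replicate_sd = config@replicateSd,
                             cell_sd = config@cellSd, seed = config@seed)
  metadata(ke)$config <- config
  ke
}

#' Default RNA-quality targets
#'
#' Condition medians for the three RNA quality metrics: RIN and DV200 from
#' the electrophoresis trace of the extracted RNA, and median TIN (transcript
#' integrity) from aligned reads. Defaults are the medians observed in the
#' motivating study for a fresh-frozen arm and FFPE kits N, Q and R.
#'
#' @return data.frame with columns \code{condition}, \code{RIN},
#'   \code{DV200}, \code{medTIN}.
#' @export
qualityTargets <- function() {
  data.frame(condition = c("FF", "N", "Q", "R"),
             RIN = c(7.2, 2.4, 2.5, 2.5),
             DV200 = c(88, 79.5, 73, 83),
             medTIN = c(75.84, 82.02, 81.41, 81.27),
             stringsAsFactors = FALSE)
}

#' Simulate per-sample RNA-quality metrics
#'
#' Draws RIN, DV200 and median TIN for every sample of the design implied by
#' \code{config}, normally distributed around the per-condition target
#' medians and clipped to the valid metric ranges (RIN 1-10, DV200 0-100,
#' TIN 0-100).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param targets data.frame as \code{\link{qualityTargets}}; must cover all
#'   configured conditions and lie within the metric ranges.
#' @param spread named numeric sd per metric (zero gives exact targets).
#' @param seed integer seed (defaults to \code{config@seed}).
#' @return data.frame with one row per sample: design columns plus
#'   \code{RIN}, \code{DV200}, \code{medTIN}.
#' @examples
#' q <- simulateQuality(simulationConfig(nGenes = 10, seed = 2))
#' summary(q$RIN)
#' @export
simulateQuality <- function(config, targets = qualityTargets(),
                            spread = c(RIN = 0.8, DV200 = 6, medTIN = 2),
                            seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  ranges <- list(RIN = c(1, 10), DV200 = c(0, 100), medTIN = c(0, 100))
  miss <- setdiff(config@conditions, targets$condition)
  if (length(miss))
    stop("quality targets missing for condition(s): ",
         paste(miss, collapse = ", "))
  for (m in names(ranges)) {
    if (!m %in% colnames(targets)) stop("targets lack column ", m)
    bad <- targets[[m]] < ranges[[m]][1] | targets[[m]] > ranges[[m]][2]
    if (any(bad))
      stop(m, " target outside valid range [", ranges[[m]][1], ", ",
           ranges[[m]][2], "]")
  }
  spread <- spread[names(ranges)]
  if (any(is.na(spread)) || any(spread < 0))
    stop("spread must give a non-negative sd for RIN, DV200 and medTIN")
  design <- do.call(rbind, lapply(sprintf("C%02d", seq_len(config@nCancers)),
    function(cc) do.call(rbind, lapply(config@conditions, function(k) {
      data.frame(sample_id = sprintf("%s_%s_r%d", cc, k,
                                     seq_len(config@replicates[k])),
                 cancer_id = cc, condition = k,
                 replicate = seq_len(config@replicates[k]),
                 stringsAsFactors = FALSE)
    }))))
  idx <- match(design$condition, targets$condition)
  .withSeed(seed, {
    for (m in names(ranges)) {
      v <- rnorm(nrow(design), mean = targets[[m]][idx], sd = spread[[m]])
      design[[m]] <- pmin(pmax(v, ranges[[m]][1]), ranges[[m]][2])
    }
    design
  })
}
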