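#' Pipeline configuration
#'
#' Collects everything \code{\link{runPipeline}} needs: either a simulation
#' block or input file paths (exactly one of the two), the reference
#' condition, the analysis thresholds (all defaulting to the study's
#' constants: expression -7.5, CCC 0.5, FDR 0.05, |LFC| grid 0/0.5/1/2),
#' the random-signature null parameters and the mixed-model options. A
#' configuration can also be read from YAML or JSON with
#' \code{\link{readPipelineConfig}}.
#'
#' @param simulation a \linkS4class{SimulationConfig}, or NULL when reading
#'   files.
#' @param expression,design,quality input TSV paths (NULL when simulating).
#' @param scale declared scale of the expression file.
#' @param referenceGenes normalizer panel gene ids; defaults to the
#'   simulated panel (simulation) and is required for count input.
#' @param signatures named list of \linkS4class{GeneSignature} objects, or
#'   NULL to use a signature assembled from the simulated truth.
#' @param reference reference condition label.
#' @param exprThreshold,cccThreshold,fdrAlpha,lfcGrid analysis thresholds.
#' @param nullB,nullBins random-signature null draw count and bin count.
#' @param nullKit kit for the null statistic (default: first kit).
#' @param lmeStructure,includeCell mixed-model options (see
#'   \code{\link{fitLmeSingle}}).
#' @param seed integer seed for every stochastic stage.
#' @param outDir output directory (created), or NULL to skip writing.
#' @return a validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulation = NULL, expression = NULL,
                           design = NULL, quality = NULL,
                           scale = "counts", referenceGenes = NULL,
                           signatures = NULL, reference = "FF",
                           exprThreshold = -7.5, cccThreshold = 0.5,
                           fdrAlpha = 0.05, lfcGrid = c(0, 0.5, 1, 2),
                           nullB = 10000, nullBins = 10, nullKit = NULL,
                           lmeStructure = "diagonal", includeCell = FALSE,
                           seed = 1, outDir = NULL) {
  sim <- !is.null(simulation)
  files <- !is.null(expression) || !is.null(design)
  if (sim == files)
    stop("exactly one of a simulation block or input file paths required")
  if (files && (is.null(expression) || is.null(design)))
    stop("file input needs both expression and design paths")
  if (sim && !is(simulation, "SimulationConfig"))
    stop("simulation must be a SimulationConfig")
  if (!is.null(fdrAlpha) && (fdrAlpha <= 0 || fdrAlpha >= 1))
    stop("fdrAlpha must be in (0, 1)")
  if (cccThreshold < -1 || cccThreshold > 1)
    stop("cccThreshold must be in [-1, 1]")
  if (nullB < 0 || nullBins < 1) stop("invalid null parameters")
  cfg <- list(simulation = simulation, expression = expression,
              design = design, quality = quality, scale = scale,
              referenceGenes = referenceGenes, signatures = signatures,
              reference = reference, exprThreshold = exprThreshold,
              cccThreshold = cccThreshold, fdrAlpha = fdrAlpha,
              lfcGrid = lfcGrid, nullB = as.integer(nullB),
              nullBins = as.integer(nullBins), nullKit = nullKit,
              lmeStructure = lmeStructure, includeCell = includeCell,
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields map directly onto \code{\link{pipelineConfig}} arguments;
#' a \code{simulation} block maps onto \code{\link{simulationConfig}}
#' arguments.
#'
#' @param path .yaml/.yml or .json file.
#' @return a \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$simulation))
    raw$simulation <- do.call(simulationConfig, raw$simulation)
  do.call(pipelineConfig, raw)
}

.writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

#' Run the full reliability pipeline
#'
#' Executes filter (counts only) -> reference-panel normalization ->
#' replicate averaging -> concordance, replicate-difference, mixed-model,
#' differential and signature analyses, and writes per-stage TSV/JSON
#' artifacts plus a summary (per-kit medians of CCC / correlation /
#' accuracy, mixed-model bias and slope variance, replicate difference) and
#' a run log (seed, config hash, package versions) to \code{outDir}.
#'
#' @param config a \code{"PipelineConfig"} from \code{\link{pipelineConfig}}
#'   or \code{\link{readPipelineConfig}}.
#' @param verbose print stage progress.
#' @return (invisibly) a report list with elements \code{data} (the
#'   normalized \linkS4class{KitExperiment}), \code{averaged},
#'   \code{concordance} (per-kit tables), \code{overlap},
#'   \code{replicateDifference}, \code{lme}, \code{de}, \code{degCounts},
#'   \code{signatures}, \code{quality}, \code{summary}.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  quality <- NULL
  if (!is.null(config$simulation)) {
    say("simulating study")
    sim <- config$simulation
    sim@seed <- config$seed
    ke <- stage("simulate", simulateStudy(sim))
    quality <- stage("simulate", simulateQuality(sim, seed = config$seed + 1L))
    refGenes <- syntheticTruth(ke)$genes$gene_id[
      syntheticTruth(ke)$genes$is_reference]
    if (!length(refGenes)) refGenes <- config$referenceGenes
  } else {
    say("reading inputs")
    ke <- stage("read", {
      m <- readExpressionMatrix(config$expression, scale = config$scale)
      d <- readDesign(config$design, reference = config$reference)
      KitExperiment(m, d, scale = attr(m, "scale"),
                    reference = config$reference)
    })
    if (!is.null(config$quality))
      quality <- utils::read.delim(config$quality, stringsAsFactors = FALSE)
    refGenes <- config$referenceGenes
  }

  if (exprScale(ke) == "counts") {
    say("filtering unexpressed genes")
    ke <- stage("filter", filterExpressed(ke))
  }
  norm <- ke
  if (exprScale(norm) != "normalized-log2") {
    if (is.null(refGenes))
      stop("pipeline stage 'normalize' failed: no reference panel ",
           "(set referenceGenes)", call. = FALSE)
    refGenes <- intersect(refGenes, rownames(norm))
    say("normalizing against ", length(refGenes), " reference genes")
    norm <- stage("normalize", logNormalize(norm, refGenes))
  }
  say("averaging replicates")
  avg <- stage("average", averageReplicates(norm))

  kits <- kitConditions(norm)
  say("concordance analysis")
  conc <- stage("concordance",
                lapply(setNames(kits, kits),
                       function(k) concordanceTable(avg, k)))
  overlap <- stage("concordance",
                   highConcordantOverlap(conc, config$exprThreshold,
                                         config$cccThreshold))
  repdiff <- stage("replicates", replicateDifference(norm))

  say("mixed-model analysis")
  lme <- stage("lme", fitLmeAll(norm, structure = config$lmeStructure,
                                includeCell = config$includeCell))

  say("differential analysis")
  de <- stage("differential",
              pairedLinearFit(avg, contrasts = "all",
                              alpha = config$fdrAlpha))
  degs <- stage("differential",
                countDegs(de, lfcThresholds = config$lfcGrid,
                          alpha = config$fdrAlpha))

  say("signature analysis")
  sigs <- config$signatures
  if (is.null(sigs) && !is.null(syntheticTruth(norm))) {
    tg <- syntheticTruth(norm)$genes
    inf <- utils::head(tg$gene_id[!tg$is_reference &
                                    tg$gene_id %in% rownames(norm)], 18)
    ref <- intersect(tg$gene_id[tg$is_reference], rownames(norm))
    if (length(inf) >= 2L)
      sigs <- list(synthetic18 = geneSignature("synthetic18", inf, ref))
  }
  sigRes <- NULL
  if (!is.null(sigs)) {
    nullKit <- if (is.null(config$nullKit)) kits[1] else config$nullKit
    sigRes <- stage("signatures", lapply(sigs, function(sg) {
      sc <- scoreSignature(norm, sg)
      list(signature = sg, scores = sc,
           concordance = signatureConcordance(sc, norm),
           replicate_percent = replicatePercentDifference(sc, norm),
           null = if (config$nullB > 0)
             randomSignatureNull(norm, sg, kit = nullKit,
                                 B = config$nullB,
                                 nBins = config$nullBins,
                                 seed = config$seed + 2L) else NULL)
    }))
  }

  qualRes <- if (!is.null(quality))
    stage("quality", qualityIndexEffects(quality,
                                         reference = config$reference))

  summary <- .pipelineSummary(conc, lme, repdiff, overlap, kits)
  report <- list(data = norm, averaged = avg, concordance = conc,
                 overlap = overlap, replicateDifference = repdiff,
                 lme = lme, de = de, degCounts = degs,
                 signatures = sigRes, quality = quality,
                 qualityEffects = qualRes, summary = summary,
                 seed = config$seed)
  if (!is.null(config$outDir))
    .writeReport(report, config, quality)
  invisible(report)
}

.pipelineSummary <- function(conc, lme, repdiff, overlap, kits) {
  mad1 <- function(v) stats::mad(v, constant = 1, na.rm = TRUE)
  rows <- lapply(kits, function(k) {
    tb <- conc[[k]]; ok <- tb$defined
    ls <- lme$summary[lme$summary$kit == k, ]
    rd <- repdiff$summary[repdiff$summary$condition == k, ]
    data.frame(kit = k,
               ccc_median = stats::median(tb$ccc[ok]),
               ccc_mad = mad1(tb$ccc[ok]),
               r_median = stats::median(tb$pearson_r[ok]),
               r_mad = mad1(tb$pearson_r[ok]),
               bias_term_median = stats::median(tb$bias_term[ok],
                                                na.rm = TRUE),
               bias_term_mad = mad1(tb$bias_term[ok]),
               lme_bias_median = ls$median_bias,
               lme_bias_mad = ls$mad_bias,
               lme_variance_median = ls$median_tau2,
               lme_variance_mad = ls$mad_tau2,
               replicate_diff_median = rd$median,
               replicate_diff_mad = rd$mad,
               stringsAsFactors = FALSE)
  })
  list(perKit = do.call(rbind, rows),
       percentSharedHighConcordant = overlap$percentShared)
}

.writeReport <- function(report, config, quality) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(config$outDir, ...)
  writeExpressionMatrix(report$data, fp("expression_normalized.tsv"))
  writeDesign(studyDesign(report$data), fp("design.tsv"))
  tr <- syntheticTruth(report$data)
  if (!is.null(tr))
    utils::write.table(tr$genes, fp("synthetic_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  concAll <- do.call(rbind, lapply(names(report$concordance), function(k)
    cbind(kit = k, report$concordance[[k]])))
  utils::write.table(concAll, fp("concordance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$lme$results, fp("lme_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$de, fp("de_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$degCounts, fp("deg_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(report$replicateDifference$perGene),
               report$replicateDifference$perGene, check.names = FALSE),
    fp("replicate_difference.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(quality))
    utils::write.table(quality, fp("quality.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$qualityEffects))
    utils::write.table(report$qualityEffects, fp("quality_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$signatures)) {
    for (nm in names(report$signatures)) {
      sr <- report$signatures[[nm]]
      utils::write.table(
        data.frame(sample_id = names(sr$scores), score = sr$scores),
        fp(paste0("signature_scores_", nm, ".tsv")), sep = "\t",
        quote = FALSE, row.names = FALSE)
      utils::write.table(sr$concordance,
                         fp(paste0("signature_concordance_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(sr$null)) {
        .writeJSON(sr$null[c("observed", "percentile", "B", "kit",
                             "n_bins", "seed")],
                   fp(paste0("signature_null_", nm, ".json")))
        utils::write.table(data.frame(draw = seq_along(sr$null$draws),
                                      ccc = sr$null$draws),
                           fp(paste0("signature_null_draws_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  .writeJSON(list(perKit = report$summary$perKit,
                  percent_shared_high_concordant =
                    report$summary$percentSharedHighConcordant),
             fp("summary.json"))
  cfgOut <- config
  cfgOut$outDir <- NULL          # not part of the analysis provenance
  cfgOut$signatures <- names(config$signatures)
  cfgOut$simulation <- if (!is.null(config$simulation))
    list(nGenes = config$simulation@nGenes,
         nCancers = config$simulation@nCancers,
         conditions = config$simulation@conditions,
         seed = config$simulation@seed)
  .writeJSON(unclass(cfgOut), fp("config.json"))
  .writeJSON(list(seed = config$seed,
                  config_hash = unname(tools::md5sum(fp("config.json"))),
                  packages = list(
                    ffpeReliability =
                      as.character(utils::packageVersion("ffpeReliability")),
                    limma = as.character(utils::packageVersion("limma")),
                    R = paste(R.version$major, R.version$minor, sep = "."))),
             fp("runlog.json"))
  invisible(config$outDir)
}
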