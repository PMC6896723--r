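# ffpeReliability

Reliability analysis of RNA-seq gene expression from formalin-fixed
paraffin-embedded (FFPE) tumor tissue against matched fresh-frozen (FF)
samples, across RNA extraction kits.

## The problem

FFPE is how clinical archives preserve tissue, and fixation degrades RNA.
Before an expression assay or a multi-gene signature can be run on FFPE
material, it has to be credentialed against matched FF tissue — and the RNA
extraction kit is one of the pre-analytical choices that could move the
numbers. The study design this package analyzes is a replicated paired one:
each of *C* tumors contributes an FF arm plus one FFPE arm per extraction
kit (here N, Q, R), with duplicate RNA extractions per kit.

For every gene the package quantifies:

* **Agreement** between arms via Lin's concordance correlation coefficient

  $$\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x-\bar y)^2}
    = r \cdot C_b,$$

  with population (1/n) moments; the Pearson factor $r$ measures scatter,
  the accuracy factor $C_b \in (0,1]$ measures how far the best-fit line
  sits from the identity.

* **A bias/variance decomposition** via the gene-level mixed model

  $$Y = \mathsf{Kit} + (\mathsf{Kit} \mid \mathsf{Cancer})
        + (1 \mid \mathsf{cell}) + \varepsilon,$$

  fitted by REML: fixed kit bias $\beta_k$, across-tumor bias variance
  $\tau_k^2$, replicate noise $\sigma_e^2$.

* **Differential distortion** via the paired two-factor model
  $\text{value} = \mathsf{Cancer} + \mathsf{Kit}$ with ordinary t-tests and
  Benjamini–Hochberg correction, counted at |LFC| thresholds 0/0.5/1/2.

* **Signature robustness**: two-gene-set scores (bundled EndoPredict,
  Recurrence Score and SET ER/PR gene lists) compared against 10,000
  random signatures matched in size and expression range, plus
  between-replicate score reproducibility and Bland–Altman agreement.

Because no public dataset pairs FF with three FFPE kits in duplicate on the
same tumors, the package ships a synthetic-data generator
(`simulateStudy()`) that draws from exactly the mixed model above with full
ground truth, so every estimator is testable by parameter recovery. See the
methods vignette (`vignettes/ffpe-reliability-methods.Rmd`) for the model,
parameter defaults, and design decisions.

## A worked example

```r
library(ffpeReliability)
library(SummarizedExperiment)   # for assay()

cfg <- simulationConfig(nGenes = 2000, seed = 42)   # 12 tumors, FF + N/Q/R
ke  <- simulateStudy(cfg)
ke
#> KitExperiment: 2000 genes x 96 samples
#>   scale: log2
#>   cancers: 12  conditions: FF, N, Q, R (reference: FF )
#>   samples per condition: FF=24, N=24, Q=24, R=24

tg   <- syntheticTruth(ke)$genes
norm <- logNormalize(ke, tg$gene_id[tg$is_reference])  # 10-gene panel
avg  <- averageReplicates(norm)

tab <- concordanceTable(avg, "N")
round(c(median_ccc = median(tab$ccc), median_r = median(tab$pearson_r),
        median_bias_term = median(tab$bias_term)), 3)
#>       median_ccc         median_r median_bias_term
#>            0.853            0.950            0.911
```

Median CCC 0.85 with median correlation 0.95 says most disagreement between
the FFPE kit and FF comes from per-gene shifts (accuracy 0.91), not from
scatter. The mixed model decomposes one gene's disagreement explicitly:

```r
fitLmeSingle(assay(norm)[42, ], studyDesign(norm), unit = "G00042")
#> LMEResult [G00042] diagonal structure, n = 96
#>   kit bias: N=1.28, Q=0.1938, R=-0.3742
#>   slope var: N=0.09299, Q=0.09455, R=0.08563
#>   sigma_a2 = 0.8134  sigma_e2 = 0.04029  sigma_u2 = 0
#>   -2 REML = -24.9923  converged: TRUE
```

This gene is inflated by ~1.3 log2 units in kit N relative to FF (the
generator's truth for it was 1.24), with that bias varying across tumors
(slope sd ~0.3) on top of replicate noise sd ~0.2. A signature built from
high-signal genes beats most expression-matched random signatures:

```r
sig <- geneSignature("demo", tg$gene_id[!tg$is_reference][1:18],
                     tg$gene_id[tg$is_reference])
randomSignatureNull(norm, sig, kit = "N", B = 1000, seed = 42)
#> RandomSignatureNull: observed CCC = 0.9699 vs 1000 expression-matched random signatures (kit N )
#>   percentile: 95.4  (null median 0.8287 )
```

`runPipeline(pipelineConfig(simulation = cfg, outDir = "out"))` runs every
stage and writes per-gene TSVs plus a JSON summary of the per-kit medians
(CCC / r / accuracy, mixed-model bias and variance, replicate difference)
and DEG counts.

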