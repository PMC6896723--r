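---
title: "Methods: quantifying the reliability of FFPE RNA-seq across extraction kits"
author: "ffpeReliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the reliability of FFPE RNA-seq across extraction kits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpeReliability)
```

# The problem

Clinical archives preserve tumor tissue as formalin-fixed paraffin-embedded
(FFPE) blocks. Formalin fixation fragments and chemically modifies RNA, so
any expression assay run on FFPE material has to be credentialed against the
gold standard — matched fresh-frozen (FF) tissue — before its numbers can be
trusted. One pre-analytical choice in that chain is the RNA extraction kit.
This package implements the statistical side of such a credentialing study:
a replicated paired design in which every tumor contributes one FF arm and
several FFPE arms (one per extraction kit), with duplicate RNA extractions
per kit, all measured by whole-transcriptome RNA-seq.

The package answers four questions, each with its own module:

1. **Agreement** — per gene and per signature, how close are FFPE
   measurements to matched FF? (Lin's concordance correlation coefficient.)
2. **Decomposition** — how much of the disagreement is a systematic kit
   bias, how much is tumor-specific bias, and how much is replicate noise?
   (A gene-level linear mixed model, estimated by REML.)
3. **Differential distortion** — which genes shift significantly between
   arms, and by how much? (A paired two-factor model with BH correction.)
4. **Signature robustness** — do multi-gene scores survive the
   FF-to-FFPE transfer better than chance? (An expression-matched
   random-signature null.)

# Data model and preprocessing

Data live in a `KitExperiment`, a `SummarizedExperiment` whose `colData`
records `(cancer_id, condition, replicate)` and whose metadata carries a
declared value scale: raw `counts`, `log2`, or `normalized-log2`.

Preprocessing mirrors standard practice for reference-panel assays:

* `filterExpressed()` removes genes with a zero count in *any* sample (one
  global intersection across condition groups, not per-kit lists). "Not
  expressed" is operationalized as `count == 0`; a `minCount` argument is
  exposed because the zero cutoff is a convention, not a law.
* `logNormalize()` log2-transforms (pseudo-count 1 — immaterial for genes
  that survived the zero filter, kept for robustness) and subtracts, per
  sample, the arithmetic mean of a housekeeping panel: the 10 reference
  genes of the SET ER/PR index (`referencePanel()`). The mean (not median)
  matches how such panels are used in signature assays; both are available.
  After this step every sample's values are invariant to per-sample shifts,
  which is the entire point of a reference panel.
* `averageReplicates()` collapses technical replicates by arithmetic mean;
  agreement and differential analyses run on the averaged cells, while the
  mixed model uses the replicate-level matrix (it needs the replicates).
* `stratifyByExpression()` splits genes at normalized expression −7.5,
  "high" meaning strictly greater. With a reference panel whose log2 mean
  sits near +7.5, −7.5 is where a raw count of ~1 lands, i.e. the detection
  limit. The gene summary used is the mean across samples (the choice is
  documented and configurable because the convention is not universal).

# Agreement: Lin's CCC

For paired vectors \(x, y\) over tumors,
\[
\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},
\]
with population (1/n) moments, following Lin's original estimator — at
n = 12 tumors the sample-moment variant differs noticeably, so the choice
is fixed and tested. CCC factors as Pearson correlation (scatter around the
best-fit line) times an accuracy term \(C_b \in (0,1]\) (distance of that
line from the identity); both factors are reported so that "noisy" and
"shifted" genes can be told apart. Zero-variance genes are flagged
undefined and excluded from medians, never silently scored 0.

Per-kit gene tables feed:

* `highConcordantOverlap()` — the share of genes that are high-expression
  (mean normalized expression > −7.5) *and* concordant (CCC > 0.5) in every
  kit. The denominator is the union of the per-kit sets; a union denominator
  is the conservative reading and is stated here because other denominators
  (per-kit list sizes) change the number.
* `replicateDifference()` — per gene and condition, the median across tumors
  of |replicate 1 − replicate 2|; with noise sd \(\sigma_e\) this statistic
  concentrates at the half-normal median \(\sigma_e \sqrt2 \cdot 0.6745\),
  which is what the calibration tests assert.
* `blandAltman()` — mean difference and 1.96·sd limits of agreement, for
  cross-platform score comparisons.

Summaries use the median and the *raw* median absolute deviation
(`mad(constant = 1)`), matching how such tables are usually printed.

# Decomposition: the reliability mixed model

Per gene (or signature score), on normalized log2 values \(Y\):
\[
Y = \mathsf{Kit} + (\mathsf{Kit} \mid \mathsf{Cancer}) + (1 \mid \mathsf{cell}) + \varepsilon
\]
with the FF arm as fixed-effect reference. The fixed kit coefficients
\(\beta_k\) are systematic log2 biases of each kit against FF; the random
per-tumor slopes (variance \(\tau_k^2\)) measure how much that bias varies
across tumors; the residual \(\sigma_e^2\) is replicate noise; a random
per-tumor intercept (\(\sigma_a^2\)) absorbs tumor-level expression.

Implementation choices, each of which was genuinely open:

* **Slope covariance.** The notation \((\mathsf{Kit}\mid\mathsf{Cancer})\)
  implies a full 4×4 covariance of intercept and slopes. With 12 tumors
  that matrix is barely identified, so the default is diagonal
  (independent per-kit slopes); `structure = "full"` fits the unstructured
  covariance through its Cholesky factor for users who want it. The
  default is a stability choice, not a claim about which structure any
  particular study used.
* **The cell term.** With duplicate extractions, a per-(tumor, kit) cell
  intercept is aliased with the slope except through the FF cells and is
  weakly identified; the default fixes \(\sigma_u^2 = 0\) and
  `includeCell = TRUE` turns it on. The synthetic generator exposes the
  same term (`cellSd`, default 0) so the assumption can be stress-tested.
* **Estimation.** REML, with variances optimized on the log scale from a
  deterministic method-of-moments start (`balancedClosedForm()`), a
  bounded quasi-Newton pass from two deterministic starts, a Nelder-Mead
  escape, and a final bounded polish; convergence tolerance ~1e-8 on the
  criterion. The criterion function itself (`remlCriterion()`) is exported
  so the optimum can be audited with independent optimizers — the test
  suite does exactly that, and also cross-checks estimates against lme4.
* **Boundaries.** Variance estimates driven to zero are reported as pinned
  (`boundary`), never jittered; a stall with components on the boundary is
  a boundary optimum, reported as converged-with-boundary.

# Differential distortion

Genome-wide differential analysis in the original count world would use a
negative-binomial tool; this package instead fits, per gene, ordinary least
squares on the replicate-averaged normalized log2 cells:
\(\text{value} = \mathsf{Cancer} + \mathsf{Kit}\), the tumor acting as a
blocking factor. This preserves the design matrix of the count-based
approach while staying on the scale every other module uses; it is declared
as a simplification — dispersion shrinkage and count-level inference are
deliberately out of scope. The gene-wise least squares goes through
`limma::lmFit`, but each kit contrast gets an *ordinary* t-test on the
residual degrees of freedom (no empirical-Bayes moderation), BH-adjusted
across genes within each contrast (pooling across contrasts is the other
defensible choice; per-contrast is the default and is stated). Kit-vs-kit
contrasts reuse the one joint fit. DEG tables count genes with FDR < 0.05
at |LFC| thresholds 0/0.5/1/2, split by direction. Degenerate fits (zero
residual df, or an exact fit) are flagged, never given a fabricated p.

RNA-quality indices (RIN, DV200, median TIN) run through the same paired
two-factor model after replicate averaging (`qualityIndexEffects()`), and
`mannWhitneyU()` provides the nonparametric two-sample comparison (exact by
enumeration when n + m ≤ 12 without ties, else normal approximation with
tie and continuity corrections).

# Signature robustness

`scoreSignature()` computes the classic two-set score: mean log2 expression
of informative genes minus mean of reference genes, optionally weighted.
The bundled definitions (EndoPredict 8+3, Recurrence Score 16+5, SET ER/PR
18+10) are gene lists only — the commercial coefficient sets are
proprietary, so scores here are unweighted by default and per-gene weights
are user-suppliable. This is a documented deviation from the commercial
scales; concordance statements about these scores concern the gene sets,
not the branded algorithms.

`randomSignatureNull()` asks whether a signature's FF-vs-kit CCC is better
than that of a random signature of the same size and expression profile:
genes are binned into quantile bins of mean expression (default 10), and
each of B = 10,000 draws replaces every informative gene by a random gene
from the same bin, without replacement within a draw, scored against the
true reference panel. "Same expression range" is operationalized as
bin-matching because no finer definition is standard; the bin count is a
parameter. The percentile is the fraction of null draws strictly below the
observed CCC — under exchangeability it is uniform, and the test suite
verifies that calibration (200 trials at B = 500, Kolmogorov–Smirnov).
Resampling replaces informative genes only, reusing the true reference
panel; resampling the panel too would conflate normalizer choice with
signature choice.

`replicatePercentDifference()` reports 100·|replicate score difference| /
(range of replicate-averaged scores across samples) — the range denominator
makes the percentage scale-invariant; it is configurable because the
denominator convention is not standard.

# The synthetic-data generator

No public dataset accompanies this design (matched FF + three FFPE kits,
in duplicate, on the same tumors), so the generator *is* the study bed. It
draws
\[
Y_{gckt} = \mu_g + a_{gc} + \beta_{gk} + b_{gck} + u_{gck} + \varepsilon_{gckt}
\]
exactly as the mixed model assumes, with full ground truth retained for
recovery tests. Defaults are the study conditions:

* 12 cancers; conditions FF, N, Q, R; 2 replicates each. (FF replicates
  default to 2 so that FF replicate noise is estimable; the count is
  configurable per condition.)
* 18,695 genes, 10 of them a reference panel drawn at high baseline
  (log2 ≈ 7–8), so that the panel mean sits near +7.5 and the −7.5
  normalized threshold corresponds to the count-of-1 detection limit.
  Baselines for the other genes are uniform on (−4, 9), which exercises
  both sides of that threshold.
* Per-kit parameters back-derived from the decomposition medians this
  design typically produces: kit bias means 0.27/0.23/0.19 (per-gene sd
  0.6), slope sd 0.35 (≈ variance 0.12), replicate noise sd
  0.14/0.14/0.19/0.23 for FF/N/Q/R (the half-normal median maps these to
  replicate differences of ≈ 0.13/0.13/0.18/0.22). Cancer sd 1.
* An optional negative-binomial count layer (mean \(2^Y\)) feeds the
  zero-count filter; it is off by default because every analysis model
  operates on the log2 scale.
* Quality metrics are drawn around condition medians (FF RIN 7.2 vs FFPE
  ≈ 2.5, DV200 88 vs 73–83, median TIN 75.8 vs ≈ 81.5) and clipped to
  their valid ranges.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: expression-dependent noise (in real FFPE
data low-count genes are noisier, which drags the genome-wide median CCC
down; here noise is constant per condition, so simulated median CCC runs
higher than a real study's), library-size and GC effects, non-normal error
tails, fixation-time covariates, and any correlation structure between
genes beyond the shared tumor effect. Recovery tests certify the
estimators under the model's own assumptions; they are necessary, not
sufficient, for real-data validity.

# Numerical choices and problem sizes

* Determinism: every stochastic routine takes a seed and uses a private
  RNG stream; fixed-seed pipeline runs are byte-identical, which the test
  suite asserts file-by-file.
* The REML surface is optimized on log variances with bounds
  [log 1e-12, log(10³·var(y))]; ties at the zero boundary are reported.
* Test and acceptance problem sizes are chosen so the whole suite runs in
  minutes on one CPU while keeping Monte-Carlo error inside the asserted
  tolerances: 500 genes for mixed-model recovery, 2000 for replicate-noise
  calibration and FDR control, 200 × B = 500 for null calibration; the
  acceptance script runs the full pipeline at 4000 genes with B = 10,000
  null draws. These sizes are the package's own trade-off between runtime
  and Monte-Carlo precision at the asserted tolerances.

# Known limitations

* The per-gene OLS differential model understates the count-level
  uncertainty of genuinely low-count genes; it is honest on the log2 scale
  the package works in, but is not a drop-in replacement for
  negative-binomial inference on raw counts.
* With 12 tumors, per-gene slope variances \(\tau_k^2\) are estimated with
  ~20% relative noise; only their distribution across genes (medians,
  MADs) is stable, and the reported per-gene values should be read
  accordingly.
* The full slope-covariance structure frequently lands on boundary fits at
  this design size — that is a property of the design, and the reason the
  diagonal structure is the default.
* Bundled signature scores are unweighted surrogates for the commercial
  algorithms and must not be interpreted on their clinical scales.
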