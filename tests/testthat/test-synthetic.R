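test_that("zero-noise simulation reproduces mu + beta exactly", {
  cfg <- simulationConfig(nGenes = 40, nCancers = 4, nReferenceGenes = 5,
                          sigmaCancer = 0, slopeSd = 0, replicateSd = 0,
                          kitBiasMean = c(N = 0.3, Q = -0.2, R = 0.5),
                          kitBiasSd = 0, seed = 7)
  ke <- simulateStudy(cfg)
  tg <- syntheticTruth(ke)$genes
  d <- studyDesign(ke)
  x <- assay(ke)
  for (j in seq_len(ncol(x))) {
    k <- as.character(d$condition[j])
    expected <- tg$mu + if (k == "FF") 0 else tg[[paste0("bias_", k)]]
    expect_equal(unname(x[, j]), expected, tolerance = 0)
  }
  # replicates of every cell identical
  cells <- split(seq_len(ncol(x)), paste(d$cancer_id, d$condition))
  for (ii in cells)
    expect_identical(x[, ii[1]], x[, ii[2]])
  # reference genes carry no kit bias
  expect_true(all(tg$bias_N[tg$is_reference] == 0))
})

test_that("simulation is bit-identical across runs with the same seed", {
  cfg <- simulationConfig(nGenes = 60, nCancers = 5, seed = 42)
  expect_identical(assay(simulateStudy(cfg)), assay(simulateStudy(cfg)))
  expect_identical(simulateQuality(cfg), simulateQuality(cfg))
  cfg2 <- simulationConfig(nGenes = 60, nCancers = 5, seed = 43)
  expect_false(identical(assay(simulateStudy(cfg)),
                         assay(simulateStudy(cfg2))))
})

test_that("moments of the generated data match the configured parameters", {
  cfg <- simulationConfig(nGenes = 2000, nCancers = 12,
                          nReferenceGenes = 0,
                          kitBiasMean = 0.3, kitBiasSd = 0,
                          slopeSd = 0.35, replicateSd = 0.15, seed = 101)
  ke <- simulateStudy(cfg)
  d <- studyDesign(ke)
  x <- assay(ke)
  cell <- paste(d$cancer_id, d$condition, sep = "_")
  cm <- t(rowsum(t(x), cell) / 2)           # cell means (2 reps each)
  ffCells <- paste(unique(d$cancer_id), "FF", sep = "_")
  for (k in c("N", "Q", "R")) {
    diffs <- cm[, paste(unique(d$cancer_id), k, sep = "_")] - cm[, ffCells]
    expect_lt(abs(mean(diffs) - 0.3), 0.02)
  }
  # within-cell replicate variance: mean of squared replicate diff / 2
  reps <- split(seq_len(ncol(x)), cell)
  sqdiff <- vapply(reps, function(ii) (x[, ii[1]] - x[, ii[2]])^2,
                   numeric(nrow(x)))
  expect_lt(abs(mean(sqdiff) / 2 - 0.15^2), 0.1 * 0.15^2)
})

test_that("variance components converge to configuration at many genes", {
  cfg <- simulationConfig(nGenes = 5000, nCancers = 12, nReferenceGenes = 0,
                          sigmaCancer = 0.8, kitBiasMean = 0, kitBiasSd = 0,
                          slopeSd = 0.3, replicateSd = 0.2, seed = 55)
  ke <- simulateStudy(cfg)
  d <- studyDesign(ke)
  x <- assay(ke)
  cell <- paste(d$cancer_id, d$condition, sep = "_")
  cm <- t(rowsum(t(x), cell) / 2)
  reps <- split(seq_len(ncol(x)), cell)
  sqd <- vapply(reps, function(ii) (x[, ii[1]] - x[, ii[2]])^2,
                numeric(nrow(x)))
  se2 <- mean(sqd) / 2
  expect_lt(abs(se2 - 0.2^2), 0.1 * 0.2^2)
  ffCells <- paste(unique(d$cancer_id), "FF", sep = "_")
  dN <- cm[, paste(unique(d$cancer_id), "N", sep = "_")] - cm[, ffCells]
  tau2 <- mean(apply(dN, 1, var)) - se2        # minus noise of two cell means
  expect_lt(abs(tau2 - 0.3^2), 0.1 * 0.3^2)
  va <- mean(apply(cm[, ffCells], 1, var)) - se2 / 2
  expect_lt(abs(va - 0.8^2), 0.1 * 0.8^2)
})

test_that("negative-binomial count layer yields counts near 2^Y", {
  cfg <- simulationConfig(nGenes = 500, nCancers = 6, nReferenceGenes = 0,
                          muRange = c(4, 8), sigmaCancer = 0.3,
                          kitBiasMean = 0, kitBiasSd = 0, slopeSd = 0,
                          replicateSd = 0.1, countModel = TRUE,
                          dispersion = 0.05, seed = 8)
  ke <- simulateStudy(cfg)
  expect_identical(exprScale(ke), "counts")
  x <- assay(ke)
  expect_true(all(x >= 0) && all(x == round(x)))
  tg <- syntheticTruth(ke)$genes
  expect_lt(abs(median(log2(rowMeans(x) + 1)) - median(tg$mu)), 0.5)
})

test_that("quality simulation respects targets, ranges and determinism", {
  cfg <- simulationConfig(nGenes = 15, nCancers = 3, seed = 3)
  q0 <- simulateQuality(cfg, spread = c(RIN = 0, DV200 = 0, medTIN = 0))
  expect_true(all(q0$RIN[q0$condition == "FF"] == 7.2))
  expect_true(all(q0$DV200[q0$condition == "Q"] == 73))
  qw <- simulateQuality(cfg, spread = c(RIN = 50, DV200 = 500, medTIN = 500))
  expect_true(all(qw$RIN >= 1 & qw$RIN <= 10))
  expect_true(all(qw$DV200 >= 0 & qw$DV200 <= 100))
  expect_true(all(qw$medTIN >= 0 & qw$medTIN <= 100))
  bad <- qualityTargets(); bad$RIN[1] <- 12
  expect_error(simulateQuality(cfg, targets = bad), "outside valid range")
  expect_error(simulateQuality(simulationConfig(nGenes = 15,
                                                conditions = c("FF", "X"),
                                                replicateSd = 0.1,
                                                kitBiasMean = 0)),
               "missing for condition")
})

test_that("sample medians converge to quality targets", {
  # 2500 cancers x 4 replicates of one FF condition = 10,000 samples
  cfg <- simulationConfig(nGenes = 15, nCancers = 2500,
                          conditions = "FF", replicates = c(FF = 4),
                          replicateSd = c(FF = 0.1), seed = 12)
  q <- simulateQuality(cfg)
  expect_lt(abs(median(q$RIN) - 7.2) / 7.2, 0.02)
  expect_lt(abs(median(q$DV200) - 88) / 88, 0.02)
  expect_lt(abs(median(q$medTIN) - 75.84) / 75.84, 0.02)
})

test_that("invalid designs are rejected", {
  expect_error(simulationConfig(replicates = c(FF = 0, N = 2, Q = 2, R = 2)),
               "replicate")
  expect_error(simulationConfig(nGenes = 5, nReferenceGenes = 5),
               "nReferenceGenes")
  expect_error(simulationConfig(replicateSd = -1), "sds")
})
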