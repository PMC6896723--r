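test_that("balancedClosedForm matches hand moment computations", {
  # zero replicate noise: kit - FF cell differences 0.1 / 0.5 / 0.3
  cancers <- c("C1", "C2", "C3")
  ff <- c(1, 2, 3)
  diffs <- c(0.1, 0.5, 0.3)
  vals <- as.vector(rbind(ff, ff, ff + diffs, ff + diffs))
  d <- expand.grid(replicate = 1:2, condition = c("FF", "N"),
                   cancer_id = cancers, stringsAsFactors = FALSE)
  d$condition <- factor(d$condition, levels = c("FF", "N"))
  d$sample_id <- sprintf("s%d", seq_len(nrow(d)))
  y <- vals[order(rep(seq_len(12), 1))]
  # rebuild y aligned with d: replicate-major within condition within cancer
  y <- unlist(lapply(seq_along(cancers), function(i)
    c(ff[i], ff[i], ff[i] + diffs[i], ff[i] + diffs[i])))
  cf <- balancedClosedForm(y, d)
  expect_equal(cf$sigma_e2, 0)
  expect_equal(unname(cf$beta["N"]), 0.3)
  expect_equal(unname(cf$tau2["N"]), var(diffs))
  expect_equal(cf$sigma_a2, var(ff))
  expect_equal(cf$intercept, mean(ff))

  d2 <- d[-1, ]
  expect_error(balancedClosedForm(y[-1], d2), "unbalanced")
})

test_that("REML fit is exact in the zero-noise limit", {
  cfg <- simulationConfig(nGenes = 5, nCancers = 12, nReferenceGenes = 0,
                          sigmaCancer = 0, slopeSd = 0, replicateSd = 0,
                          kitBiasMean = c(N = 0.3, Q = -0.2, R = 0.5),
                          kitBiasSd = 0, seed = 2)
  ke <- simulateStudy(cfg)
  d <- studyDesign(ke)
  for (g in 1:3) {
    f <- fitLmeSingle(assay(ke)[g, ], d)
    expect_lt(max(abs(f$beta - c(N = 0.3, Q = -0.2, R = 0.5))), 1e-8)
    expect_lt(max(f$sigma_a2, f$tau2, f$sigma_e2), 1e-8)
    expect_true(f$converged)
  }
})

test_that("fixed-kit bias equals the classical paired estimate in a single-kit design", {
  set.seed(14)
  cancers <- sprintf("C%d", 1:8)
  d <- expand.grid(replicate = 1:2, condition = c("FF", "N"),
                   cancer_id = cancers, stringsAsFactors = FALSE)
  d$condition <- factor(d$condition, levels = c("FF", "N"))
  d$sample_id <- sprintf("s%d", seq_len(nrow(d)))
  slope <- rep(rnorm(8, sd = 0.5), each = 4) * (d$condition == "N")
  y <- rnorm(nrow(d), sd = 0.3) + 2 +
    0.4 * (d$condition == "N") + rep(rnorm(8), each = 4) + slope
  f <- fitLmeSingle(y, d)
  cm <- tapply(y, list(d$cancer_id, d$condition), mean)
  expect_equal(unname(f$beta["N"]), mean(cm[, "N"] - cm[, "FF"]),
               tolerance = 1e-6)
  # residual variance sits at the within-cell mean square (moment level;
  # REML shifts it slightly because the slope stratum shares information)
  cellmean <- ave(y, paste(d$cancer_id, d$condition))
  expect_equal(f$sigma_e2, sum((y - cellmean)^2) / 16, tolerance = 0.02)
})

test_that("REML matches lme4 on simulated genes", {
  skip_if_not_installed("lme4")
  ke <- simulateStudy(simulationConfig(nGenes = 12, nCancers = 12,
                                       nReferenceGenes = 0, seed = 9))
  d <- studyDesign(ke)
  offsets <- numeric(4)
  for (g in 1:4) {
    y <- assay(ke)[g, ]
    f <- fitLmeSingle(y, d)
    df <- data.frame(y = y, kit = d$condition, cancer = d$cancer_id)
    for (k in c("N", "Q", "R"))
      df[[paste0("d", k)]] <- as.numeric(df$kit == k)
    fm <- lme4::lmer(
      y ~ kit + (1 | cancer) + (0 + dN | cancer) + (0 + dQ | cancer) +
        (0 + dR | cancer),
      data = df, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))
    expect_equal(unname(f$beta), unname(lme4::fixef(fm)[-1]),
                 tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(fm))
    expect_equal(unname(c(f$sigma_a2, f$tau2)),
                 vc$vcov[1:4], tolerance = 1e-3)
    expect_equal(f$sigma_e2, lme4::getME(fm, "sigma")^2, tolerance = 1e-3)
    offsets[g] <- lme4::REMLcrit(fm) - f$m2reml
  }
  # criteria agree up to one design-dependent constant
  expect_lt(diff(range(offsets)), 1e-3)
})

test_that("the optimum never sits above the moment start (descent)", {
  ke <- simulateStudy(simulationConfig(nGenes = 12, nCancers = 12,
                                       nReferenceGenes = 0, seed = 17))
  d <- studyDesign(ke)
  for (g in 1:10) {
    f <- fitLmeSingle(assay(ke)[g, ], d)
    expect_lte(f$m2reml, f$crit_start + 1e-9)
  }
})

test_that("estimates are invariant to cancer relabeling and location shift", {
  ke <- simulateStudy(simulationConfig(nGenes = 12, nCancers = 8,
                                       nReferenceGenes = 0, seed = 23))
  d <- studyDesign(ke)
  y <- assay(ke)[1, ]
  f1 <- fitLmeSingle(y, d)
  d2 <- d
  perm <- setNames(sample(unique(d$cancer_id)), unique(d$cancer_id))
  d2$cancer_id <- unname(perm[d$cancer_id])
  f2 <- fitLmeSingle(y, d2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$m2reml, f2$m2reml, tolerance = 1e-6)
  f3 <- fitLmeSingle(y + 5, d)
  expect_equal(f3$intercept, f1$intercept + 5, tolerance = 1e-6)
  expect_equal(f3$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f3$sigma_e2, f1$sigma_e2, tolerance = 1e-6)
})

test_that("moment and REML estimates agree on a large balanced simulation", {
  cfg <- simulationConfig(nGenes = 60, nCancers = 12, nReferenceGenes = 0,
                          kitBiasMean = 0.25, kitBiasSd = 0,
                          slopeSd = 0.3, replicateSd = 0.2, seed = 37)
  ke <- simulateStudy(cfg)
  d <- studyDesign(ke)
  x <- assay(ke)
  rem <- mom <- matrix(0, nrow(x), 2)
  for (g in seq_len(nrow(x))) {
    f <- fitLmeSingle(x[g, ], d)
    cf <- balancedClosedForm(x[g, ], d)
    rem[g, ] <- c(f$beta["N"], f$sigma_e2)
    mom[g, ] <- c(cf$beta["N"], cf$sigma_e2)
  }
  expect_equal(colMeans(rem), colMeans(mom), tolerance = 0.02)
})

test_that("full slope-covariance structure fits and nests the diagonal", {
  ke <- simulateStudy(simulationConfig(nGenes = 12, nCancers = 12,
                                       nReferenceGenes = 0, seed = 41))
  d <- studyDesign(ke)
  y <- assay(ke)[1, ]
  fd <- fitLmeSingle(y, d, structure = "diagonal")
  ff <- fitLmeSingle(y, d, structure = "full")
  expect_true(all(eigen(ff$Lambda)$values > -1e-8))
  # richer covariance cannot fit worse than its diagonal special case
  expect_lte(ff$m2reml, fd$m2reml + 0.05)
  expect_equal(unname(ff$beta), unname(fd$beta), tolerance = 0.1)
})

test_that("fitLmeAll summarizes per-kit bias and variance", {
  cfg <- simulationConfig(nGenes = 40, nCancers = 12, nReferenceGenes = 0,
                          kitBiasMean = c(N = 0.5, Q = 0, R = -0.5),
                          kitBiasSd = 0, slopeSd = 0.2,
                          replicateSd = 0.15, seed = 51)
  fit <- fitLmeAll(simulateStudy(cfg))
  expect_identical(nrow(fit$results), 40L)
  expect_gt(fit$convergence_rate, 0.9)
  s <- fit$summary
  expect_lt(abs(s$median_bias[s$kit == "N"] - 0.5), 0.15)
  expect_lt(abs(s$median_bias[s$kit == "R"] + 0.5), 0.15)
  expect_error(fitLmeAll(simulateStudy(cfg), maxNonConvergent = -1),
               "converge")
})
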