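test_that("scoreSignature is a two-set mean difference on log2 values", {
  vals <- matrix(c(3, 5, 2, 2), 4, 1)
  ke <- makeKe(vals, "C1", "FF", scale = "log2",
               genes = c("a", "b", "r1", "r2"))
  sig <- geneSignature("toy", c("a", "b"), c("r1", "r2"))
  expect_equal(unname(scoreSignature(ke, sig)), 2)   # 4 - 2

  # informative mean equal to reference mean scores 0
  ke0 <- makeKe(matrix(c(2, 2, 1, 3), 4, 1), "C1", "FF", scale = "log2",
                genes = c("a", "b", "r1", "r2"))
  expect_equal(unname(scoreSignature(ke0, sig)), 0)

  # per-sample shift invariance
  ke2 <- makeKe(vals + 4.2, "C1", "FF", scale = "log2",
                genes = c("a", "b", "r1", "r2"))
  expect_equal(scoreSignature(ke2, sig), scoreSignature(ke, sig))

  # weights tilt the informative mean
  wsig <- geneSignature("w", c("a", "b"), c("r1", "r2"),
                        weights = c(a = 3, b = 1))
  expect_equal(unname(scoreSignature(ke, wsig)), (3 * 3 + 5) / 4 - 2)

  expect_error(scoreSignature(ke, geneSignature("x", c("a", "zz"))), "zz")
  expect_warning(s <- scoreSignature(ke, geneSignature("x", c("a", "zz")),
                                     missing = "drop"), "dropped")
  expect_equal(unname(s), 3)
})

test_that("signatureConcordance reuses Lin's CCC across cancers", {
  d <- data.frame(sample_id = paste0("s", 1:6),
                  cancer_id = rep(c("C1", "C2", "C3"), each = 2),
                  condition = factor(rep(c("FF", "N"), 3),
                                     levels = c("FF", "N")),
                  replicate = 1L)
  scores <- setNames(c(0, 1, 1, 2, 2, 3), d$sample_id)
  sc <- signatureConcordance(scores, d)
  expect_equal(sc$ccc, 4 / 7)
  expect_equal(sc$pearson_r, 1)

  same <- setNames(c(0, 0, 1, 1, 2, 2), d$sample_id)
  expect_equal(signatureConcordance(same, d)$ccc, 1)
  flat <- setNames(rep(1, 6), d$sample_id)
  expect_false(signatureConcordance(flat, d)$defined)
})

test_that("random-signature null is deterministic and percentile-correct", {
  ke <- smallStudy(nGenes = 120, seed = 61, nReferenceGenes = 4)
  tg <- syntheticTruth(ke)$genes
  sig <- geneSignature("s", tg$gene_id[!tg$is_reference][1:8],
                       tg$gene_id[tg$is_reference])
  n1 <- randomSignatureNull(ke, sig, kit = "N", B = 60, nBins = 5,
                            seed = 99)
  n2 <- randomSignatureNull(ke, sig, kit = "N", B = 60, nBins = 5,
                            seed = 99)
  expect_identical(n1$draws, n2$draws)
  expect_identical(n1$percentile, n2$percentile)
  expect_equal(n1$percentile, 100 * mean(n1$draws < n1$observed))

  # percentile is invariant to a strictly monotone transform of the statistic
  expect_equal(100 * mean(tanh(n1$draws) < tanh(n1$observed)),
               n1$percentile)

  # observed above every draw -> percentile 100
  fake <- n1; fake$observed <- max(n1$draws) + 1
  expect_equal(100 * mean(fake$draws < fake$observed), 100)

  smallU <- ke[seq_len(8), ]
  expect_error(randomSignatureNull(smallU, sig, kit = "N", B = 10,
                                   nBins = 2, seed = 1), "universe")
})

test_that("a concordant signature outranks a noisy low-expression one", {
  # informative genes with strong tumor signal and low kit bias score high;
  # genes that are pure replicate noise score low
  set.seed(3)
  nG <- 160
  cancers <- sprintf("C%02d", 1:12)
  d <- expand.grid(replicate = 1:2, condition = c("FF", "N"),
                   cancer_id = cancers, stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_r%d", d$cancer_id, d$condition, d$replicate)
  x <- matrix(rnorm(nG * nrow(d), sd = 0.35), nG, nrow(d),
              dimnames = list(sprintf("g%03d", 1:nG), d$sample_id))
  tumor <- rnorm(12, sd = 1.5)
  good <- 1:10
  x[good, ] <- x[good, ] +
    matrix(rep(tumor[match(d$cancer_id, cancers)], each = 10), 10)
  bad <- 11:20
  x[bad, ] <- x[bad, ] + 3 * rnorm(length(bad) * nrow(d))  # noise-dominated
  ke <- KitExperiment(x, d, scale = "log2")
  sGood <- geneSignature("good", rownames(x)[good])
  sBad <- geneSignature("bad", rownames(x)[bad])
  nGood <- randomSignatureNull(ke, sGood, kit = "N", B = 150, nBins = 4,
                               seed = 7)
  nBad <- randomSignatureNull(ke, sBad, kit = "N", B = 150, nBins = 4,
                              seed = 7)
  expect_gt(nGood$percentile, nBad$percentile)
  expect_gt(nGood$percentile, 60)
})

test_that("replicate percent difference is range-normalized", {
  d <- data.frame(sample_id = paste0("s", 1:8),
                  cancer_id = rep(c("C1", "C2"), each = 4),
                  condition = factor(rep(c("FF", "FF", "N", "N"), 2),
                                     levels = c("FF", "N")),
                  replicate = rep(1:2, 4))
  # replicate-averaged scores span 0..10; C1 N replicates differ by 1
  scores <- setNames(c(0, 0, 4.5, 5.5, 10, 10, 3, 3), d$sample_id)
  rp <- replicatePercentDifference(scores, d)
  expect_equal(rp$score_range, 10)
  c1n <- rp$perCancer$percent_diff[rp$perCancer$cancer_id == "C1" &
                                     rp$perCancer$condition == "N"]
  expect_equal(c1n, 10)
  expect_equal(rp$summary$median_percent_diff[
    rp$summary$condition == "FF"], 0)
  # invariant to rescaling all scores
  rp2 <- replicatePercentDifference(scores * 2, d)
  expect_equal(rp2$perCancer$percent_diff, rp$perCancer$percent_diff)
  expect_error(replicatePercentDifference(setNames(rep(1, 8),
                                                   d$sample_id), d),
               "zero range")
})

test_that("bundled signatures carry the published gene counts", {
  ep <- bundledSignature("endopredict")
  expect_length(ep@informative, 8)
  expect_length(ep@reference, 3)
  rs <- bundledSignature("recurrence_score")
  expect_length(rs@informative, 16)
  expect_length(rs@reference, 5)
  set <- bundledSignature("set_erpr")
  expect_length(set@informative, 18)
  expect_length(set@reference, 10)
  expect_length(intersect(set@informative, set@reference), 0)
  expect_identical(referencePanel(), set@reference)
  expect_true(all(c("ESR1", "SCUBE2", "STC2") %in% set@informative))
})
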