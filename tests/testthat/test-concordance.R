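test_that("linCCC reproduces hand-computed examples", {
  r <- linCCC(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(r$ccc, r$pearson_r, r$bias_term), c(1, 1, 1))
  r <- linCCC(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$ccc, 4 / 7)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$bias_term, 4 / 7)
  r <- linCCC(c(1, 2, 3), c(3, 2, 1))
  expect_equal(c(r$ccc, r$pearson_r, r$bias_term), c(-1, -1, 1))
})

test_that("linCCC agrees with brute-force moment evaluation", {
  set.seed(77)
  for (i in 1:200) {
    x <- rnorm(12); y <- 0.8 * x + rnorm(12, sd = 0.5) + 0.3
    r <- linCCC(x, y)
    expect_equal(r$ccc, bruteCCC(x, y), tolerance = 1e-12)
    expect_equal(r$ccc, r$pearson_r * r$bias_term, tolerance = 1e-10)
    expect_lte(abs(r$ccc), abs(r$pearson_r) + 1e-12)
  }
})

test_that("degenerate inputs are flagged, not zeroed", {
  r <- linCCC(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_false(r$defined)
  expect_true(is.na(r$ccc))
  expect_error(linCCC(1:2, 1:2), "3 pairs")
  expect_error(linCCC(c(1, 2, NA), 1:3), "finite")
})

test_that("a location bias lowers CCC monotonically while r stays 1", {
  x <- c(-1, 0, 1, 2, 4)
  cccs <- vapply(c(0, 0.5, 1, 2), function(b) {
    r <- linCCC(x, x + b)
    expect_equal(r$pearson_r, 1)
    r$ccc
  }, numeric(1))
  expect_equal(cccs[1], 1)
  expect_true(all(diff(cccs) < 0))
})

test_that("concordanceTable pairs FF with the kit across cancers", {
  # identical arms -> ccc 1; one gene follows the 4/7 pattern
  vals <- rbind(gA = c(1, 1, 2, 2, 3, 3),         # FF == N per cancer
                gB = c(1, 2, 2, 3, 3, 4),         # N = FF + 1
                gC = rep(2, 6))                   # constant
  ke <- makeKe(vals, cancers = c("C1", "C2", "C3"),
               conditions = c("FF", "N"), scale = "normalized-log2",
               genes = rownames(vals))
  tb <- concordanceTable(ke, "N")
  expect_equal(tb$ccc[tb$gene_id == "gA"], 1)
  expect_equal(tb$ccc[tb$gene_id == "gB"], 4 / 7)
  expect_false(tb$defined[tb$gene_id == "gC"])
  expect_identical(tb$n_pairs, rep(3L, 3))
  expect_error(concordanceTable(ke, "FF"), "non-reference")
})

test_that("replicateDifference takes the per-cancer median of |delta|", {
  # one gene, 3 cancers x 2 reps in one condition beyond the reference
  vals <- matrix(c(0, 0,   0, 0.4,   0, 0,  0, 0.2,  0, 0,  0, 0.6),
                 nrow = 1)
  ke <- makeKe(vals, cancers = c("C1", "C2", "C3"),
               conditions = c("FF", "N"), replicates = 2, scale = "log2")
  rd <- replicateDifference(ke)
  expect_equal(unname(rd$perGene[1, "N"]), 0.4)   # median(0.4, 0.2, 0.6)
  expect_equal(unname(rd$perGene[1, "FF"]), 0)
  expect_equal(rd$summary$median[rd$summary$condition == "N"], 0.4)

  single <- makeKe(matrix(1:2, 1, 2), "C1", c("FF", "N"), scale = "log2")
  expect_false(any(replicateDifference(single)$summary$available))
})

test_that("high-concordant overlap is intersection over union", {
  mk <- function(ids, inSet) {
    data.frame(gene_id = ids, ccc = ifelse(inSet, 0.9, 0.1),
               pearson_r = 0.9, bias_term = 1,
               mean_ff = 0, mean_kit = 0, n_pairs = 3, defined = TRUE)
  }
  ids <- c("g1", "g2", "g3", "g4")
  tabs <- list(A = mk(ids, c(TRUE, TRUE, TRUE, FALSE)),
               B = mk(ids, c(TRUE, TRUE, FALSE, FALSE)),
               C = mk(ids, c(TRUE, TRUE, FALSE, TRUE)))
  ov <- highConcordantOverlap(tabs)
  expect_equal(ov$percentShared, 50)                 # {g1,g2} / {g1..g4}
  same <- highConcordantOverlap(tabs[c(2, 2)])
  expect_equal(same$percentShared, 100)
  disj <- highConcordantOverlap(list(mk(ids, c(TRUE, FALSE, FALSE, FALSE)),
                                     mk(ids, c(FALSE, TRUE, FALSE, FALSE))))
  expect_equal(disj$percentShared, 0)
  none <- highConcordantOverlap(list(mk(ids, rep(FALSE, 4))))
  expect_true(is.na(none$percentShared))
  # the expression filter removes low-expressed genes from the sets
  lowexpr <- mk(ids, rep(TRUE, 4)); lowexpr$mean_ff <- -20
  lowexpr$mean_kit <- -20
  expect_true(is.na(highConcordantOverlap(list(lowexpr))$percentShared))
})

test_that("summarizeByGroup gives per-label medians and logs strays", {
  tb <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                   ccc = c(0.2, 0.4, 0.6, 0.9, 0.5),
                   defined = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  groups <- c(g1 = "A", g2 = "A", g3 = "A", g4 = "B", gX = "C")
  s <- summarizeByGroup(tb, groups)
  expect_equal(s$median_ccc[s$group == "A"], 0.4)
  expect_equal(s$median_ccc[s$group == "B"], 0.9)
  expect_identical(attr(s, "n_unknown_ids"), 1L)
  expect_identical(attr(s, "n_ungrouped"), 1L)   # g5 carries no label
  one <- summarizeByGroup(tb, setNames(rep("all", 5), tb$gene_id))
  expect_equal(one$median_ccc, median(tb$ccc))
})

test_that("blandAltman returns bias and limits of agreement", {
  expect_equal(unlist(blandAltman(1:3, 1:3)), c(bias = 0, loa_lower = 0,
                                                loa_upper = 0))
  ba <- blandAltman(c(1, 2, 3), c(2, 3, 4))
  expect_equal(unlist(ba), c(bias = 1, loa_lower = 1, loa_upper = 1))
  ba <- blandAltman(c(0, 0, 0), c(-1, 0, 1))   # d has sd 1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
  expect_error(blandAltman(1, 2), "2 pairs")
})

test_that("CCC of kit pairs simulated alike correlates across kits", {
  ke <- smallStudy(nGenes = 400, seed = 31)
  refs <- syntheticTruth(ke)$genes$gene_id[
    syntheticTruth(ke)$genes$is_reference]
  avg <- averageReplicates(logNormalize(ke, refs))
  tn <- concordanceTable(avg, "N")
  tq <- concordanceTable(avg, "Q")
  rs <- cor(tn$ccc, tq$ccc, method = "spearman", use = "complete.obs")
  expect_gt(rs, 0)
})
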