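suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# small KitExperiment from a matrix and a compact design description
makeKe <- function(values, cancers, conditions, replicates = 1L,
                   scale = "log2", reference = "FF",
                   genes = sprintf("g%d", seq_len(nrow(values)))) {
  design <- expand.grid(replicate = seq_len(replicates),
                        condition = conditions, cancer_id = cancers,
                        stringsAsFactors = FALSE)
  design <- design[, c("cancer_id", "condition", "replicate")]
  design$sample_id <- sprintf("%s_%s_r%d", design$cancer_id,
                              design$condition, design$replicate)
  values <- matrix(values, nrow = length(genes),
                   dimnames = list(genes, design$sample_id))
  KitExperiment(values, design, scale = scale, reference = reference)
}

# independent brute-force evaluation of Lin's moment formula
bruteCCC <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# literal BH step-up: sorted p_(i) -> min_{j >= i} m p_(j) / j, capped at 1
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min((m / (i:m)) * ps[i:m]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact two-sided Mann-Whitney p by enumeration of all labelings
enumMWp <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  labs <- utils::combn(n + m, n)
  Uall <- apply(labs, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  Uobs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  min(1, 2 * min(mean(Uall <= Uobs), mean(Uall >= Uobs)))
}

# study-shaped simulation at reduced gene count
smallStudy <- function(nGenes = 100, seed = 1, ...) {
  simulateStudy(simulationConfig(nGenes = nGenes, seed = seed, ...))
}
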