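#' Read a gene x sample expression matrix
#'
#' Tab-separated text, UTF-8, '.' decimal: first column gene ids, header
#' row of sample ids. Ragged rows, non-numeric or missing cells and
#' duplicated ids are rejected with the offending line/column named.
#'
#' @param path file path.
#' @param scale declared scale of the values (\code{"counts"},
#'   \code{"log2"} or \code{"normalized-log2"}).
#' @return numeric matrix with a \code{"scale"} attribute; combine with a
#'   design via \code{\link{KitExperiment}}.
#' @export
readExpressionMatrix <- function(path, scale = c("counts", "log2",
                                                 "normalized-log2")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  samples <- hdr[-1]
  if (length(samples) < 1L) stop("header row has no sample ids")
  if (anyDuplicated(samples))
    stop("duplicated sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  nf <- lengths(fields[-1])
  bad <- which(nf != length(hdr))
  if (length(bad))
    stop(sprintf("line %d has %d fields, expected %d", bad[1] + 1L,
                 nf[bad[1]], length(hdr)))
  genes <- vapply(fields[-1], `[[`, character(1), 1)
  if (anyDuplicated(genes))
    stop("duplicated gene id: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(fields[-1], function(f) as.numeric(f[-1]),
           numeric(length(samples))))
  vals <- if (length(samples) == 1L) matrix(vals, nrow = 1L) else t(vals)
  if (anyNA(vals)) {
    w <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at gene '%s' (line %d), sample '%s'",
                 genes[w[1]], w[1] + 1L, samples[w[2]]))
  }
  dimnames(vals) <- list(genes, samples)
  attr(vals, "scale") <- scale
  vals
}

#' Write an expression matrix as TSV
#'
#' @param x a \linkS4class{KitExperiment} or a matrix with dimnames.
#' @param path output file.
#' @param geneCol header name of the gene-id column.
#' @export
writeExpressionMatrix <- function(x, path, geneCol = "gene_id") {
  if (is(x, "KitExperiment")) x <- assay(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- geneCol
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a study design table
#'
#' TSV with columns \code{sample_id}, \code{cancer_id}, \code{condition},
#' \code{replicate}. Duplicated (cancer, condition, replicate) rows and a
#' missing reference condition are errors; an unbalanced design is reported
#' with a message.
#'
#' @param path file path.
#' @param reference reference condition label that must be present.
#' @return validated design data.frame.
#' @export
readDesign <- function(path, reference = "FF") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cancer_id", "condition", "replicate")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("design file lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(d$cancer_id, d$condition, d$replicate)
  if (anyDuplicated(key))
    stop("duplicated (cancer, condition, replicate): ",
         key[duplicated(key)][1])
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample_id: ", d$sample_id[duplicated(d$sample_id)][1])
  if (!reference %in% d$condition)
    stop("reference condition '", reference, "' absent from design")
  d$replicate <- as.integer(d$replicate)
  tab <- table(d$cancer_id, d$condition)
  message(sprintf("design: %d cancers x %d conditions (%s)%s",
                  nrow(tab), ncol(tab),
                  paste(colnames(tab), collapse = ", "),
                  if (any(tab == 0L)) " [unbalanced]" else ""))
  d
}

#' @rdname readDesign
#' @param design design data.frame.
#' @param path output file.
#' @export
writeDesign <- function(design, path) {
  utils::write.table(design[, c("sample_id", "cancer_id", "condition",
                                "replicate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature gene-list file
#'
#' Either a two-column TSV (\code{gene_id}, \code{role}) with roles
#' \code{informative} / \code{reference}, or a plain list of one gene id per
#' line (all informative). A gene listed in both roles is an error.
#'
#' @param path file path.
#' @param name signature name (default: file name without extension).
#' @return a \linkS4class{GeneSignature}.
#' @export
readSignature <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(first) >= 2L) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "role") %in% colnames(d)))
      stop("two-column signature file needs 'gene_id' and 'role' columns")
    bad <- setdiff(unique(d$role), c("informative", "reference"))
    if (length(bad))
      stop("unknown role(s): ", paste(bad, collapse = ", "))
    geneSignature(name, d$gene_id[d$role == "informative"],
                  d$gene_id[d$role == "reference"])
  } else {
    ids <- readLines(path)
    ids <- ids[nzchar(trimws(ids))]
    geneSignature(name, trimws(ids))
  }
}

#' @rdname readSignature
#' @param sig a \linkS4class{GeneSignature}.
#' @export
writeSignature <- function(sig, path) {
  df <- data.frame(gene_id = c(sig@informative, sig@reference),
                   role = c(rep("informative", length(sig@informative)),
                            rep("reference", length(sig@reference))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
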