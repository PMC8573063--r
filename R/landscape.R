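# Mutational-landscape views of the matrix: the gene x cancer-type
# submatrix, the per-gene literature frequency vector, and the
# cosine-similarity validation against an external clinical frequency
# vector. Year-sliced matrices come from filterByYear() + the full
# pipeline.

#' Gene x cancer-type association submatrix
#'
#' Restricts the matrix to its cancer-category columns; when a descriptor
#' -> display-type mapping is supplied, descriptor columns sharing a type
#' are aggregated by elementwise sum (of counts and scores). The operation
#' is a projection: applying it twice equals applying it once.
#'
#' @param gtm a [GeneTermMatrix-class] with TF-IDF scores built.
#' @param cancerMap optional named character vector, descriptor id ->
#'   display cancer-type name; unmapped cancer columns keep their own id.
#' @return a [GeneTermMatrix-class] whose columns are all cancer-category.
#' @export
geneCancerMatrix <- function(gtm, cancerMap = NULL) {
  stopifnot(is(gtm, "GeneTermMatrix"))
  sel <- featureCategories(gtm) == "cancer"
  if (!any(sel)) stop("matrix has no cancer-category features")
  counts <- gtm@counts[, sel, drop = FALSE]
  scores <- if (is.null(gtm@scores)) NULL else gtm@scores[, sel, drop = FALSE]
  ids <- colnames(counts)
  if (!is.null(cancerMap)) {
    type <- ifelse(ids %in% names(cancerMap), cancerMap[ids], ids)
    if (anyDuplicated(type)) {
      agg <- function(m) {
        g <- factor(type, levels = sort(unique(type)))
        out <- m %*% Matrix::sparseMatrix(
          i = seq_along(type), j = as.integer(g), x = 1,
          dims = c(length(type), nlevels(g)))
        colnames(out) <- levels(g)
        as(out, "CsparseMatrix")
      }
      counts <- agg(counts)
      if (!is.null(scores)) scores <- agg(scores)
      ids <- colnames(counts)
    } else {
      colnames(counts) <- type
      if (!is.null(scores)) colnames(scores) <- type
      ids <- type
    }
  }
  ord <- order(ids)
  counts <- counts[, ord, drop = FALSE]
  if (!is.null(scores)) scores <- scores[, ord, drop = FALSE]
  cats <- rep("cancer", length(ids))
  names(cats) <- ids[ord]
  new("GeneTermMatrix", counts = as(counts, "generalMatrix"),
      scores = if (is.null(scores)) NULL else as(scores, "generalMatrix"),
      featureCategories = cats)
}

#' Per-gene literature frequency over cancer types
#'
#' The text-mining analogue of a clinical mutation-frequency vector: each
#' gene's TF-IDF row sum over the cancer columns, normalized so the vector
#' sums to 1 across genes.
#'
#' @param gcm gene x cancer matrix from [geneCancerMatrix()] (scores
#'   built).
#' @return named non-negative numeric vector summing to 1.
#' @export
geneFrequency <- function(gcm) {
  stopifnot(is(gcm, "GeneTermMatrix"))
  rs <- Matrix::rowSums(tfidfScores(gcm))
  tot <- sum(rs)
  if (tot == 0) stop("all-zero gene-cancer matrix")
  rs / tot
}

#' Cosine similarity of two non-negative gene frequency vectors
#'
#' Vectors are aligned on the union of their gene ids, with genes present
#' in only one vector contributing 0 in the other; the result is
#' `u . v / (||u|| ||v||)`, symmetric and invariant to positive scaling.
#'
#' @param u,v named non-negative numeric vectors.
#' @return similarity in [0, 1].
#' @export
cosineSimilarity <- function(u, v) {
  stopifnot(!is.null(names(u)), !is.null(names(v)))
  ids <- union(names(u), names(v))
  ua <- ifelse(ids %in% names(u), u[ids], 0)
  va <- ifelse(ids %in% names(v), v[ids], 0)
  nu <- sqrt(sum(ua^2))
  nv <- sqrt(sum(va^2))
  if (nu == 0 || nv == 0) stop("zero-norm input vector")
  sum(ua * va) / (nu * nv)
}

#' Read an external clinical gene-frequency vector
#'
#' Tab-separated with header columns `gene_id` and `frequency`.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
readClinicalFrequency <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("gene_id", "frequency") %in% names(tab)))
    stop("clinical frequency table must have columns gene_id, frequency")
  out <- as.numeric(tab$frequency)
  names(out) <- as.character(tab$gene_id)
  out
}

#' Export landscape tables as TSV
#'
#' Writes `heatmap.tsv` (long table `gene`, `cancer_type`, `score`,
#' suitable for any plotting layer) and `gene_frequency.tsv` (`gene_id`,
#' `frequency`).
#'
#' @param gcm gene x cancer matrix from [geneCancerMatrix()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeLandscape <- function(gcm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- tfidfScores(gcm)
  tm <- Matrix::summary(s)
  long <- data.frame(gene = rownames(s)[tm$i], cancer_type = colnames(s)[tm$j],
                     score = sprintf("%.10g", tm$x), stringsAsFactors = FALSE)
  long <- long[order(long$gene, long$cancer_type), , drop = FALSE]
  utils::write.table(long, file.path(dir, "heatmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  freq <- geneFrequency(gcm)
  utils::write.table(
    data.frame(gene_id = names(freq), frequency = sprintf("%.10g", freq)),
    file.path(dir, "gene_frequency.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
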