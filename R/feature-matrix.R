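# The gene x term-feature matrix: raw window co-occurrence counts, the
# TF-IDF weighting TF = log(1 + tf), IDF = log(1 + n_gene / df), and the
# minimum-feature gene filter.

#' Count gene/feature co-occurrence over all windows
#'
#' `counts[g, t]` is the total multiplicity of feature `t` over all windows
#' of gene `g` in the corpus. Rows and columns are ordered
#' lexicographically by identifier so serialization is deterministic and
#' independent of corpus order.
#'
#' @param windows result of [collectWindows()].
#' @return a [GeneTermMatrix-class] with counts only (no scores yet).
#' @export
countCooccurrence <- function(windows) {
  f <- windows$features
  if (is.null(f) || nrow(f) == 0L) stop("no gene windows with features")
  agg <- data.table::as.data.table(f)[, list(count = sum(count)),
                                      by = c("geneId", "featureId", "category")]
  if (anyDuplicated(agg[, c("geneId", "featureId")]))
    stop("a feature id maps to more than one category")
  genes <- sort(unique(agg$geneId))
  feats <- sort(unique(agg$featureId))
  m <- Matrix::sparseMatrix(
    i = match(agg$geneId, genes), j = match(agg$featureId, feats),
    x = as.numeric(agg$count), dims = c(length(genes), length(feats)),
    dimnames = list(genes, feats))
  catMap <- agg$category[match(feats, agg$featureId)]
  names(catMap) <- feats
  new("GeneTermMatrix", counts = m, scores = NULL, featureCategories = catMap)
}

#' Term-frequency score: log(1 + tf)
#'
#' Natural-log sublinear term frequency; 0 exactly when `tf = 0`, strictly
#' increasing in `tf`.
#'
#' @param tf non-negative count (vectorized).
#' @return numeric vector of TF scores.
#' @export
tfScore <- function(tf) {
  if (any(!is.finite(tf)) || any(tf < 0)) stop("tf must be non-negative")
  log1p(tf)
}

#' Inverse-document-frequency score: log(1 + n_gene / df)
#'
#' Strictly decreasing in `df` at fixed `nGene`; its minimum, `log 2`, is
#' attained when the feature occurs in every gene (`df = nGene`).
#'
#' @param nGene number of gene rows in the matrix.
#' @param df per-feature document frequency (number of genes with a
#'   positive count), `1 <= df <= nGene` (vectorized).
#' @return numeric vector of IDF scores.
#' @export
idfScore <- function(nGene, df) {
  if (any(df < 1) || any(df > nGene))
    stop("df must satisfy 1 <= df <= nGene (a feature absent from all genes cannot be scored)")
  log1p(nGene / df)
}

#' Fill the TF-IDF scores of a count matrix
#'
#' `scores[g, t] = log(1 + counts[g, t]) * log(1 + n_gene / df_t)`; the
#' sparsity pattern of the counts is preserved exactly.
#'
#' @param gtm a [GeneTermMatrix-class] with counts.
#' @return the matrix with the `scores` slot filled.
#' @export
buildTfidf <- function(gtm) {
  stopifnot(is(gtm, "GeneTermMatrix"))
  m <- gtm@counts
  df <- diff(m@p)
  if (any(df == 0L))
    stop("feature(s) with zero document frequency; filter them out first")
  idf <- idfScore(nrow(m), df)
  s <- m
  s@x <- tfScore(m@x) * rep.int(idf, df)
  gtm@scores <- s
  validObject(gtm)
  gtm
}

#' Remove genes with fewer than k distinct term features
#'
#' Drops gene rows having fewer than `k` nonzero columns, then drops
#' features left with zero document frequency; `n_gene` and `df` are
#' recomputed and, when scores were present, the TF-IDF is rebuilt on the
#' reduced matrix so it stays self-consistent.
#'
#' @param gtm a [GeneTermMatrix-class].
#' @param k minimum number of distinct features per retained gene
#'   (default 10).
#' @return the filtered [GeneTermMatrix-class].
#' @export
filterMinFeatures <- function(gtm, k = 10) {
  stopifnot(is(gtm, "GeneTermMatrix"), k >= 0)
  m <- gtm@counts
  nFeat <- Matrix::rowSums(m > 0)
  keep <- nFeat >= k
  if (!any(keep)) stop("min-feature filter removed every gene (k = ", k, ")")
  m2 <- m[keep, , drop = FALSE]
  colKeep <- diff(m2@p) > 0L
  m2 <- m2[, colKeep, drop = FALSE]
  out <- new("GeneTermMatrix", counts = m2, scores = NULL,
             featureCategories = gtm@featureCategories[colKeep])
  if (!is.null(gtm@scores)) out <- buildTfidf(out)
  out
}

#' Subset a GeneTermMatrix by feature columns
#'
#' Keeps the listed features (and all genes); scores are carried over
#' unchanged since `n_gene` and per-feature `df` are unaffected by a column
#' subset.
#'
#' @param gtm a [GeneTermMatrix-class].
#' @param features character vector of feature ids to keep.
#' @return the column-subset matrix.
#' @export
subsetFeatures <- function(gtm, features) {
  sel <- colnames(gtm@counts) %in% features
  if (!any(sel)) stop("no matching features")
  new("GeneTermMatrix",
      counts = gtm@counts[, sel, drop = FALSE],
      scores = if (is.null(gtm@scores)) NULL else gtm@scores[, sel, drop = FALSE],
      featureCategories = gtm@featureCategories[sel])
}

#' Serialize a GeneTermMatrix as MatrixMarket plus sidecar TSVs
#'
#' Writes `counts.mtx` (and `scores.mtx` when built) in MatrixMarket
#' coordinate format, `genes.tsv` (row gene ids), and `features.tsv`
#' (column `feature_id`, `category`).
#'
#' @param gtm a [GeneTermMatrix-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [readGeneTermMatrix()]
#' @export
writeGeneTermMatrix <- function(gtm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(gtm@counts, file.path(dir, "counts.mtx"))
  if (!is.null(gtm@scores))
    Matrix::writeMM(gtm@scores, file.path(dir, "scores.mtx"))
  writeLines(rownames(gtm@counts), file.path(dir, "genes.tsv"), useBytes = TRUE)
  utils::write.table(
    data.frame(feature_id = colnames(gtm@counts),
               category = unname(gtm@featureCategories)),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a GeneTermMatrix written by [writeGeneTermMatrix()]
#'
#' @param dir directory holding `counts.mtx`, `genes.tsv`, `features.tsv`,
#'   and optionally `scores.mtx`.
#' @return a [GeneTermMatrix-class].
#' @export
readGeneTermMatrix <- function(dir) {
  genes <- readLines(file.path(dir, "genes.tsv"), encoding = "UTF-8")
  feats <- utils::read.delim(file.path(dir, "features.tsv"),
                             stringsAsFactors = FALSE, quote = "")
  m <- as(as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix"),
          "generalMatrix")
  dimnames(m) <- list(genes, feats$feature_id)
  sPath <- file.path(dir, "scores.mtx")
  s <- NULL
  if (file.exists(sPath)) {
    s <- as(as(Matrix::readMM(sPath), "CsparseMatrix"), "generalMatrix")
    dimnames(s) <- dimnames(m)
  }
  cats <- feats$category
  names(cats) <- feats$feature_id
  new("GeneTermMatrix", counts = m, scores = s, featureCategories = cats)
}
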