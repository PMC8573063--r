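#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t rowSums colSums readMM writeMM
#' @importClassesFrom Matrix dgCMatrix
NULL

setClassUnion("dgCMatrixOrNULL", c("dgCMatrix", "NULL"))

#' AnnotatedAbstract: one document with sentence spans and entity annotations
#'
#' Represents a single abstract in the PubTator exchange dialect: a title,
#' an abstract body, an optional publication year, sentence spans over the
#' concatenated text (`title`, one space, `abstract`), and a table of entity
#' annotations. All offsets are 0-based, half-open, over that concatenation.
#'
#' @slot docId document identifier (PMID-like string).
#' @slot title title text.
#' @slot abstract abstract text.
#' @slot year integer publication year, `NA` if absent.
#' @slot sentences `data.frame` with integer columns `start`, `end`
#'   (0-based half-open intervals, sorted and non-overlapping, jointly
#'   covering all non-whitespace text).
#' @slot annotations `data.frame` with columns `start`, `end` (integer),
#'   `mention`, `etype`, `conceptId` (character). `mention` always equals
#'   the text slice at its offsets.
#'
#' @seealso [readPubtator()], [splitSentences()]
#' @exportClass AnnotatedAbstract
setClass("AnnotatedAbstract",
  representation(
    docId = "character",
    title = "character",
    abstract = "character",
    year = "integer",
    sentences = "data.frame",
    annotations = "data.frame"
  )
)

.emptyAnnotations <- function() {
  data.frame(start = integer(), end = integer(), mention = character(),
             etype = character(), conceptId = character(),
             stringsAsFactors = FALSE)
}

.emptySentences <- function() {
  data.frame(start = integer(), end = integer())
}

setValidity("AnnotatedAbstract", function(object) {
  msg <- character()
  if (length(object@docId) != 1L || !nzchar(object@docId))
    msg <- c(msg, "docId must be a single non-empty string")
  txt <- abstractText(object)
  s <- object@sentences
  if (nrow(s)) {
    if (is.unsorted(s$start)) msg <- c(msg, "sentence intervals must be sorted")
    if (any(s$end <= s$start)) msg <- c(msg, "sentence intervals must be non-empty")
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      msg <- c(msg, "sentence intervals must be non-overlapping")
    if (any(s$end > nchar(txt)))
      msg <- c(msg, "sentence interval exceeds text bounds")
  }
  a <- object@annotations
  if (nrow(a)) {
    if (any(a$end <= a$start)) msg <- c(msg, "annotation spans must satisfy end > start")
    if (any(a$start < 0L) || any(a$end > nchar(txt)))
      msg <- c(msg, "annotation span outside text bounds")
    slice <- substring(txt, a$start + 1L, a$end)
    if (any(slice != a$mention))
      msg <- c(msg, "annotation mention must equal the text slice at its offsets")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn AnnotatedAbstract full document text: title + space + abstract.
#' @param x,object an `AnnotatedAbstract`.
#' @export
abstractText <- function(x) {
  stopifnot(is(x, "AnnotatedAbstract"))
  if (nzchar(x@abstract)) paste(x@title, x@abstract) else x@title
}

#' @describeIn AnnotatedAbstract `TRUE` if the document has at least one
#'   Gene-typed annotation.
#' @export
hasGeneAnnotation <- function(x) {
  stopifnot(is(x, "AnnotatedAbstract"))
  any(x@annotations$etype == "Gene")
}

setMethod("show", "AnnotatedAbstract", function(object) {
  cat("AnnotatedAbstract", object@docId,
      sprintf("(%d sentences, %d annotations%s)\n",
              nrow(object@sentences), nrow(object@annotations),
              if (is.na(object@year)) "" else paste0(", year ", object@year)))
})

#' GenePanel: a named set of gene identifiers
#'
#' A curated set of genes sequenced together in a clinical assay
#' (e.g. MSK-IMPACT with 410 genes, Oncomine Comprehensive Assay with 161).
#' Genes are keyed by normalized concept identifier, not surface mention.
#'
#' @slot name panel name.
#' @slot genes unique, non-empty character vector of gene identifiers.
#' @seealso [readPanel()]
#' @exportClass GenePanel
setClass("GenePanel",
  representation(name = "character", genes = "character")
)

setValidity("GenePanel", function(object) {
  msg <- character()
  if (length(object@genes) == 0L) msg <- c(msg, "panel must be non-empty")
  if (anyDuplicated(object@genes)) msg <- c(msg, "gene identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GenePanel
#' @param name panel name.
#' @param genes character vector of gene identifiers (deduplicated, sorted).
#' @return a [GenePanel-class] object.
#' @export
GenePanel <- function(name, genes) {
  new("GenePanel", name = name, genes = sort(unique(as.character(genes))))
}

#' @describeIn GenePanel the gene identifiers of the panel.
#' @param x a `GenePanel`.
#' @export
panelGenes <- function(x) {
  stopifnot(is(x, "GenePanel"))
  x@genes
}

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel", sQuote(object@name), "with", length(object@genes), "genes\n")
})

setMethod("length", "GenePanel", function(x) length(x@genes))

#' MeshThesaurus: descriptor table with tree numbers and entry terms
#'
#' Maps each MeSH descriptor id to its preferred name, its hierarchical
#' tree numbers (dot-delimited paths), and its entry terms (synonyms; the
#' preferred name always counts as one).
#'
#' @slot ids descriptor ids.
#' @slot names preferred names, parallel to `ids`.
#' @slot treeNumbers list of character vectors, parallel to `ids`.
#' @slot entryTerms list of character vectors, parallel to `ids`; always
#'   includes the preferred name.
#' @seealso [readMeshTable()], [meshDescendants()]
#' @exportClass MeshThesaurus
setClass("MeshThesaurus",
  representation(ids = "character", names = "character",
                 treeNumbers = "list", entryTerms = "list")
)

setValidity("MeshThesaurus", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids))
    msg <- c(msg, paste("duplicate descriptor id:",
                        object@ids[duplicated(object@ids)][1L]))
  if (length(object@names) != n || length(object@treeNumbers) != n ||
      length(object@entryTerms) != n)
    msg <- c(msg, "slots must be parallel to ids")
  if (n && any(!vapply(object@entryTerms, length, 0L)))
    TRUE
  if (n && any(vapply(object@entryTerms, length, 0L) == 0L))
    msg <- c(msg, "every descriptor needs at least one entry term")
  if (length(msg)) msg else TRUE
})

#' Construct a MeshThesaurus
#'
#' @param ids descriptor ids.
#' @param names preferred names.
#' @param treeNumbers list of character vectors of dot-delimited tree paths.
#' @param entryTerms list of character vectors of synonyms; the preferred
#'   name is added automatically.
#' @return a [MeshThesaurus-class].
#' @export
MeshThesaurus <- function(ids, names, treeNumbers, entryTerms = NULL) {
  ids <- as.character(ids)
  if (is.null(entryTerms)) entryTerms <- rep(list(character()), length(ids))
  entryTerms <- mapply(function(nm, et) unique(c(nm, et)),
                       names, entryTerms, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  new("MeshThesaurus", ids = ids, names = as.character(names),
      treeNumbers = unname(treeNumbers), entryTerms = entryTerms)
}

#' @describeIn MeshThesaurus descriptor ids in the thesaurus.
#' @param x a `MeshThesaurus`.
#' @export
meshIds <- function(x) {
  stopifnot(is(x, "MeshThesaurus"))
  x@ids
}

setMethod("length", "MeshThesaurus", function(x) length(x@ids))

setMethod("show", "MeshThesaurus", function(object) {
  cat("MeshThesaurus with", length(object@ids), "descriptors\n")
})

#' GeneTermMatrix: sparse gene x term-feature counts and TF-IDF scores
#'
#' Rows are genes (by concept id), columns are term features (by concept
#' id, each carrying one of the five categories cancer / drug /
#' genetic_phenomena / mutation / phenotype). `counts` holds raw window
#' co-occurrence frequencies; `scores` (once built) holds
#' `log(1 + tf) * log(1 + n_gene / df)`.
#'
#' @slot counts `dgCMatrix` of non-negative integers, dimnames gene x feature.
#' @slot scores `dgCMatrix` of TF-IDF scores with the same sparsity
#'   pattern, or `NULL` before [buildTfidf()] is applied.
#' @slot featureCategories named character vector, one category per feature
#'   column.
#' @seealso [countCooccurrence()], [buildTfidf()], [filterMinFeatures()]
#' @exportClass GeneTermMatrix
setClass("GeneTermMatrix",
  representation(counts = "dgCMatrix",
                 scores = "dgCMatrixOrNULL",
                 featureCategories = "character")
)

.CATEGORIES <- c("cancer", "drug", "genetic_phenomena", "mutation", "phenotype")

setValidity("GeneTermMatrix", function(object) {
  msg <- character()
  cn <- colnames(object@counts)
  rn <- rownames(object@counts)
  if (is.null(cn) || is.null(rn))
    msg <- c(msg, "counts must carry gene and feature dimnames")
  if (any(object@counts@x < 0)) msg <- c(msg, "counts must be non-negative")
  if (!identical(names(object@featureCategories), cn))
    msg <- c(msg, "featureCategories must be named by the feature columns")
  if (!all(object@featureCategories %in% .CATEGORIES))
    msg <- c(msg, "unknown feature category")
  if (!is.null(object@scores)) {
    if (!identical(dim(object@scores), dim(object@counts)))
      msg <- c(msg, "scores dimensions must match counts")
    if (any(object@scores@x < 0)) msg <- c(msg, "scores must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneTermMatrix gene (row) identifiers.
#' @param x,object a `GeneTermMatrix`.
#' @export
geneIds <- function(x) rownames(x@counts)

#' @describeIn GeneTermMatrix term-feature (column) identifiers.
#' @export
featureIds <- function(x) colnames(x@counts)

#' @describeIn GeneTermMatrix named character vector of feature categories.
#' @export
featureCategories <- function(x) x@featureCategories

#' @describeIn GeneTermMatrix sparse matrix of raw co-occurrence counts.
#' @export
termCounts <- function(x) x@counts

#' @describeIn GeneTermMatrix sparse matrix of TF-IDF scores (errors if not
#'   yet built).
#' @export
tfidfScores <- function(x) {
  if (is.null(x@scores))
    stop("TF-IDF scores not built yet; call buildTfidf() first")
  x@scores
}

#' @describeIn GeneTermMatrix per-feature document frequency: the number of
#'   genes with a positive count.
#' @export
featureDf <- function(x) {
  df <- diff(x@counts@p)
  names(df) <- colnames(x@counts)
  df
}

setMethod("dim", "GeneTermMatrix", function(x) dim(x@counts))

setMethod("show", "GeneTermMatrix", function(object) {
  cat(sprintf("GeneTermMatrix: %d genes x %d term features (%s)\n",
              nrow(object@counts), ncol(object@counts),
              if (is.null(object@scores)) "counts only" else "TF-IDF built"))
  tab <- table(factor(object@featureCategories, levels = .CATEGORIES))
  cat("  categories:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' TopicModel: non-negative matrix factorization of a gene term-feature matrix
#'
#' Factors `X ~ W H` with `W >= 0` (gene x k loadings) and `H >= 0`
#' (k x feature loadings), fitted by minimizing the squared Frobenius norm.
#'
#' @slot k number of topics.
#' @slot W gene x k loading matrix (rownames = genes).
#' @slot H k x feature loading matrix (colnames = features).
#' @slot lossTrace squared-Frobenius objective per iteration (element 1 is
#'   the objective at the initialization).
#' @slot nIter number of multiplicative-update iterations performed.
#' @slot seed integer seed used for random initialization (`NA` for the
#'   deterministic SVD-based init).
#' @slot init initialization scheme, `"nndsvd"` or `"random"`.
#' @seealso [fitNmf()], [topicSummaries()]
#' @exportClass TopicModel
setClass("TopicModel",
  representation(k = "integer", W = "matrix", H = "matrix",
                 lossTrace = "numeric", nIter = "integer",
                 seed = "integer", init = "character")
)

setValidity("TopicModel", function(object) {
  msg <- character()
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "W and H must be non-negative")
  if (ncol(object@W) != object@k || nrow(object@H) != object@k)
    msg <- c(msg, "factor dimensions must match k")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TopicModel", function(object) {
  cat(sprintf("TopicModel: k=%d over %d genes x %d features (%s init, %d iters, loss %.4g)\n",
              object@k, nrow(object@W), ncol(object@H), object@init,
              object@nIter, utils::tail(object@lossTrace, 1L)))
})

#' ClassifierReport: cross-validated panel-membership benchmark for one model
#'
#' Stores pooled out-of-fold predictions of a stratified k-fold
#' cross-validation, the derived confusion metrics (accuracy and per-class
#' precision / recall / F1), and the ROC curve with its trapezoidal AUC.
#'
#' @slot model model family name.
#' @slot predictions `data.frame` with one row per gene: `gene`, `label`
#'   (0/1 truth), `predicted` (0/1 out-of-fold), `score` (continuous
#'   decision score for the target class), `fold`.
#' @slot metrics named list: `accuracy`, and `precision`, `recall`, `f1`
#'   for both `target` and `non_target` classes.
#' @slot roc `data.frame` of ROC points (`fpr`, `tpr`) from (0,0) to (1,1).
#' @slot auc trapezoidal area under the stored ROC.
#' @slot nFolds fold count.
#' @slot seed integer seed that fixed the fold split and any model randomness.
#' @seealso [crossValidate()], [rocAuc()]
#' @exportClass ClassifierReport
setClass("ClassifierReport",
  representation(model = "character", predictions = "data.frame",
                 metrics = "list", roc = "data.frame", auc = "numeric",
                 nFolds = "integer", seed = "integer")
)

setValidity("ClassifierReport", function(object) {
  msg <- character()
  m <- unlist(object@metrics)
  if (any(m < 0 | m > 1, na.rm = TRUE)) msg <- c(msg, "metrics must lie in [0, 1]")
  r <- object@roc
  if (nrow(r)) {
    if (r$fpr[1L] != 0 || r$tpr[1L] != 0 ||
        r$fpr[nrow(r)] != 1 || r$tpr[nrow(r)] != 1)
      msg <- c(msg, "ROC must start at (0,0) and end at (1,1)")
    if (is.unsorted(r$fpr) || is.unsorted(r$tpr))
      msg <- c(msg, "ROC must be non-decreasing in both coordinates")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport [%s]: accuracy %.3f, AUC %.3f (%d-fold, seed %d)\n",
              object@model, object@metrics$accuracy, object@auc,
              object@nFolds, object@seed))
})

#' @describeIn ClassifierReport named list of pooled metrics.
#' @param x a `ClassifierReport`.
#' @export
reportMetrics <- function(x) x@metrics

#' @describeIn ClassifierReport area under the ROC curve.
#' @export
reportAuc <- function(x) x@auc
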