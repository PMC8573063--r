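# Three-sentence gene context windows: for every gene mention, the sentence
# containing the gene plus the previous and next sentences (clipped at
# document boundaries), and the term features co-occurring inside them.

#' Extract three-sentence gene windows from one document
#'
#' One window per unique (gene, center sentence) pair: the window spans the
#' center sentence, the previous one, and the next one, clipped to document
#' bounds; windows of the same gene with an identical clipped span are
#' deduplicated. A window's features are all annotations other than the
#' focal gene's own (including other genes, as gene-type features) whose
#' span starts inside the window's sentences; a feature mentioned twice in
#' one window counts twice (multiset semantics).
#'
#' @param abstract an [AnnotatedAbstract-class] with sentences and
#'   annotations present.
#' @param categories optional character vector assigning a feature category
#'   to every annotation row of `abstract` (from [categorizeFeatures()]);
#'   when `NULL`, every non-gene feature is categorized on the fly with no
#'   thesaurus (MeSH features then need `thesaurus`).
#' @param thesaurus optional [MeshThesaurus-class] forwarded to
#'   [categorizeFeatures()] when `categories` is `NULL`.
#' @return list with two `data.frame`s:
#'   `windows` (`docId`, `geneId`, `first`, `last` — sentence indices,
#'   1-based inclusive) and
#'   `features` (`docId`, `geneId`, `first`, `last`, `featureId`,
#'   `category`, `count`).
#' @export
extractGeneWindows <- function(abstract, categories = NULL, thesaurus = NULL) {
  emptyW <- data.frame(docId = character(), geneId = character(),
                       first = integer(), last = integer(),
                       stringsAsFactors = FALSE)
  emptyF <- cbind(emptyW, data.frame(featureId = character(),
                                     category = character(), count = integer(),
                                     stringsAsFactors = FALSE))
  ann <- abstract@annotations
  sen <- abstract@sentences
  if (nrow(ann) == 0L || nrow(sen) == 0L)
    return(list(windows = emptyW, features = emptyF))
  gene <- ann$etype == "Gene"
  if (!any(gene)) return(list(windows = emptyW, features = emptyF))
  if (is.null(categories))
    categories <- categorizeFeatures(ann$etype, ann$conceptId, thesaurus)

  nSen <- nrow(sen)
  sidx <- findInterval(ann$start, sen$start)  # sentence index per annotation

  centers <- unique(data.frame(geneId = ann$conceptId[gene],
                               center = sidx[gene], stringsAsFactors = FALSE))
  w <- data.frame(docId = abstract@docId, geneId = centers$geneId,
                  first = pmax(1L, centers$center - 1L),
                  last = pmin(nSen, centers$center + 1L),
                  stringsAsFactors = FALSE)
  w <- unique(w[order(w$geneId, w$first, w$last), , drop = FALSE])
  rownames(w) <- NULL

  feats <- vector("list", nrow(w))
  for (i in seq_len(nrow(w))) {
    inWin <- sidx >= w$first[i] & sidx <= w$last[i]
    own <- gene & ann$conceptId == w$geneId[i]
    sel <- which(inWin & !own)
    if (length(sel) == 0L) next
    key <- paste(ann$conceptId[sel], categories[sel], sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    feats[[i]] <- data.frame(
      docId = w$docId[i], geneId = w$geneId[i],
      first = w$first[i], last = w$last[i],
      featureId = vapply(parts, `[`, "", 1L),
      category = vapply(parts, `[`, "", 2L),
      count = as.integer(tab), stringsAsFactors = FALSE)
  }
  feats <- feats[!vapply(feats, is.null, TRUE)]
  f <- if (length(feats)) do.call(rbind, feats) else emptyF
  rownames(f) <- NULL
  list(windows = w, features = f)
}

#' Collect gene windows over a corpus
#'
#' Applies [extractGeneWindows()] to every document and concatenates the
#' per-document tables; every window appears exactly once.
#'
#' @param abstracts list of [AnnotatedAbstract-class].
#' @param thesaurus optional [MeshThesaurus-class] for MeSH feature
#'   categorization.
#' @param neoplasmsRoot,geneticRoot branch roots passed to
#'   [categorizeFeatures()].
#' @return list with concatenated `windows` and `features` tables (see
#'   [extractGeneWindows()]).
#' @export
collectWindows <- function(abstracts, thesaurus = NULL,
                           neoplasmsRoot = "C04", geneticRoot = "G05") {
  parts <- lapply(abstracts, function(a) {
    cats <- if (nrow(a@annotations))
      categorizeFeatures(a@annotations$etype, a@annotations$conceptId,
                         thesaurus, neoplasmsRoot, geneticRoot)
    extractGeneWindows(a, categories = cats)
  })
  windows <- data.table::rbindlist(lapply(parts, `[[`, "windows"))
  features <- data.table::rbindlist(lapply(parts, `[[`, "features"))
  list(windows = as.data.frame(windows), features = as.data.frame(features))
}

#' Export gene windows as a TSV audit table
#'
#' @param windows result of [collectWindows()].
#' @param path output path; columns `doc_id`, `gene_id`, `first_sentence`,
#'   `last_sentence`, `feature_id`, `category`, `count`.
#' @return `path`, invisibly.
#' @export
writeWindows <- function(windows, path) {
  f <- windows$features
  tab <- data.frame(doc_id = f$docId, gene_id = f$geneId,
                    first_sentence = f$first, last_sentence = f$last,
                    feature_id = f$featureId, category = f$category,
                    count = f$count, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
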