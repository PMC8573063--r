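# MeSH hierarchy tagging: expand an article's indexed descriptors to their
# descendant subtrees, string-match entry terms in the text, and emit MeSH
# annotations that complement the PubTator ones.

#' Descendant closure of a MeSH descriptor
#'
#' Returns the descriptor itself plus every descriptor having a tree number
#' that strictly extends (dot-prefix) any tree number of `id`.
#'
#' @param thesaurus a [MeshThesaurus-class].
#' @param id descriptor id present in the thesaurus.
#' @return character vector of descriptor ids (sorted; includes `id`).
#' @export
meshDescendants <- function(thesaurus, id) {
  i <- match(id, thesaurus@ids)
  if (is.na(i)) stop("unknown descriptor id: ", id)
  roots <- thesaurus@treeNumbers[[i]]
  if (length(roots) == 0L) return(id)
  prefixes <- paste0(roots, ".")
  hit <- vapply(thesaurus@treeNumbers, function(tns) {
    any(vapply(prefixes, function(p) any(startsWith(tns, p)), TRUE))
  }, TRUE)
  sort(unique(c(id, thesaurus@ids[hit])))
}

#' Build a MeSH term-mapping set from an article's indexing
#'
#' Union of [meshDescendants()] over all descriptors indexed for the
#' article: the set of descriptors whose entry terms the tagger will try to
#' match in the text.
#'
#' @param thesaurus a [MeshThesaurus-class].
#' @param indexedIds character vector of descriptor ids assigned to the
#'   article.
#' @return sorted character vector of descriptor ids.
#' @export
buildMappingSet <- function(thesaurus, indexedIds) {
  indexedIds <- unique(indexedIds)
  unknown <- setdiff(indexedIds, thesaurus@ids)
  if (length(unknown)) stop("unknown descriptor id: ", unknown[1L])
  if (length(indexedIds) == 0L) return(character())
  sort(unique(unlist(lapply(indexedIds, meshDescendants,
                            thesaurus = thesaurus))))
}

# Case-fold and make hyphen/space equivalent, preserving string length.
.foldText <- function(x) gsub("-", " ", tolower(x), fixed = TRUE)

.escapeRegex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Tag entry-term occurrences of indexed MeSH subtrees
#'
#' For every descriptor in the article's mapping set (indexed descriptors
#' plus their subtree descendants), finds each case-insensitive whole-token
#' occurrence of any of its entry terms in the document text and emits an
#' annotation with `etype = "MeSH"` and `conceptId` = the descriptor id.
#' Hyphens and spaces are interchangeable ("non small cell" matches
#' "non-small cell"). Matches must lie within a single sentence. Spans
#' overlapping an existing annotation are skipped (PubTator precedence), so
#' tagging is idempotent; among overlapping candidates the longest span
#' wins, ties broken by lexicographically smallest descriptor id, then
#' leftmost position.
#'
#' @param abstract an [AnnotatedAbstract-class] with sentences computed.
#' @param thesaurus a [MeshThesaurus-class].
#' @param indexedIds descriptor ids indexed for this article.
#' @return `data.frame` of new annotations (same columns as the
#'   `annotations` slot), possibly empty.
#' @seealso [tagCorpus()] to merge the result back into the corpus.
#' @export
tagWithMesh <- function(abstract, thesaurus, indexedIds) {
  mapping <- buildMappingSet(thesaurus, indexedIds)
  if (length(mapping) == 0L) return(.emptyAnnotations())
  txt <- abstractText(abstract)
  folded <- .foldText(txt)
  idx <- match(mapping, thesaurus@ids)

  cand <- list()
  for (j in seq_along(mapping)) {
    for (term in unique(.foldText(thesaurus@entryTerms[[idx[j]]]))) {
      if (!nzchar(term)) next
      pat <- paste0("(?<![[:alnum:]])", .escapeRegex(term), "(?![[:alnum:]])")
      m <- gregexpr(pat, folded, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      len <- attr(m, "match.length")
      cand[[length(cand) + 1L]] <- data.frame(
        start = as.integer(m) - 1L, end = as.integer(m) - 1L + len,
        conceptId = mapping[j], stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(.emptyAnnotations())
  cand <- do.call(rbind, cand)

  # constrain to a single sentence
  s <- abstract@sentences
  if (nrow(s)) {
    si <- findInterval(cand$start, s$start)
    ok <- si >= 1L & cand$start >= s$start[pmax(si, 1L)] &
      cand$end <= s$end[pmax(si, 1L)]
    cand <- cand[ok, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(.emptyAnnotations())

  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  exist <- abstract@annotations
  if (nrow(exist)) {
    clash <- vapply(seq_len(nrow(cand)), function(i) {
      any(overlaps(cand$start[i], cand$end[i], exist$start, exist$end))
    }, TRUE)
    cand <- cand[!clash, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(.emptyAnnotations())

  # longest-match-wins greedy resolution
  cand <- cand[order(-(cand$end - cand$start), cand$conceptId, cand$start), ,
               drop = FALSE]
  keepS <- keepE <- integer()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(overlaps(cand$start[i], cand$end[i], keepS, keepE))) {
      keep[i] <- TRUE
      keepS <- c(keepS, cand$start[i]); keepE <- c(keepE, cand$end[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  data.frame(start = cand$start, end = cand$end,
             mention = substring(txt, cand$start + 1L, cand$end),
             etype = "MeSH", conceptId = cand$conceptId,
             stringsAsFactors = FALSE)
}

#' Tag a whole corpus with MeSH annotations
#'
#' Applies [tagWithMesh()] per document and merges the new annotations into
#' each abstract (sorted by span). Documents without an indexing entry are
#' left unchanged.
#'
#' @param abstracts list of [AnnotatedAbstract-class].
#' @param thesaurus a [MeshThesaurus-class].
#' @param indexing named list doc_id -> descriptor ids
#'   (see [readMeshIndexing()]).
#' @return the corpus with MeSH annotations merged in.
#' @export
tagCorpus <- function(abstracts, thesaurus, indexing) {
  att <- attributes(abstracts)
  out <- lapply(abstracts, function(a) {
    ids <- indexing[[a@docId]]
    if (is.null(ids) || length(ids) == 0L) return(a)
    extra <- tagWithMesh(a, thesaurus, ids)
    if (nrow(extra) == 0L) return(a)
    ann <- rbind(a@annotations, extra)
    ann <- ann[order(ann$start, ann$end, ann$conceptId), , drop = FALSE]
    rownames(ann) <- NULL
    initialize(a, annotations = ann)
  })
  attributes(out) <- att
  out
}

#' Categorize term features into the five feature groups
#'
#' Deterministic mapping of annotations onto the groups
#' `cancer`, `drug`, `genetic_phenomena`, `mutation`, `phenotype`:
#' Mutation-typed annotations are `mutation`; Chemical-typed are `drug`;
#' Disease-typed are `cancer`; MeSH-typed annotations are `cancer` when any
#' tree number lies under the neoplasms branch, `genetic_phenomena` under
#' the genetic-phenomena branch, otherwise `phenotype` (an unknown
#' descriptor id also falls back to `phenotype`, with a warning). Gene and
#' Species annotations map to `phenotype`.
#'
#' @param etype character vector of annotation types.
#' @param conceptId character vector of concept ids, parallel to `etype`.
#' @param thesaurus a [MeshThesaurus-class] (used for MeSH-typed features).
#' @param neoplasmsRoot,geneticRoot tree-number prefixes of the two special
#'   branches; defaults `"C04"` and `"G05"` match the real MeSH trees.
#' @return character vector of categories.
#' @export
categorizeFeatures <- function(etype, conceptId, thesaurus = NULL,
                               neoplasmsRoot = "C04", geneticRoot = "G05") {
  stopifnot(length(etype) == length(conceptId))
  out <- rep("phenotype", length(etype))
  out[etype == "Mutation"] <- "mutation"
  out[etype == "Chemical"] <- "drug"
  out[etype == "Disease"] <- "cancer"
  isMesh <- which(etype == "MeSH")
  if (length(isMesh)) {
    if (is.null(thesaurus))
      stop("a thesaurus is required to categorize MeSH-typed features")
    underBranch <- function(tns, root)
      any(tns == root | startsWith(tns, paste0(root, ".")))
    i <- match(conceptId[isMesh], thesaurus@ids)
    if (anyNA(i))
      warning("unknown MeSH descriptor(s) categorized as phenotype: ",
              paste(unique(conceptId[isMesh][is.na(i)]), collapse = ", "))
    for (k in seq_along(isMesh)) {
      if (is.na(i[k])) next
      tns <- thesaurus@treeNumbers[[i[k]]]
      out[isMesh[k]] <- if (underBranch(tns, neoplasmsRoot)) "cancer"
        else if (underBranch(tns, geneticRoot)) "genetic_phenomena"
        else "phenotype"
    }
  }
  out
}
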