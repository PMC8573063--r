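# Fully self-contained synthetic study generator: a toy MeSH thesaurus, a
# gene universe with a panel, and a PubTator-format corpus whose sentences
# carry planted gene mentions and feature mentions with an elevated
# co-occurrence rate between panel genes and designated signal features.
# A ground-truth manifest records every planted quantity so each pipeline
# stage can be validated against it.

#' SyntheticSpec: parameters of a synthetic literature study
#'
#' Defines the study conditions the generator emulates. Every document has
#' one focal gene mentioned in its center sentence; features co-occur in
#' the three-sentence window around it with probability `pSignal` for
#' (panel gene, signal feature) pairs and `pBackground` otherwise; two
#' distractor feature mentions per document are planted outside the window.
#'
#' @slot nGenes gene universe size.
#' @slot nPanel panel size.
#' @slot nFeatures named integer vector: features per category (names must
#'   be the five categories).
#' @slot nSignalFeatures number of signal features (taken from
#'   `signalCategory`).
#' @slot signalCategory category holding the signal features.
#' @slot docsPerGene documents per gene.
#' @slot sentencesPerDoc sentences per document (title included; >= 5 so
#'   the window has out-of-window neighbours on both sides).
#' @slot pSignal per-window co-occurrence probability for (panel gene,
#'   signal feature) pairs.
#' @slot pBackground baseline per-window co-occurrence probability
#'   (`pBackground <= pSignal`; equality gives a null corpus).
#' @slot pUntagged fraction of MeSH-typed feature mentions emitted without
#'   an entity line (recoverable only through the MeSH tagger).
#' @slot pParentIndex probability an untagged mention is indexed through
#'   its parent descriptor rather than itself (exercises subtree
#'   expansion).
#' @slot yearRange inclusive publication-year range.
#' @slot eraSplit first year of the late era; era-switched features are
#'   emitted only in their own era.
#' @slot nEraFeatures number of early-only and of late-only cancer
#'   features.
#' @slot seed integer seed; the whole generation is deterministic given it.
#' @seealso [syntheticSpec()], [generateCorpus()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nGenes = "integer", nPanel = "integer",
                 nFeatures = "integer", nSignalFeatures = "integer",
                 signalCategory = "character", docsPerGene = "integer",
                 sentencesPerDoc = "integer", pSignal = "numeric",
                 pBackground = "numeric", pUntagged = "numeric",
                 pParentIndex = "numeric", yearRange = "integer",
                 eraSplit = "integer", nEraFeatures = "integer",
                 seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (!identical(sort(names(object@nFeatures)), sort(.CATEGORIES)))
    msg <- c(msg, "nFeatures must be named by the five categories")
  if (any(c(object@nGenes, object@nPanel, object@nFeatures,
            object@docsPerGene, object@sentencesPerDoc) < 1L))
    msg <- c(msg, "all counts must be positive")
  if (object@nPanel >= object@nGenes)
    msg <- c(msg, "nPanel must be smaller than nGenes")
  if (object@sentencesPerDoc < 5L)
    msg <- c(msg, "sentencesPerDoc must be >= 5")
  if (object@pBackground < 0 || object@pSignal > 1 ||
      object@pBackground > object@pSignal)
    msg <- c(msg, "need 0 <= pBackground <= pSignal <= 1")
  nSig <- object@nSignalFeatures
  if (nSig + 2L * object@nEraFeatures >
      object@nFeatures[[object@signalCategory]])
    msg <- c(msg, "signal + era features exceed the signal category size")
  if (object@yearRange[1L] > object@yearRange[2L])
    msg <- c(msg, "yearRange must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticSpec
#'
#' Defaults encode the package's reference study: a 600-gene universe with
#' a 100-gene panel, five feature categories of 40 features each, 20
#' cancer-category signal features, 4 documents per gene with 5 sentences
#' each, per-window co-occurrence rates 0.6 (panel x signal) versus 0.05
#' baseline, publication years 2011-2019 with an era switch at 2016, and
#' two era-switched cancer features per era.
#'
#' @param nGenes,nPanel,nFeatures,nSignalFeatures,signalCategory see
#'   [SyntheticSpec-class].
#' @param docsPerGene,sentencesPerDoc,pSignal,pBackground,pUntagged see
#'   [SyntheticSpec-class].
#' @param pParentIndex,yearRange,eraSplit,nEraFeatures,seed see
#'   [SyntheticSpec-class].
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nGenes = 600, nPanel = 100,
                          nFeatures = c(cancer = 40, drug = 40,
                                        genetic_phenomena = 40,
                                        mutation = 40, phenotype = 40),
                          nSignalFeatures = 20, signalCategory = "cancer",
                          docsPerGene = 4, sentencesPerDoc = 5,
                          pSignal = 0.6, pBackground = 0.05,
                          pUntagged = 0.3, pParentIndex = 0.2,
                          yearRange = c(2011, 2019), eraSplit = 2016,
                          nEraFeatures = 2, seed = 1) {
  nf <- as.integer(nFeatures)
  names(nf) <- names(nFeatures)
  new("SyntheticSpec", nGenes = as.integer(nGenes), nPanel = as.integer(nPanel),
      nFeatures = nf, nSignalFeatures = as.integer(nSignalFeatures),
      signalCategory = signalCategory, docsPerGene = as.integer(docsPerGene),
      sentencesPerDoc = as.integer(sentencesPerDoc), pSignal = pSignal,
      pBackground = pBackground, pUntagged = pUntagged,
      pParentIndex = pParentIndex, yearRange = as.integer(yearRange),
      eraSplit = as.integer(eraSplit), nEraFeatures = as.integer(nEraFeatures),
      seed = as.integer(seed))
}

# The planted vocabulary: one row per feature with its emission type,
# surface token, and (for MeSH features) descriptor id, tree number, and
# parent descriptor.
.syntheticVocab <- function(spec) {
  rows <- list()
  trees <- c(cancer = "C04", genetic_phenomena = "G05", phenotype = "F01")
  for (cat in .CATEGORIES) {
    n <- spec@nFeatures[[cat]]
    j <- seq_len(n)
    rows[[cat]] <- switch(cat,
      cancer = data.frame(
        category = cat,
        etype = ifelse(j %% 2L == 1L, "MeSH", "Disease"),
        featureId = ifelse(j %% 2L == 1L, sprintf("D1%04d", j),
                           sprintf("MESH:DC%04d", j)),
        token = sprintf("cancerterm%03d", j),
        tree = ifelse(j %% 2L == 1L, sprintf("C04.%03d", j), NA),
        stringsAsFactors = FALSE),
      drug = data.frame(
        category = cat, etype = "Chemical",
        featureId = sprintf("MESH:DD%04d", j),
        token = sprintf("drugterm%03d", j), tree = NA,
        stringsAsFactors = FALSE),
      mutation = data.frame(
        category = cat, etype = "Mutation",
        featureId = sprintf("V%dE", 100L + j),
        token = sprintf("V%dE", 100L + j), tree = NA,
        stringsAsFactors = FALSE),
      genetic_phenomena = data.frame(
        category = cat, etype = "MeSH", featureId = sprintf("D3%04d", j),
        token = sprintf("geneticterm%03d", j),
        tree = sprintf("G05.%03d", j), stringsAsFactors = FALSE),
      phenotype = data.frame(
        category = cat, etype = "MeSH", featureId = sprintf("D4%04d", j),
        token = sprintf("phenotypeterm%03d", j),
        tree = sprintf("F01.%03d", j), stringsAsFactors = FALSE))
  }
  vocab <- do.call(rbind, rows)
  rownames(vocab) <- NULL
  # signal features: the first nSignalFeatures of the signal category;
  # era-switched features: the last 2 * nEraFeatures of the cancer block
  vocab$signal <- FALSE
  sigIdx <- which(vocab$category == spec@signalCategory)[
    seq_len(spec@nSignalFeatures)]
  vocab$signal[sigIdx] <- TRUE
  vocab$era <- "all"
  if (spec@nEraFeatures > 0L) {
    canIdx <- which(vocab$category == "cancer")
    tailIdx <- utils::tail(canIdx, 2L * spec@nEraFeatures)
    vocab$era[tailIdx[seq_len(spec@nEraFeatures)]] <- "early"
    vocab$era[utils::tail(tailIdx, spec@nEraFeatures)] <- "late"
  }
  parents <- c(cancer = "D100000", genetic_phenomena = "D300000",
               phenotype = "D400000")
  vocab$parent <- ifelse(vocab$etype == "MeSH",
                         parents[vocab$category], NA)
  vocab
}

# Toy thesaurus covering all MeSH-typed features plus the three branch
# roots used for categorization.
.syntheticThesaurus <- function(vocab) {
  mesh <- vocab[vocab$etype == "MeSH", , drop = FALSE]
  MeshThesaurus(
    ids = c("D100000", "D300000", "D400000", mesh$featureId),
    names = c("Neoplasms", "Genetic Phenomena", "Phenotypic Traits",
              paste("Concept", mesh$token)),
    treeNumbers = c(list("C04", "G05", "F01"), as.list(mesh$tree)),
    entryTerms = c(rep(list(character()), 3L), as.list(mesh$token)))
}

# A sentence from lead words, mention tokens, and tail words; returns its
# text (terminal period attached) and the 0-based offset of each mention
# within the sentence.
.mkSentence <- function(lead, mentions = character(), tail = character()) {
  toks <- c(lead, mentions, tail)
  starts <- cumsum(c(0L, nchar(toks) + 1L))[seq_along(toks)]
  list(text = paste0(paste(toks, collapse = " "), "."),
       mentionStart = starts[seq_along(mentions) + length(lead)])
}

#' Generate a synthetic annotated corpus with ground truth
#'
#' Writes, under `dir`: `corpus.pubtator` (PubTator dialect with the
#' `|y|` year extension), `mesh.tsv` (toy thesaurus), `indexing.tsv`
#' (per-document indexed descriptors), `panel.txt` (the planted panel),
#' `clinical_freq_synthetic.tsv` (a synthetic stand-in for an external
#' clinical gene-frequency vector, derived from the planted cancer
#' co-occurrence counts), and `manifest.json`. Returns the manifest, which
#' records every planted quantity: per-document sentence counts, window
#' spans, feature mentions with their sentence and tagging status, and the
#' aggregate in-window gene x feature co-occurrence tallies.
#'
#' Byte-identical outputs are guaranteed for a fixed spec (all randomness
#' is drawn under `spec@seed`).
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if missing).
#' @return invisibly, a list: `paths` (named file paths), `manifest`
#'   (list with `genes`, `panel`, `features`, `docs`, `mentions`,
#'   `cooccurrence`), `thesaurus` (the toy [MeshThesaurus-class]).
#' @export
generateCorpus <- function(spec, dir) {
  validObject(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vocab <- .syntheticVocab(spec)
  thes <- .syntheticThesaurus(vocab)
  geneTok <- sprintf("GTX%04d", seq_len(spec@nGenes))
  geneId <- sprintf("%d", 60000L + seq_len(spec@nGenes))

  res <- withSeed(spec@seed, {
    panel <- sort(sample(geneId, spec@nPanel))
    years <- seq.int(spec@yearRange[1L], spec@yearRange[2L])
    center <- 3L
    win <- c(2L, 4L)
    nSen <- spec@sentencesPerDoc

    blocks <- character()
    indexing <- list()
    docRows <- mentionRows <- vector("list", spec@nGenes * spec@docsPerGene)
    docNo <- 0L
    for (g in seq_len(spec@nGenes)) {
      isPanel <- geneId[g] %in% panel
      for (d in seq_len(spec@docsPerGene)) {
        docNo <- docNo + 1L
        docId <- sprintf("%d", 10000000L + docNo)
        year <- sample(years, 1L)
        early <- year < spec@eraSplit
        elig <- which(vocab$era == "all" |
                        (vocab$era == "early") == early & vocab$era != "all")
        p <- ifelse(isPanel & vocab$signal[elig], spec@pSignal,
                    spec@pBackground)
        inc <- elig[stats::runif(length(elig)) < p]
        sentOf <- if (length(inc))
          sample(win[1L]:win[2L], length(inc), replace = TRUE) else integer()
        distr <- elig[sample.int(length(elig), 2L)]

        sents <- vector("list", nSen)
        sents[[1L]] <- .mkSentence(
          c("Observational", "registry", "record", paste0("doc", docId),
            "mentions"), vocab$token[distr[1L]], c("in", "archives"))
        for (sIdx in 2L:nSen) {
          m <- vocab$token[inc[sentOf == sIdx]]
          sents[[sIdx]] <- if (sIdx == center)
            .mkSentence(c("The", "gene"), c(geneTok[g], m),
                        c("was", "profiled", "in", "this", "cohort"))
          else if (sIdx >= win[1L] && sIdx <= win[2L])
            .mkSentence(c("Cohort", "screening", "noted"), m,
                        c("during", "assessment"))
          else if (sIdx == win[2L] + 1L)
            .mkSentence(c("Unrelated", "archival", "notes", "describe"),
                        vocab$token[distr[2L]], c("separately"))
          else
            .mkSentence(c("Further", "methodological", "details", "appear",
                          "in", "the", "registry"))
        }
        sentText <- vapply(sents, `[[`, "", "text")
        sentStart <- cumsum(c(0L, nchar(sentText) + 1L))[seq_len(nSen)]

        # absolute mention offsets
        mk <- function(sIdx, which) sentStart[sIdx] + sents[[sIdx]]$mentionStart[which]
        annStart <- annEnd <- integer()
        annMention <- annEtype <- annConcept <- character()
        addAnn <- function(start, tok, etype, concept) {
          annStart <<- c(annStart, start)
          annEnd <<- c(annEnd, start + nchar(tok))
          annMention <<- c(annMention, tok)
          annEtype <<- c(annEtype, etype)
          annConcept <<- c(annConcept, concept)
        }
        addAnn(mk(center, 1L), geneTok[g], "Gene", geneId[g])

        mRows <- list()
        docIndex <- character()
        planted <- data.frame(
          feat = c(inc, distr), sentence = c(sentOf, 1L, win[2L] + 1L))
        # locate each mention among its sentence's mention tokens (center
        # sentence mentions sit after the gene token)
        for (r in seq_len(nrow(planted))) {
          f <- planted$feat[r]
          sIdx <- planted$sentence[r]
          mtoks <- if (sIdx == center) c(geneTok[g], vocab$token[inc[sentOf == sIdx]])
            else if (sIdx == 1L) vocab$token[distr[1L]]
            else if (sIdx == win[2L] + 1L) vocab$token[distr[2L]]
            else vocab$token[inc[sentOf == sIdx]]
          wi <- which(mtoks == vocab$token[f])[1L]
          start <- mk(sIdx, wi)
          tagged <- TRUE
          if (vocab$etype[f] == "MeSH") {
            tagged <- stats::runif(1L) >= spec@pUntagged
            if (!tagged) {
              idxId <- if (stats::runif(1L) < spec@pParentIndex)
                vocab$parent[f] else vocab$featureId[f]
              docIndex <- c(docIndex, idxId)
            }
          }
          if (tagged)
            addAnn(start, vocab$token[f], vocab$etype[f], vocab$featureId[f])
          mRows[[r]] <- data.frame(
            docId = docId, featureId = vocab$featureId[f], sentence = sIdx,
            tagged = tagged, inWindow = sIdx >= win[1L] & sIdx <= win[2L],
            stringsAsFactors = FALSE)
        }
        ord <- order(annStart, annEnd)
        lines <- c(paste0(docId, "|t|", sentText[1L]),
                   paste0(docId, "|a|", paste(sentText[-1L], collapse = " ")),
                   paste0(docId, "|y|", year),
                   paste(docId, annStart[ord], annEnd[ord], annMention[ord],
                         annEtype[ord], annConcept[ord], sep = "\t"))
        blocks[docNo] <- paste0(paste(lines, collapse = "\n"), "\n")
        if (length(docIndex)) indexing[[docId]] <- sort(unique(docIndex))
        docRows[[docNo]] <- data.frame(
          docId = docId, geneId = geneId[g], year = year, nSentences = nSen,
          center = center, windowFirst = win[1L], windowLast = win[2L],
          stringsAsFactors = FALSE)
        mentionRows[[docNo]] <- do.call(rbind, mRows)
      }
    }
    list(panel = panel, blocks = blocks, indexing = indexing,
         docs = do.call(rbind, docRows),
         mentions = do.call(rbind, mentionRows))
  })

  docs <- res$docs
  mentions <- res$mentions
  # ground-truth in-window co-occurrence tallies
  mw <- mentions[mentions$inWindow, c("docId", "featureId")]
  mw$geneId <- docs$geneId[match(mw$docId, docs$docId)]
  co <- data.table::as.data.table(mw)[, list(count = .N),
                                      by = c("geneId", "featureId")]
  co <- as.data.frame(co[order(co$geneId, co$featureId)])

  paths <- c(pubtator = file.path(dir, "corpus.pubtator"),
             mesh = file.path(dir, "mesh.tsv"),
             indexing = file.path(dir, "indexing.tsv"),
             panel = file.path(dir, "panel.txt"),
             clinical = file.path(dir, "clinical_freq_synthetic.tsv"),
             manifest = file.path(dir, "manifest.json"))
  writeLines(res$blocks, paths[["pubtator"]], sep = "\n", useBytes = TRUE)
  writeMeshTable(thes, paths[["mesh"]])
  writeMeshIndexing(res$indexing, paths[["indexing"]])
  writeLines(res$panel, paths[["panel"]], useBytes = TRUE)

  # synthetic clinical-frequency stand-in: planted cancer co-occurrence
  # counts per gene, normalized
  cancerIds <- vocab$featureId[vocab$category == "cancer"]
  cc <- co[co$featureId %in% cancerIds, , drop = FALSE]
  freq <- tapply(cc$count, factor(cc$geneId, levels = sort(unique(docs$geneId))),
                 sum, default = 0)
  freq <- freq / sum(freq)
  utils::write.table(
    data.frame(gene_id = names(freq), frequency = sprintf("%.10g", freq)),
    paths[["clinical"]], sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    genes = data.frame(geneId = geneId, token = geneTok,
                       panel = geneId %in% res$panel,
                       stringsAsFactors = FALSE),
    panel = res$panel, features = vocab, docs = docs,
    mentions = mentions, cooccurrence = co)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(list(paths = paths, manifest = manifest, thesaurus = thes))
}
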