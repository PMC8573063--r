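# End-to-end orchestration: ingest -> MeSH tag -> windows -> matrix ->
# TF-IDF -> min-feature filter -> hypergeometric selection -> topics ->
# classification -> landscape, with deterministic on-disk exports. The
# genecontext command-line script is a thin wrapper over runPipeline().

#' Run the full literature-mining pipeline
#'
#' Reads a PubTator corpus, a MeSH thesaurus, a per-document indexing
#' table, and a panel list; runs every stage; and writes deterministic
#' exports under `outDir`: `matrix/` (MatrixMarket + sidecars),
#' `selection.tsv`, `category_proportions.tsv`, `topics/`, `classifier/`,
#' `landscape/`, `windows.tsv`, and `run.json` (parameters and stage
#' summaries). Two runs with identical inputs and parameters produce
#' byte-identical files.
#'
#' @param pubtator,mesh,indexing,panel input file paths (see
#'   [readPubtator()], [readMeshTable()], [readMeshIndexing()],
#'   [readPanel()]).
#' @param outDir output directory.
#' @param yearFrom,yearTo optional inclusive year slice applied before any
#'   other stage (see [filterByYear()]).
#' @param minFeatures minimum distinct features per gene (default 10).
#' @param alpha,nRandom selection parameters (see [selectFeatures()]).
#' @param nTopics requested topic count (default 30, clamped to the
#'   filtered matrix dimensions with a warning).
#' @param models classifier families to benchmark (`"all"` or a subset of
#'   [classifierModels()]).
#' @param folds cross-validation folds (default 5).
#' @param seed integer seed driving background sampling, fold splits, and
#'   any model randomness.
#' @param clinicalFreq optional path to an external gene-frequency TSV for
#'   the cosine-similarity validation.
#' @param cancerMap optional named descriptor -> cancer-type vector for
#'   column aggregation in the landscape stage.
#' @return invisibly, a list with the in-memory stage results: `corpus`,
#'   `windows`, `matrix` (filtered, scored), `selection`, `topics`,
#'   `reports`, `landscape` (`NULL` when no cancer feature survives
#'   selection), `cosine` (`NA` without `clinicalFreq`).
#' @export
runPipeline <- function(pubtator, mesh, indexing, panel, outDir,
                        yearFrom = NULL, yearTo = NULL, minFeatures = 10,
                        alpha = 0.05, nRandom = 500, nTopics = 30,
                        models = "all", folds = 5, seed = 1,
                        clinicalFreq = NULL, cancerMap = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  thes <- readMeshTable(mesh)
  idx <- readMeshIndexing(indexing)
  pan <- readPanel(panel)
  corpus <- readPubtator(pubtator)
  if (!is.null(yearFrom) || !is.null(yearTo)) {
    if (is.null(yearFrom) || is.null(yearTo))
      stop("supply both yearFrom and yearTo, or neither")
    corpus <- filterByYear(corpus, yearFrom, yearTo)
  }
  corpus <- tagCorpus(corpus, thes, idx)

  windows <- collectWindows(corpus, thesaurus = thes)
  writeWindows(windows, file.path(outDir, "windows.tsv"))

  gtm <- countCooccurrence(windows)
  gtm <- filterMinFeatures(gtm, k = minFeatures)
  gtm <- buildTfidf(gtm)

  sel <- selectFeatures(gtm, pan, alpha = alpha, nRandom = nRandom,
                        seed = seed)
  writeGeneTermMatrix(sel$matrix, file.path(outDir, "matrix"))
  writeSelectionTable(sel$table, file.path(outDir, "selection.tsv"))
  props <- categoryProportions(sel$table)
  propsOut <- props
  propsOut$before <- sprintf("%.10g", propsOut$before)
  propsOut$after <- sprintf("%.10g", propsOut$after)
  utils::write.table(propsOut, file.path(outDir, "category_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  k <- min(nTopics, nrow(sel$matrix@counts), ncol(sel$matrix@counts))
  if (k < nTopics)
    warning(sprintf("nTopics reduced from %d to %d (matrix dimensions)",
                    nTopics, k))
  model <- fitNmf(sel$matrix, k = k)
  writeTopicModel(model, file.path(outDir, "topics"))

  y <- makeLabels(sel$matrix, pan)
  X <- as.matrix(tfidfScores(sel$matrix))
  reports <- benchmarkClassifiers(X, y, models = models, folds = folds,
                                  seed = seed)
  writeClassifierReports(reports, file.path(outDir, "classifier"))

  landscape <- NULL
  cosine <- NA_real_
  if (any(featureCategories(sel$matrix) == "cancer")) {
    landscape <- geneCancerMatrix(sel$matrix, cancerMap = cancerMap)
    writeLandscape(landscape, file.path(outDir, "landscape"))
    if (!is.null(clinicalFreq)) {
      ext <- readClinicalFrequency(clinicalFreq)
      cosine <- cosineSimilarity(geneFrequency(landscape), ext)
    }
  }

  run <- list(
    parameters = list(yearFrom = yearFrom, yearTo = yearTo,
                      minFeatures = minFeatures, alpha = alpha,
                      nRandom = nRandom, nTopics = k, models = models,
                      folds = folds, seed = seed),
    corpus = list(nDocs = length(corpus),
                  nNoGene = length(attr(corpus, "noGene"))),
    matrix = list(nGenes = nrow(sel$matrix@counts),
                  nFeatures = ncol(sel$matrix@counts),
                  nTested = nrow(sel$table),
                  nSelected = sum(sel$table$selected)),
    classifier = lapply(reports, function(r)
      list(accuracy = r@metrics$accuracy, auc = r@auc)),
    cosine_similarity = if (is.na(cosine)) NULL else cosine)
  jsonlite::write_json(run, file.path(outDir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(corpus = corpus, windows = windows, matrix = sel$matrix,
                 selection = sel$table, topics = model, reports = reports,
                 landscape = landscape, cosine = cosine))
}

#' Generate a synthetic study and measure pipeline recovery
#'
#' Runs [generateCorpus()] and the full pipeline on its outputs, then
#' scores recovery against the planted truth: the fraction of signal
#' features selected, the per-category proportion shift, classifier
#' AUC/accuracy, how strongly one NMF topic concentrates the signal
#' features, and the cosine similarity against the synthetic clinical
#' frequency stand-in.
#'
#' @param spec a [SyntheticSpec-class].
#' @param alpha selection threshold (default 0.05).
#' @param nTopics topic count for the NMF stage (default 5).
#' @param models classifier families (default `"linear_svm"` for speed).
#' @param nRandom background size (default 500).
#' @param dir working directory (default: a fresh temporary directory).
#' @param folds,minFeatures forwarded to [runPipeline()].
#' @return list: `signalRecall`, `selectedFraction`,
#'   `noiseSelectedFraction`, `pValues` (named by feature, noise features
#'   only), `proportions` (category shift table), `accuracy` and `auc`
#'   (named by model), `topicSignalOverlap`, `cosine`, plus the full
#'   `pipeline` result and the generator `manifest`.
#' @export
endToEndCheck <- function(spec, alpha = 0.05, nTopics = 5,
                          models = "linear_svm", nRandom = 500,
                          dir = tempfile("synthstudy"), folds = 5,
                          minFeatures = 10) {
  gen <- generateCorpus(spec, dir)
  p <- gen$paths
  out <- runPipeline(p[["pubtator"]], p[["mesh"]], p[["indexing"]],
                     p[["panel"]], file.path(dir, "out"),
                     minFeatures = minFeatures, alpha = alpha,
                     nRandom = nRandom, nTopics = nTopics, models = models,
                     folds = folds, seed = spec@seed,
                     clinicalFreq = p[["clinical"]])
  vocab <- gen$manifest$features
  tab <- out$selection
  sig <- vocab$featureId[vocab$signal]
  tested <- tab$featureId
  signalRecall <- mean(sig %in% tested[tab$selected])
  noise <- setdiff(tested, sig)
  noiseSel <- tab$selected[match(noise, tab$featureId)]
  pv <- tab$pValue[match(noise, tab$featureId)]
  names(pv) <- noise

  summ <- topicSummaries(out$topics,
                         nTop = min(20L, ncol(out$topics@H),
                                    nrow(out$topics@W)))
  overlap <- max(vapply(summ, function(s)
    length(intersect(s$features$item, sig)), 0L))
  topicSignalOverlap <- overlap / min(length(sig), nrow(summ[[1L]]$features))

  list(signalRecall = signalRecall,
       selectedFraction = mean(tab$selected),
       noiseSelectedFraction = mean(noiseSel),
       pValues = pv,
       proportions = categoryProportions(tab),
       accuracy = vapply(out$reports, function(r) r@metrics$accuracy, 0),
       auc = vapply(out$reports, function(r) r@auc, 0),
       topicSignalOverlap = topicSignalOverlap,
       cosine = out$cosine,
       pipeline = out, manifest = gen$manifest)
}
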