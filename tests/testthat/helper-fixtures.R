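# Shared fixtures, built in code at test time.

emptyAnn <- function() {
  data.frame(start = integer(), end = integer(), mention = character(),
             etype = character(), conceptId = character(),
             stringsAsFactors = FALSE)
}

# Bare annotated abstract around a single text string.
textAbstract <- function(txt, docId = "1", annotations = emptyAnn()) {
  new("AnnotatedAbstract", docId = docId, title = txt, abstract = "",
      year = NA_integer_, sentences = splitSentences(txt),
      annotations = annotations)
}

# Hand-built toy thesaurus: a three-level neoplasm chain, a genetic branch,
# and an unrelated descriptor, with multi-word and hyphenated entry terms.
toyThesaurus <- function() {
  MeshThesaurus(
    ids = c("D009369", "D008175", "D055728", "D030342", "D009154"),
    names = c("Neoplasms", "Lung Neoplasms", "Primary Lesions",
              "Genetic Diseases", "Mutation Concept"),
    treeNumbers = list("C04", c("C04.588", "C08.785"), "C04.588.894",
                       "G05.200", "G05.365"),
    entryTerms = list(
      c("Tumors", "Cancer"),
      c("Lung Cancer", "Pulmonary Neoplasms", "non-small cell lung cancer"),
      character(),
      c("Inherited Diseases"),
      character()))
}

# One handcrafted annotated abstract with 4 sentences and mixed annotations.
toyAbstract <- function() {
  title <- "EGFR mutations in lung cancer."
  abstract <- paste("The EGFR gene is often mutated.",
                    "Patients received gefitinib after diagnosis.",
                    "The V600E variant occurs in BRAF.")
  txt <- paste(title, abstract)
  locate <- function(mention, occurrence = 1L) {
    m <- gregexpr(mention, txt, fixed = TRUE)[[1L]]
    as.integer(m[occurrence]) - 1L
  }
  mention <- c("EGFR", "lung cancer", "EGFR", "gefitinib", "V600E", "BRAF")
  occ <- c(1L, 1L, 2L, 1L, 1L, 1L)
  start <- mapply(locate, mention, occ)
  ann <- data.frame(
    start = as.integer(start), end = as.integer(start + nchar(mention)),
    mention = mention,
    etype = c("Gene", "Disease", "Gene", "Chemical", "Mutation", "Gene"),
    conceptId = c("1956", "MESH:D008175", "1956", "MESH:D020123",
                  "p.V600E", "673"),
    stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  stopifnot(substring(txt, ann$start + 1L, ann$end) == ann$mention)
  new("AnnotatedAbstract", docId = "900001", title = title,
      abstract = abstract, year = 2018L, sentences = splitSentences(txt),
      annotations = ann)
}

# A small random toy thesaurus for property tests: ids D001..Dn with random
# tree paths of depth <= 3 under roots C04/G05/F01.
randomToyThesaurus <- function(n, seed) {
  set.seed(seed)
  roots <- c("C04", "G05", "F01")
  paths <- vapply(seq_len(n), function(i) {
    depth <- sample(0:3, 1L)
    paste(c(sample(roots, 1L), sprintf("%03d", sample(999, depth))),
          collapse = ".")
  }, "")
  MeshThesaurus(ids = sprintf("D%03d", seq_len(n)),
                names = sprintf("Concept %03d", seq_len(n)),
                treeNumbers = as.list(paths))
}

# Brute-force descendant oracle: strict dot-prefix scan over all pairs.
bruteDescendants <- function(thesaurus, id) {
  i <- match(id, thesaurus@ids)
  roots <- thesaurus@treeNumbers[[i]]
  hits <- vapply(seq_along(thesaurus@ids), function(j) {
    any(vapply(thesaurus@treeNumbers[[j]], function(tn) {
      any(vapply(roots, function(r) startsWith(tn, paste0(r, ".")), TRUE))
    }, TRUE))
  }, TRUE)
  sort(unique(c(id, thesaurus@ids[hits])))
}

# Hand 3x4 toy count matrix used by the formula-exactness checks.
toyCountMatrix <- function() {
  counts <- Matrix::Matrix(
    matrix(c(2, 1, 1, 0,
             1, 0, 3, 1,
             4, 0, 0, 2), nrow = 3, byrow = TRUE,
           dimnames = list(c("g1", "g2", "g3"), c("f1", "f2", "f3", "f4"))),
    sparse = TRUE)
  cats <- c(f1 = "cancer", f2 = "drug", f3 = "mutation", f4 = "phenotype")
  new("GeneTermMatrix", counts = as(counts, "generalMatrix"),
      scores = NULL, featureCategories = cats)
}

# Separable planted feature matrix: panel genes carry positive values in the
# signal columns, all other entries are shared background noise.
separableMatrix <- function(nGenes = 120, nPanel = 20, nSignal = 8,
                            nNoise = 20, seed = 42) {
  set.seed(seed)
  X <- matrix(stats::runif(nGenes * nNoise), nGenes, nNoise)
  sig <- matrix(0, nGenes, nSignal)
  sig[seq_len(nPanel), ] <- 1 + stats::runif(nPanel * nSignal)
  X <- cbind(sig, X)
  rownames(X) <- sprintf("g%04d", seq_len(nGenes))
  colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  y <- c(rep(1L, nPanel), rep(0L, nGenes - nPanel))
  names(y) <- rownames(X)
  list(X = X, y = y)
}

# Cached full-scale strong-signal study, shared by the acceptance checks
# that measure recovery under the reference conditions.
.fixtureCache <- new.env(parent = emptyenv())
strongSignalRun <- function() {
  if (is.null(.fixtureCache$strong)) {
    dir <- tempfile("strongstudy")
    res <- endToEndCheck(syntheticSpec(seed = 11), models = "linear_svm",
                         dir = dir)
    .fixtureCache$strong <- list(res = res, dir = dir,
                                 spec = syntheticSpec(seed = 11))
  }
  .fixtureCache$strong
}

# Small corpus + manifest for structural checks (fast to generate).
smallStudy <- function(seed = 7) {
  key <- paste0("small", seed)
  if (is.null(.fixtureCache[[key]])) {
    spec <- syntheticSpec(nGenes = 40, nPanel = 10, docsPerGene = 3,
                          seed = seed)
    dir <- tempfile("smallstudy")
    gen <- generateCorpus(spec, dir)
    .fixtureCache[[key]] <- list(spec = spec, gen = gen,
                                 corpus = readPubtator(gen$paths[["pubtator"]]),
                                 thes = readMeshTable(gen$paths[["mesh"]]),
                                 idx = readMeshIndexing(gen$paths[["indexing"]]),
                                 panel = readPanel(gen$paths[["panel"]]))
  }
  .fixtureCache[[key]]
}
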