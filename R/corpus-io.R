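# Readers and writers for the line-oriented exchange formats the pipeline
# consumes: the PubTator tab dialect (with a "|y|" year extension), the MeSH
# thesaurus TSV, the per-document MeSH indexing TSV, and panel gene lists.
# All offsets are 0-based half-open over "title + single space + abstract".

# Abbreviations that never terminate a sentence (lowercase, with period).
.ABBREV <- c("e.g.", "i.e.", "cf.", "vs.", "etc.", "fig.", "figs.", "al.",
             "et al.", "dr.", "prof.", "st.", "no.", "approx.", "ca.",
             "resp.", "ref.", "refs.", "spp.", "sp.")

#' Split text into sentence intervals
#'
#' Deterministic rule-based sentence segmentation. A sentence boundary is a
#' run of `.`, `!` or `?` followed by whitespace (or end of text) whose
#' preceding token is not on a fixed biomedical abbreviation stop-list
#' ("e.g.", "i.e.", "Fig.", "et al.", ...) and whose following character is
#' an uppercase letter, digit, or opening quote/parenthesis. Returned
#' intervals are 0-based half-open, sorted, non-overlapping, and jointly
#' cover every non-whitespace character.
#'
#' @param text a single character string.
#' @return `data.frame` with integer columns `start`, `end`.
#' @examples
#' splitSentences("A. B. C.")            # three intervals
#' splitSentences("Genes, e.g. EGFR, mutate. They matter.")  # two
#' @export
splitSentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  n <- nchar(text)
  if (n == 0L || !grepl("[^[:space:]]", text)) return(.emptySentences())

  bounds <- integer()
  m <- gregexpr("[.!?]+(?=[[:space:]]|$)", text, perl = TRUE)[[1L]]
  if (m[1L] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      tok <- tolower(sub(".*[[:space:](]", "", substr(text, 1L, e)))
      if (tok %in% .ABBREV) next
      # "et al." carries a space; check the two-token tail too
      tok2 <- tolower(sub(".*[[:space:]]([^[:space:]]+[[:space:]][^[:space:]]+)$",
                          "\\1", substr(text, 1L, e)))
      if (tok2 %in% .ABBREV) next
      nxt <- sub("^[[:space:]]*", "", substr(text, e + 1L, n))
      if (nzchar(nxt) && !grepl("^[A-Z0-9\"'(\\[]", nxt)) next
      bounds <- c(bounds, e)
    }
  }
  if (length(bounds) == 0L || bounds[length(bounds)] < n) bounds <- c(bounds, n)

  starts <- ends0 <- integer()
  pos <- 1L
  for (e in bounds) {
    seg <- substr(text, pos, e)
    first <- regexpr("[^[:space:]]", seg)
    if (first > 0L) {
      last <- nchar(sub("[[:space:]]+$", "", seg))
      starts <- c(starts, pos + first - 2L)   # 0-based
      ends0 <- c(ends0, pos + last - 1L)      # half-open
    }
    pos <- e + 1L
  }
  data.frame(start = starts, end = ends0)
}

.parseTitleLine <- function(line, tag) {
  pat <- paste0("^([^|\t]+)\\|", tag, "\\|(.*)$")
  if (!grepl(pat, line)) return(NULL)
  c(sub(pat, "\\1", line), sub(pat, "\\2", line))
}

#' Read a PubTator-format annotated corpus
#'
#' Parses the line-oriented PubTator exchange dialect: per document a
#' `PMID|t|title` line, a `PMID|a|abstract` line, an optional `PMID|y|YYYY`
#' publication-year line (a dialect extension of this package), then
#' tab-separated entity lines `PMID<TAB>start<TAB>end<TAB>mention<TAB>type
#' <TAB>conceptId`, with a blank line between documents. Offsets are 0-based
#' half-open over `title + " " + abstract`.
#'
#' When an entity line's mention does not equal the text slice at its
#' offsets, the offsets are trusted: the mention is recomputed from the text
#' and a warning names the line (annotated corpora in the wild contain
#' drifted offsets). Non-integer or out-of-bounds offsets are hard errors
#' naming the line.
#'
#' @param path file path (UTF-8).
#' @return list of [AnnotatedAbstract-class]; attribute `"noGene"` holds the
#'   ids of retained documents that carry no Gene annotation.
#' @seealso [writePubtator()]
#' @export
readPubtator <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) {
    out <- list()
    attr(out, "noGene") <- character()
    return(out)
  }
  isBlank <- !nzchar(trimws(lines))
  block <- cumsum(c(TRUE, isBlank[-length(isBlank)]))
  out <- list()
  for (b in unique(block[!isBlank])) {
    idx <- which(block == b & !isBlank)
    out[[length(out) + 1L]] <- .parsePubtatorBlock(lines[idx], idx)
  }
  names(out) <- vapply(out, function(a) a@docId, "")
  attr(out, "noGene") <- names(out)[!vapply(out, hasGeneAnnotation, TRUE)]
  out
}

.parsePubtatorBlock <- function(lines, lineNos) {
  title <- abstract <- ""
  docId <- NULL
  year <- NA_integer_
  ann <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!is.null(p <- .parseTitleLine(line, "t"))) {
      docId <- p[1L]; title <- p[2L]; next
    }
    if (!is.null(p <- .parseTitleLine(line, "a"))) {
      abstract <- p[2L]; next
    }
    if (!is.null(p <- .parseTitleLine(line, "y"))) {
      year <- suppressWarnings(as.integer(p[2L]))
      if (is.na(year))
        stop(sprintf("line %d: malformed year '%s'", lineNos[i], p[2L]))
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L)
      stop(sprintf("line %d: entity line needs 6 tab-separated fields", lineNos[i]))
    ann[[length(ann) + 1L]] <- c(f[1L:6L], lineNos[i])
  }
  if (is.null(docId)) stop("document block without a |t| line")
  txt <- if (nzchar(abstract)) paste(title, abstract) else title
  nAnn <- length(ann)
  adf <- .emptyAnnotations()
  if (nAnn) {
    m <- do.call(rbind, ann)
    start <- suppressWarnings(as.integer(m[, 2L]))
    end <- suppressWarnings(as.integer(m[, 3L]))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      stop(sprintf("line %s: malformed offset ('%s', '%s')",
                   m[bad[1L], 7L], m[bad[1L], 2L], m[bad[1L], 3L]))
    oob <- which(start < 0L | end > nchar(txt) | end <= start)
    if (length(oob))
      stop(sprintf("line %s: offset [%s,%s) out of bounds for document %s",
                   m[oob[1L], 7L], m[oob[1L], 2L], m[oob[1L], 3L], docId))
    mention <- m[, 4L]
    slice <- substring(txt, start + 1L, end)
    drift <- which(slice != mention)
    if (length(drift)) {
      warning(sprintf("line %s: mention does not match text slice; offsets trusted, mention recomputed",
                      paste(m[drift, 7L], collapse = ",")))
      mention[drift] <- slice[drift]
    }
    adf <- data.frame(start = start, end = end, mention = mention,
                      etype = m[, 5L], conceptId = m[, 6L],
                      stringsAsFactors = FALSE)
  }
  new("AnnotatedAbstract", docId = docId, title = title, abstract = abstract,
      year = year, sentences = splitSentences(txt), annotations = adf)
}

#' Write a corpus in the PubTator dialect
#'
#' Inverse of [readPubtator()]: writes each document's `|t|`, `|a|`, and
#' (when the year is present) `|y|` lines followed by its entity lines in
#' stored order, with a blank line after every document. Round-trips
#' byte-identically for canonical corpora.
#'
#' @param abstracts list of [AnnotatedAbstract-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePubtator <- function(abstracts, path) {
  blocks <- vapply(abstracts, function(a) {
    lines <- c(paste0(a@docId, "|t|", a@title),
               paste0(a@docId, "|a|", a@abstract))
    if (!is.na(a@year)) lines <- c(lines, paste0(a@docId, "|y|", a@year))
    if (nrow(a@annotations)) {
      ann <- a@annotations
      lines <- c(lines, paste(a@docId, ann$start, ann$end, ann$mention,
                              ann$etype, ann$conceptId, sep = "\t"))
    }
    paste0(paste(lines, collapse = "\n"), "\n")
  }, "")
  writeLines(blocks, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Filter a corpus by publication year
#'
#' Keeps documents whose year lies in `[yearLo, yearHi]`. Documents without
#' a year are dropped and counted in the `"droppedNoYear"` attribute of the
#' result; the `"droppedOutOfRange"` attribute counts in-corpus documents
#' outside the range.
#'
#' @param abstracts list of [AnnotatedAbstract-class].
#' @param yearLo,yearHi inclusive year bounds, `yearLo <= yearHi`.
#' @return filtered list with the two drop-count attributes.
#' @export
filterByYear <- function(abstracts, yearLo, yearHi) {
  if (yearLo > yearHi) stop("yearLo must not exceed yearHi")
  years <- vapply(abstracts, function(a) a@year, 1L)
  noYear <- is.na(years)
  keep <- !noYear & years >= yearLo & years <= yearHi
  out <- abstracts[keep]
  attr(out, "droppedNoYear") <- sum(noYear)
  attr(out, "droppedOutOfRange") <- sum(!keep & !noYear)
  out
}

#' Read a gene panel list
#'
#' One gene identifier per line; blank lines ignored, duplicates removed.
#'
#' @param path file path.
#' @param name panel name (default: file base name).
#' @return a [GenePanel-class].
#' @export
readPanel <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  genes <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("empty panel file: ", path)
  GenePanel(name, genes)
}

#' Write a gene panel list
#' @param panel a [GenePanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
  writeLines(panel@genes, path, useBytes = TRUE)
  invisible(path)
}

#' Read a MeSH thesaurus table
#'
#' Tab-separated with header columns `descriptor_id`, `name`,
#' `tree_numbers` (pipe-separated), `entry_terms` (pipe-separated; may be
#' empty — the preferred name always counts as an entry term). Duplicate
#' descriptor ids are an error naming the id.
#'
#' @param path file path.
#' @return a [MeshThesaurus-class].
#' @export
readMeshTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  need <- c("descriptor_id", "name", "tree_numbers", "entry_terms")
  if (!all(need %in% names(tab)))
    stop("MeSH table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$descriptor_id))
    stop("duplicate descriptor id: ",
         tab$descriptor_id[duplicated(tab$descriptor_id)][1L])
  splitPipe <- function(x) {
    out <- strsplit(x, "|", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  MeshThesaurus(ids = tab$descriptor_id, names = tab$name,
                treeNumbers = splitPipe(tab$tree_numbers),
                entryTerms = splitPipe(tab$entry_terms))
}

#' Write a MeSH thesaurus table
#' @param thesaurus a [MeshThesaurus-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMeshTable <- function(thesaurus, path) {
  joinPipe <- function(l) vapply(l, paste, "", collapse = "|")
  # preferred name is implicit; keep remaining synonyms
  extra <- mapply(function(nm, et) setdiff(et, nm),
                  thesaurus@names, thesaurus@entryTerms, SIMPLIFY = FALSE)
  tab <- data.frame(descriptor_id = thesaurus@ids, name = thesaurus@names,
                    tree_numbers = joinPipe(thesaurus@treeNumbers),
                    entry_terms = joinPipe(extra), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-document MeSH indexing table
#'
#' Tab-separated with header columns `doc_id` and `descriptor_ids`
#' (pipe-separated descriptor ids curators assigned to the article).
#'
#' @param path file path.
#' @return named list: `doc_id` -> character vector of descriptor ids.
#' @export
readMeshIndexing <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (!all(c("doc_id", "descriptor_ids") %in% names(tab)))
    stop("indexing table must have columns doc_id, descriptor_ids")
  out <- strsplit(tab$descriptor_ids, "|", fixed = TRUE)
  out <- lapply(out, function(v) v[nzchar(v)])
  names(out) <- tab$doc_id
  out
}

#' Write a per-document MeSH indexing table
#' @param indexing named list doc_id -> descriptor ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMeshIndexing <- function(indexing, path) {
  tab <- data.frame(doc_id = names(indexing),
                    descriptor_ids = vapply(indexing, paste, "", collapse = "|"),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
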