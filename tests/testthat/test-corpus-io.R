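test_that("splitSentences segments simple and abbreviation-bearing text", {
  s <- splitSentences("A. B. C.")
  expect_equal(nrow(s), 3L)
  expect_equal(s$start, c(0L, 3L, 6L))
  expect_equal(s$end, c(2L, 5L, 8L))

  # abbreviation periods do not split
  s2 <- splitSentences("Genes, e.g. EGFR, mutate often. They matter.")
  expect_equal(nrow(s2), 2L)
  s3 <- splitSentences("As shown by Smith et al. nothing changed.")
  expect_equal(nrow(s3), 1L)  # "et al." never terminates a sentence
  s3b <- splitSentences("Described in Fig. 2 of the study. Results follow.")
  expect_equal(nrow(s3b), 2L)  # "Fig." does not split even before a digit

  # lowercase continuation is not a boundary
  s4 <- splitSentences("The p. value was small.")
  expect_equal(nrow(s4), 1L)

  expect_equal(nrow(splitSentences("   \t ")), 0L)
})

test_that("splitSentences intervals partition the non-delimiter text", {
  texts <- c(
    "One sentence only",
    "First sentence. Second one!  Third?",
    "Trailing text without punct. and lowercase tail",
    abstractText(toyAbstract()))
  for (txt in texts) {
    s <- splitSentences(txt)
    expect_true(all(s$end > s$start))
    expect_true(!is.unsorted(s$start))
    if (nrow(s) > 1L) expect_true(all(s$start[-1L] >= s$end[-nrow(s)]))
    # every non-whitespace character is covered by exactly one interval
    chars <- strsplit(txt, "")[[1L]]
    covered <- rep(FALSE, nchar(txt))
    for (i in seq_len(nrow(s)))
      covered[(s$start[i] + 1L):s$end[i]] <- TRUE
    expect_true(all(covered[chars != " " & chars != "\t"]))
  }
})

test_that("splitSentences recovers the generator's planted sentence counts", {
  st <- smallStudy()
  nSen <- vapply(st$corpus, function(a) nrow(a@sentences), 1L)
  expect_true(all(nSen == st$spec@sentencesPerDoc))
})

test_that("readPubtator parses documents, annotations and years", {
  f <- tempfile()
  writeLines(c(
    "101|t|Alpha beta gamma.",
    "101|a|Delta epsilon zeta.",
    "101|y|2015",
    "101\t0\t5\tAlpha\tGene\t11",
    "101\t6\t10\tbeta\tDisease\tMESH:D1",
    "101\t18\t23\tDelta\tChemical\tMESH:D2",
    "",
    "102|t|Eta theta.",
    "102|a|Iota kappa.",
    "102\t0\t3\tEta\tGene\t22",
    "102\t4\t9\ttheta\tMutation\tV1M",
    "102\t11\t15\tIota\tSpecies\t9606",
    ""), f)
  docs <- readPubtator(f)
  expect_length(docs, 2L)
  expect_equal(vapply(docs, function(a) nrow(a@annotations), 1L),
               c("101" = 3L, "102" = 3L))
  expect_equal(docs[["101"]]@year, 2015L)
  expect_true(is.na(docs[["102"]]@year))
  expect_equal(attr(docs, "noGene"), character())
  for (a in docs) expect_true(validObject(a))
})

test_that("readPubtator trusts offsets over drifted mentions, errors on bad offsets", {
  f <- tempfile()
  writeLines(c("201|t|Alpha beta.", "201|a|Gamma delta.",
               "201\t0\t5\tWRONG\tGene\t1"), f)
  expect_warning(docs <- readPubtator(f), "mention does not match")
  expect_equal(docs[[1L]]@annotations$mention, "Alpha")

  writeLines(c("202|t|Alpha beta.", "202|a|Gamma.",
               "202\t0\txx\tAlpha\tGene\t1"), f)
  expect_error(readPubtator(f), "line 3.*malformed offset")
  writeLines(c("203|t|Alpha.", "203|a|B.", "203\t0\t99\tAlpha\tGene\t1"), f)
  expect_error(readPubtator(f), "out of bounds")

  writeLines(character(), f)
  expect_length(readPubtator(f), 0L)
})

test_that("synthetic corpus round-trips byte-identically through write/read", {
  st <- smallStudy()
  f2 <- tempfile()
  writePubtator(st$corpus, f2)
  expect_identical(readLines(f2), readLines(st$gen$paths[["pubtator"]]))
  # and structural equality after a second read
  again <- readPubtator(f2)
  expect_identical(names(again), names(st$corpus))
  expect_identical(lapply(again, function(a) a@annotations),
                   lapply(st$corpus, function(a) a@annotations))
})

test_that("filterByYear slices by year and accounts for every document", {
  st <- smallStudy()
  yrs <- vapply(st$corpus, function(a) a@year, 1L)
  out <- filterByYear(st$corpus, 2011, 2019)
  expect_length(out, length(st$corpus))          # all years inside range
  expect_length(filterByYear(st$corpus, 1990, 1995), 0L)

  out2 <- filterByYear(st$corpus, 2011, 2015)
  expect_length(out2, sum(yrs <= 2015))          # planted year histogram
  expect_equal(length(out2) + attr(out2, "droppedOutOfRange") +
                 attr(out2, "droppedNoYear"), length(st$corpus))
  expect_error(filterByYear(st$corpus, 2019, 2011), "yearLo")

  # documents lacking a year are dropped and counted
  noYear <- st$corpus[[1L]]
  noYear@year <- NA_integer_
  mixed <- c(list(noYear), st$corpus[2:4])
  out3 <- filterByYear(mixed, 2000, 2030)
  expect_length(out3, 3L)
  expect_equal(attr(out3, "droppedNoYear"), 1L)
})

test_that("readPanel deduplicates and rejects empty files; 410-line panel loads fully", {
  f <- tempfile()
  writeLines(c("TP53", "EGFR", "TP53", "", "BRAF"), f)
  p <- readPanel(f, name = "toy")
  expect_s4_class(p, "GenePanel")
  expect_length(p, 3L)

  genes410 <- sprintf("GENE%04d", seq_len(410))
  writeLines(genes410, f)
  expect_length(readPanel(f), 410L)

  writeLines(character(), f)
  expect_error(readPanel(f), "empty panel")
})

test_that("MeSH thesaurus and indexing tables round-trip; duplicates rejected", {
  thes <- toyThesaurus()
  f <- tempfile()
  writeMeshTable(thes, f)
  back <- readMeshTable(f)
  expect_identical(back@ids, thes@ids)
  expect_identical(back@treeNumbers, thes@treeNumbers)
  expect_identical(lapply(back@entryTerms, sort),
                   lapply(thes@entryTerms, sort))

  tab <- utils::read.delim(f, colClasses = "character", quote = "")
  tab <- rbind(tab, tab[1L, ])
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readMeshTable(f), "duplicate descriptor id: D009369")

  idx <- list("900001" = c("D008175", "D030342"), "900002" = "D009369")
  f2 <- tempfile()
  writeMeshIndexing(idx, f2)
  expect_identical(readMeshIndexing(f2), idx)
})
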