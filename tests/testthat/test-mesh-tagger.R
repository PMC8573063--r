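test_that("meshDescendants returns the subtree closure", {
  thes <- toyThesaurus()
  # chain C04 -> C04.588 -> C04.588.894
  expect_setequal(meshDescendants(thes, "D009369"),
                  c("D009369", "D008175", "D055728"))
  expect_equal(meshDescendants(thes, "D055728"), "D055728")  # leaf
  expect_equal(meshDescendants(thes, "D030342"), "D030342")
  expect_error(meshDescendants(thes, "D999999"), "unknown descriptor")
})

test_that("descendant closure matches the brute-force prefix scan and nests", {
  for (seed in 1:5) {
    thes <- randomToyThesaurus(30, seed)
    for (id in thes@ids)
      expect_identical(meshDescendants(thes, id), bruteDescendants(thes, id))
    # nesting: descendants(child) is a subset of descendants(parent)
    for (i in seq_along(thes@ids)) {
      kids <- setdiff(meshDescendants(thes, thes@ids[i]), thes@ids[i])
      for (kid in kids)
        expect_true(all(meshDescendants(thes, kid) %in%
                          meshDescendants(thes, thes@ids[i])))
    }
  }
})

test_that("buildMappingSet unions indexed subtrees", {
  thes <- toyThesaurus()
  expect_equal(buildMappingSet(thes, character()), character())
  # two roots with disjoint subtrees
  expect_setequal(buildMappingSet(thes, c("D008175", "D030342")),
                  c("D008175", "D055728", "D030342"))
  # whole-tree root covers its entire branch
  expect_setequal(buildMappingSet(thes, "D009369"),
                  c("D009369", "D008175", "D055728"))
  expect_error(buildMappingSet(thes, "nope"), "unknown descriptor")
})

test_that("entry terms of indexed descriptors are tagged with their descriptor id", {
  thes <- toyThesaurus()
  title <- "Lung cancer screening."
  abstract <- "We discuss lung cancer and inherited diseases in this report."
  a <- textAbstract(paste(title, abstract))
  ann <- tagWithMesh(a, thes, "D008175")
  # both case variants of the "Lung Cancer" entry term, nothing else
  expect_equal(nrow(ann), 2L)
  expect_true(all(ann$conceptId == "D008175"))
  expect_true(all(ann$etype == "MeSH"))
  expect_setequal(ann$mention, c("Lung cancer", "lung cancer"))
  # indexing the genetic branch adds the "Inherited Diseases" match
  ann2 <- tagWithMesh(a, thes, c("D008175", "D030342"))
  expect_equal(nrow(ann2), 3L)
  expect_true("D030342" %in% ann2$conceptId)
  # no occurrence -> no annotations
  expect_equal(nrow(tagWithMesh(a, thes, "D055728")), 0L)
  # every emitted id stays within the mapping set
  expect_true(all(ann2$conceptId %in% buildMappingSet(thes, c("D008175", "D030342"))))
})

test_that("matching is case-insensitive and hyphen/space equivalent", {
  thes <- toyThesaurus()
  mk <- textAbstract
  hy <- tagWithMesh(mk("Cases of non-small cell lung cancer increased."),
                    thes, "D008175")
  sp <- tagWithMesh(mk("Cases of non small cell lung cancer increased."),
                    thes, "D008175")
  expect_equal(nrow(hy), 1L)
  expect_equal(hy$mention, "non-small cell lung cancer")  # longest match wins
  expect_equal(sp$conceptId, hy$conceptId)
  expect_equal(sp$start, hy$start)
  # case-folding invariance
  up <- tagWithMesh(mk("NON-SMALL CELL LUNG CANCER cases."), thes, "D008175")
  expect_equal(up$conceptId, hy$conceptId)
  # whole-token only: no match inside a longer word
  expect_equal(nrow(tagWithMesh(mk("The tumorsuppressor acts."), thes,
                                "D009369")), 0L)
})

test_that("existing annotations take precedence and tagging is idempotent", {
  thes <- toyThesaurus()
  a <- toyAbstract()  # already has a Disease annotation on "lung cancer"
  ann <- tagWithMesh(a, thes, c("D009369", "D008175"))
  # the PubTator-annotated "lung cancer" span must not be double-tagged
  expect_false(any(ann$start < 29 & ann$end > 18))
  merged <- tagCorpus(list(a), thes, list("900001" = c("D009369", "D008175")))
  again <- tagCorpus(merged, thes, list("900001" = c("D009369", "D008175")))
  expect_identical(merged[[1L]]@annotations, again[[1L]]@annotations)
})

test_that("matches never span a sentence boundary", {
  thes <- MeshThesaurus(ids = "D1", names = "Split Phrase",
                        treeNumbers = list("C04.1"),
                        entryTerms = list("cancer screening"))
  txt <- "We study cancer. Screening follows."
  a <- textAbstract(txt)
  expect_equal(nrow(tagWithMesh(a, thes, "D1")), 0L)
})

test_that("planted untagged entry-term mentions are recovered with recall 1", {
  st <- smallStudy()
  tagged <- tagCorpus(st$corpus, st$thes, st$idx)
  m <- st$gen$manifest$mentions
  unt <- m[!m$tagged, , drop = FALSE]
  expect_gt(nrow(unt), 0L)
  found <- vapply(seq_len(nrow(unt)), function(i) {
    ann <- tagged[[unt$docId[i]]]@annotations
    any(ann$etype == "MeSH" & ann$conceptId == unt$featureId[i])
  }, TRUE)
  expect_equal(mean(found), 1.0)
})

test_that("categorizeFeatures maps annotation types to the five groups", {
  thes <- toyThesaurus()
  expect_equal(categorizeFeatures("Mutation", "p.V600E"), "mutation")
  expect_equal(categorizeFeatures("Chemical", "MESH:D020123"), "drug")
  expect_equal(categorizeFeatures("Disease", "MESH:D008175"), "cancer")
  expect_equal(categorizeFeatures("Gene", "673"), "phenotype")
  # MeSH features routed by tree branch
  expect_equal(
    categorizeFeatures(rep("MeSH", 3), c("D055728", "D030342", "D009154"),
                       thes),
    c("cancer", "genetic_phenomena", "genetic_phenomena"))
  # non-default branch roots are honoured
  expect_equal(categorizeFeatures("MeSH", "D030342", thes,
                                  geneticRoot = "X99"), "phenotype")
  expect_warning(out <- categorizeFeatures("MeSH", "D404040", thes),
                 "unknown MeSH descriptor")
  expect_equal(out, "phenotype")
})
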