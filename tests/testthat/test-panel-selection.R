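# Independent enumeration oracle: direct choose() arithmetic over the
# support, no log-space tricks.
pmfOracle <- function(N, Ns, Nt, y)
  choose(Nt, y) * choose(N - Nt, Ns - y) / choose(N, Ns)
pvalueOracle <- function(N, Ns, Nt, Nst) {
  hi <- min(Ns, Nt)
  if (Nst > hi) return(0)
  sum(pmfOracle(N, Ns, Nt, max(Nst, max(0, Ns - (N - Nt))):hi))
}

test_that("hypergeomPmf matches hand arithmetic and normalizes", {
  expect_equal(hypergeomPmf(10, 10, 4, 4), 1.0, tolerance = 1e-14)
  expect_equal(hypergeomPmf(10, 3, 4, 2), 0.3, tolerance = 1e-14)  # 36/120
  expect_identical(hypergeomPmf(10, 3, 4, 5), 0)   # outside support
  expect_identical(hypergeomPmf(10, 3, 4, -1), 0)
  set.seed(4)
  for (i in 1:200) {
    N <- sample(2:60, 1L)
    Ns <- sample(N, 1L)
    Nt <- sample(0:N, 1L)
    lo <- max(0, Ns - (N - Nt))
    expect_equal(sum(hypergeomPmf(N, Ns, Nt, lo:min(Ns, Nt))), 1,
                 tolerance = 1e-12)
  }
})

test_that("hypergeomPvalue equals exhaustive enumeration and stats::phyper", {
  expect_equal(hypergeomPvalue(10, 3, 4, 0), 1.0)
  expect_equal(hypergeomPvalue(10, 3, 4, 2), 1 / 3, tolerance = 1e-14)
  set.seed(9)
  for (i in 1:300) {
    N <- sample(2:80, 1L)
    Ns <- sample(N, 1L)
    Nt <- sample(0:N, 1L)
    Nst <- sample(0:min(Ns, Nt), 1L)
    p <- hypergeomPvalue(N, Ns, Nt, Nst)
    expect_equal(p, pvalueOracle(N, Ns, Nt, Nst), tolerance = 1e-12)
    # independent library formulation as a cross-check
    expect_equal(p, min(1, stats::phyper(Nst - 1, Nt, N - Nt, Ns,
                                         lower.tail = FALSE)),
                 tolerance = 1e-12)
  }
  expect_error(hypergeomPvalue(10, 11, 4, 0), "invalid hypergeometric")
  expect_error(hypergeomPvalue(10, 3, 4, 4), "Nst must satisfy")
})

test_that("p-value is monotone non-increasing in Nst and avoids underflow", {
  ps <- vapply(0:12, function(n) hypergeomPvalue(40, 12, 18, n), 0)
  expect_true(all(diff(ps) <= 1e-15))
  # large counts: log-space accumulation keeps deep tails accurate
  p <- hypergeomPvalue(2000, 200, 150, 100)
  expect_gt(p, 0)
  expect_lt(p, 1e-60)
  expect_equal(p, stats::phyper(99, 150, 1850, 200, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("buildBackground is exhaustive, deterministic, and errors sensibly", {
  genes <- sprintf("g%03d", 1:60)
  panel <- GenePanel("p", genes[1:10])
  expect_warning(bg <- buildBackground(genes, panel, nRandom = 60, seed = 1),
                 "taking all")
  expect_setequal(bg, genes)               # pool smaller than nRandom
  b1 <- buildBackground(genes, panel, nRandom = 20, seed = 5)
  b2 <- buildBackground(genes, panel, nRandom = 20, seed = 5)
  expect_identical(b1, b2)
  expect_length(b1, 30L)
  expect_true(all(genes[1:10] %in% b1))
  outside <- GenePanel("q", c("zz1", "zz2"))
  expect_error(buildBackground(genes, outside, 20, 1), "no genes in common")
})

test_that("background sampling frequencies follow the binomial law over seeds", {
  genes <- sprintf("g%03d", 1:60)
  panel <- GenePanel("p", genes[1:10])
  pool <- genes[11:60]
  nRandom <- 20L
  nSeeds <- 1000L
  hits <- integer(length(pool))
  names(hits) <- pool
  for (s in seq_len(nSeeds)) {
    bg <- buildBackground(genes, panel, nRandom = nRandom, seed = s)
    drawn <- setdiff(bg, genes[1:10])
    hits[drawn] <- hits[drawn] + 1L
  }
  p <- nRandom / length(pool)
  sigma <- sqrt(p * (1 - p) / nSeeds)
  expect_true(all(abs(hits / nSeeds - p) <= 3 * sigma + 1e-9))
})

test_that("selectFeatures separates planted signal from noise columns", {
  # 60 genes, 12-gene panel; signal features present in most panel genes,
  # noise features spread uniformly
  set.seed(21)
  genes <- sprintf("g%03d", 1:60)
  panel <- GenePanel("p", genes[1:12])
  feats <- c(sprintf("sig%02d", 1:4), sprintf("noise%02d", 1:16))
  m <- matrix(0, 60, 20, dimnames = list(genes, feats))
  m[1:12, 1:4] <- rbinom(48, 1, 0.9)
  m[, 5:20] <- rbinom(60 * 16, 1, 0.25)
  m[13:60, 1:4] <- rbinom(48 * 4, 1, 0.25)
  cats <- setNames(rep(c("cancer", "phenotype"), c(4, 16)), feats)
  gtm <- buildTfidf(new("GeneTermMatrix",
                        counts = as(Matrix::Matrix(m, sparse = TRUE),
                                    "generalMatrix"),
                        scores = NULL, featureCategories = cats))
  sel <- selectFeatures(gtm, panel, alpha = 0.05, nRandom = 48, seed = 3)
  tab <- sel$table
  sigP <- tab$pValue[startsWith(tab$featureId, "sig")]
  noiseP <- tab$pValue[startsWith(tab$featureId, "noise")]
  expect_lt(max(sigP), min(noiseP))
  expect_true(all(tab$selected[startsWith(tab$featureId, "sig")]))
  # selection flag is exactly p <= alpha
  expect_identical(tab$selected, tab$pValue <= 0.05)
  # filtered matrix keeps all genes, restricts columns
  expect_identical(geneIds(sel$matrix), genes)
  expect_identical(featureIds(sel$matrix), tab$featureId[tab$selected])

  # alpha = 1 removes nothing; selection is monotone in alpha
  selAll <- selectFeatures(gtm, panel, alpha = 1, nRandom = 48, seed = 3)
  expect_true(all(selAll$table$selected))
  sel01 <- selectFeatures(gtm, panel, alpha = 0.01, nRandom = 48, seed = 3)
  expect_true(all(sel01$table$featureId[sel01$table$selected] %in%
                    tab$featureId[tab$selected]))
  expect_error(selectFeatures(gtm, panel, alpha = 0), "alpha")

  # category proportions shift toward the planted cancer signal
  props <- categoryProportions(tab)
  cancer <- props[props$category == "cancer", ]
  expect_gt(cancer$after, cancer$before)
})
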