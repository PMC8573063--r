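# Rank-statistic oracle: AUC as the normalized Mann-Whitney U with
# midranks for ties.
aucOracle <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

test_that("makeLabels flags panel membership and rejects degenerate labelings", {
  genes <- sprintf("g%03d", 1:60)
  panel <- GenePanel("p", genes[1:10])
  gtm <- buildTfidf(toyCountMatrix())
  y <- makeLabels(genes, panel)
  expect_equal(sum(y), 10L)
  expect_named(y, genes)
  # id alignment, not positional: permuted genes give permuted labels
  yPerm <- makeLabels(rev(genes), panel)
  expect_identical(yPerm[genes], y)
  expect_error(makeLabels(genes[1:5], panel), "both classes")
  expect_error(makeLabels(genes[11:20], GenePanel("q", "zzz")), "both classes")
})

test_that("every gene is predicted exactly once out of fold", {
  d <- separableMatrix(nGenes = 100, nPanel = 25)
  rep <- crossValidate(d$X, d$y, "decision_tree", folds = 5, seed = 2)
  pr <- rep@predictions
  expect_equal(nrow(pr), 100L)
  expect_setequal(pr$gene, rownames(d$X))
  expect_equal(sort(unique(pr$fold)), 1:5)
  # stratification: each fold holds both classes
  byFold <- table(pr$fold, pr$label)
  expect_true(all(byFold > 0))
  # confusion entries sum to n
  m <- rep@metrics
  expect_equal(sum(pr$predicted == pr$label) + sum(pr$predicted != pr$label),
               100L)
})

test_that("separable planted data is classified perfectly by the linear SVM", {
  d <- separableMatrix()
  rep <- crossValidate(d$X, d$y, "linear_svm", folds = 5, seed = 7)
  expect_equal(rep@metrics$accuracy, 1.0)
  expect_gte(rep@auc, 0.95)
  expect_equal(rep@metrics$target$f1, 1.0)
})

test_that("all seven families run, are deterministic, and stay in range", {
  d <- separableMatrix(nGenes = 60, nPanel = 15, nSignal = 5, nNoise = 8)
  for (m in classifierModels()) {
    r1 <- crossValidate(d$X, d$y, m, folds = 3, seed = 4)
    r2 <- crossValidate(d$X, d$y, m, folds = 3, seed = 4)
    expect_identical(r1@predictions, r2@predictions)
    expect_true(all(unlist(r1@metrics) >= 0 & unlist(r1@metrics) <= 1))
    expect_gte(r1@metrics$accuracy, 0.8)  # planted signal is easy
  }
  expect_error(crossValidate(d$X, d$y, "boosted_stumps"), "arg")
})

test_that("permuted labels score near the majority-class rate", {
  d <- separableMatrix(nGenes = 100, nPanel = 25)
  maj <- 0.75
  sigma <- sqrt(maj * (1 - maj) / length(d$y))
  accs <- vapply(1:20, function(s) {
    yPerm <- withr::with_seed(s, sample(d$y))
    names(yPerm) <- names(d$y)
    crossValidate(d$X, yPerm, "linear_svm", folds = 5, seed = s)@metrics$accuracy
  }, 0)
  expect_true(all(abs(accs - maj) <= 3 * sigma))
})

test_that("rocAuc matches the rank statistic and basic ROC geometry", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(20:60, 1L)
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2L) next
    s <- round(rnorm(n), sample(0:2, 1L))  # rounding forces ties
    out <- rocAuc(s, y)
    expect_equal(out$auc, aucOracle(s, y), tolerance = 1e-12)
    # sign reversal maps AUC to its complement
    expect_equal(rocAuc(-s, y)$auc, 1 - out$auc, tolerance = 1e-12)
    roc <- out$roc
    expect_equal(roc$fpr[1L], 0)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(!is.unsorted(roc$fpr) && !is.unsorted(roc$tpr))
  }
  y <- c(1L, 1L, 0L, 0L, 1L)
  expect_equal(rocAuc(rep(2, 5), y)$auc, 0.5)       # constant scores
  expect_equal(rocAuc(y, y)$auc, 1.0)               # scores = labels
  # invariant under strictly increasing transforms
  s <- rnorm(5)
  expect_equal(rocAuc(exp(s), y)$auc, rocAuc(s, y)$auc)
  expect_error(rocAuc(1:5, rep(1L, 5)), "both classes")
})

test_that("rocAuc agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rep(c(0L, 1L), each = 30)
  s <- rnorm(60) + y
  ours <- rocAuc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("classifier reports serialize losslessly", {
  d <- separableMatrix(nGenes = 60, nPanel = 15, nSignal = 5, nNoise = 8)
  reps <- benchmarkClassifiers(d$X, d$y, models = c("linear_svm", "naive_bayes"),
                               folds = 3, seed = 9)
  dir <- tempfile()
  writeClassifierReports(reps, dir)
  tab <- utils::read.delim(file.path(dir, "metrics.tsv"))
  expect_equal(tab$accuracy,
               vapply(reps, function(r) r@metrics$accuracy, 0),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(tab$auc, vapply(reps, function(r) r@auc, 0),
               ignore_attr = TRUE, tolerance = 1e-9)
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$linear_svm$metrics$accuracy,
               reps$linear_svm@metrics$accuracy, tolerance = 1e-12)
  expect_equal(js$linear_svm$predictions$predicted,
               reps$linear_svm@predictions$predicted)
})
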