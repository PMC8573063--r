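# Panel-membership classification: label genes target/non-target for a
# panel and benchmark seven classifier families with stratified 5-fold
# cross-validation, reporting accuracy, per-class precision/recall/F1, and
# ROC/AUC on pooled out-of-fold predictions.

#' Supported classifier families
#' @return character vector of model names accepted by [crossValidate()].
#' @export
classifierModels <- function() {
  c("nearest_neighbors", "linear_svm", "gaussian_process", "decision_tree",
    "random_forest", "neural_net", "naive_bayes")
}

#' Label matrix genes by panel membership
#'
#' Label 1 ("target") for genes in the panel, 0 otherwise. Errors when a
#' class is empty, since cross-validation is then undefined.
#'
#' @param gtm a [GeneTermMatrix-class] (or character vector of gene ids).
#' @param panel a [GenePanel-class].
#' @return named integer vector of 0/1 labels, one per gene.
#' @export
makeLabels <- function(gtm, panel) {
  genes <- if (is.character(gtm)) gtm else geneIds(gtm)
  y <- as.integer(genes %in% panel@genes)
  names(y) <- genes
  if (all(y == 1L) || all(y == 0L))
    stop(sprintf("need both classes: %d target, %d non-target genes",
                 sum(y), sum(y == 0L)))
  y
}

# Stratified fold assignment: within each class, shuffle and deal out
# round-robin, so every fold holds both classes when n per class >= folds.
.stratifiedFolds <- function(y, folds, seed) {
  fold <- integer(length(y))
  withSeed(seed, for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  })
  fold
}

# Each fitter returns list(class = 0/1 predictions, score = continuous
# decision score oriented so larger favors the target class). Library
# defaults are used throughout; models with internal randomness are run
# under the fold seed.
.fitPredict <- function(model, xtr, ytr, xte, seed) {
  ytrF <- factor(ytr, levels = c(0L, 1L))
  withSeed(seed, switch(model,
    nearest_neighbors = {
      pred <- class::knn(xtr, xte, cl = ytrF, k = 5L, prob = TRUE)
      pwin <- attr(pred, "prob")
      cls <- as.integer(as.character(pred))
      list(class = cls, score = ifelse(cls == 1L, pwin, 1 - pwin))
    },
    linear_svm = {
      fit <- e1071::svm(xtr, ytrF, kernel = "linear", scale = FALSE)
      pred <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # orient decision values toward the target level
      sgn <- if (startsWith(colnames(dv)[1L], "1")) 1 else -1
      list(class = as.integer(as.character(pred)), score = sgn * dv[, 1L])
    },
    gaussian_process = {
      # gausspr chats about sigma estimation on stdout; keep output clean
      utils::capture.output(suppressMessages(
        fit <- kernlab::gausspr(xtr, ytrF)))
      prob <- kernlab::predict(fit, xte, type = "probabilities")
      p1 <- prob[, colnames(prob) == "1"]
      list(class = as.integer(p1 >= 0.5), score = p1)
    },
    decision_tree = {
      d <- data.frame(xtr)
      d$.y <- ytrF
      fit <- rpart::rpart(.y ~ ., data = d, method = "class")
      p1 <- stats::predict(fit, data.frame(xte), type = "prob")[, "1"]
      list(class = as.integer(p1 >= 0.5), score = p1)
    },
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytrF)
      p1 <- stats::predict(fit, xte, type = "prob")[, "1"]
      cls <- as.integer(as.character(stats::predict(fit, xte)))
      list(class = cls, score = p1)
    },
    neural_net = {
      fit <- nnet::nnet(xtr, ytr, size = 8L, decay = 5e-4, maxit = 200L,
                        trace = FALSE)
      p1 <- as.numeric(stats::predict(fit, xte))
      list(class = as.integer(p1 >= 0.5), score = p1)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytrF)
      p1 <- stats::predict(fit, xte, type = "raw")[, "1"]
      list(class = as.integer(p1 >= 0.5), score = p1)
    },
    stop("unknown model_spec: ", model)
  ))
}

#' Cross-validate a panel-membership classifier
#'
#' Stratified k-fold cross-validation of one of the seven supported model
#' families, with metrics computed on the pooled out-of-fold predictions
#' (every gene is predicted exactly once, by the model that did not see
#' it). Models keep their library default hyperparameters; any internal
#' randomness runs under `seed`, so results are reproducible.
#'
#' @param X numeric feature matrix, genes x features (typically
#'   `as.matrix(tfidfScores(gtm))`).
#' @param y 0/1 labels from [makeLabels()].
#' @param model one of [classifierModels()].
#' @param folds number of folds (default 5).
#' @param seed integer seed fixing the fold split and model randomness.
#' @return a [ClassifierReport-class].
#' @export
crossValidate <- function(X, y, model, folds = 5, seed = 1) {
  model <- match.arg(model, classifierModels())
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) != 2L) stop("need both classes present")
  if (min(table(y)) < folds)
    stop("too few members of the minority class for ", folds, " folds")
  fold <- .stratifiedFolds(y, folds, seed)
  pred <- integer(length(y))
  score <- numeric(length(y))
  for (f in seq_len(folds)) {
    te <- fold == f
    out <- .fitPredict(model, X[!te, , drop = FALSE], y[!te],
                       X[te, , drop = FALSE], seed + f)
    pred[te] <- out$class
    score[te] <- out$score
  }
  genes <- if (!is.null(names(y))) names(y) else as.character(seq_along(y))
  preds <- data.frame(gene = genes, label = y, predicted = pred,
                      score = score, fold = fold, stringsAsFactors = FALSE)
  roc <- rocAuc(score, y)
  new("ClassifierReport", model = model, predictions = preds,
      metrics = .pooledMetrics(y, pred), roc = roc$roc, auc = roc$auc,
      nFolds = as.integer(folds), seed = as.integer(seed))
}

.pooledMetrics <- function(y, pred) {
  prf <- function(positive) {
    tp <- sum(pred == positive & y == positive)
    fp <- sum(pred == positive & y != positive)
    fn <- sum(pred != positive & y == positive)
    precision <- if (tp + fp) tp / (tp + fp) else 0
    recall <- if (tp + fn) tp / (tp + fn) else 0
    f1 <- if (precision + recall) 2 * precision * recall / (precision + recall) else 0
    list(precision = precision, recall = recall, f1 = f1)
  }
  list(accuracy = mean(pred == y), target = prf(1L), non_target = prf(0L))
}

#' ROC curve and trapezoidal AUC from decision scores
#'
#' Sweeps the threshold over the unique scores (descending), grouping tied
#' scores into single ROC steps, and accumulates the trapezoidal area. The
#' AUC is invariant under strictly increasing transforms of the scores and
#' equals the normalized Mann-Whitney U statistic (ties counted half).
#'
#' @param scores finite numeric decision scores (larger = more
#'   target-like).
#' @param y 0/1 labels; both classes must be present.
#' @return list with `roc` (`data.frame` of `fpr`, `tpr` from (0,0) to
#'   (1,1)) and `auc`.
#' @export
rocAuc <- function(scores, y) {
  stopifnot(all(is.finite(scores)), length(scores) == length(y))
  nPos <- sum(y == 1L)
  nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  grp <- cumsum(c(TRUE, s[-1L] != s[-length(s)]))
  tpAdd <- tapply(yy == 1L, grp, sum)
  fpAdd <- tapply(yy == 0L, grp, sum)
  tpr <- c(0, cumsum(tpAdd) / nPos)
  fpr <- c(0, cumsum(fpAdd) / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(roc = data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
       auc = auc)
}

#' Benchmark several classifier families on one labeling
#'
#' Runs [crossValidate()] for each requested model under a common seed.
#'
#' @inheritParams crossValidate
#' @param models character vector of model names, or `"all"`.
#' @return named list of [ClassifierReport-class] objects.
#' @export
benchmarkClassifiers <- function(X, y, models = "all", folds = 5, seed = 1) {
  if (identical(models, "all")) models <- classifierModels()
  out <- lapply(models, function(m) crossValidate(X, y, m, folds, seed))
  names(out) <- models
  out
}

#' Serialize classifier reports as JSON + TSV
#'
#' Writes `metrics.tsv` (model x metric table), per-model ROC point TSVs,
#' and a full `report.json` (metrics, fold assignments, pooled
#' predictions).
#'
#' @param reports named list of [ClassifierReport-class] (from
#'   [benchmarkClassifiers()]).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeClassifierReports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(reports, function(r) {
    m <- r@metrics
    data.frame(model = r@model, accuracy = m$accuracy,
               precision_target = m$target$precision,
               recall_target = m$target$recall, f1_target = m$target$f1,
               precision_non_target = m$non_target$precision,
               recall_non_target = m$non_target$recall,
               f1_non_target = m$non_target$f1,
               auc = r@auc, stringsAsFactors = FALSE)
  }))
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(x) sprintf("%.10g", x))
  utils::write.table(tab, file.path(dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (r in reports) {
    roc <- r@roc
    roc$fpr <- sprintf("%.10g", roc$fpr)
    roc$tpr <- sprintf("%.10g", roc$tpr)
    utils::write.table(roc, file.path(dir, paste0("roc_", r@model, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  payload <- lapply(reports, function(r) list(
    model = r@model, metrics = r@metrics, auc = r@auc,
    n_folds = r@nFolds, seed = r@seed, predictions = r@predictions))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
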