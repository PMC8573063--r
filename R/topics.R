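# NMF topic modeling of the filtered gene term-feature matrix:
# min_{W>=0, H>=0} ||X - WH||_F^2 by multiplicative updates, with
# deterministic SVD-based initialization and top-k topic summaries.

# Non-negative double SVD init (zero entries filled with mean(A) so no
# factor entry is locked at zero by the multiplicative updates).
.nndsvdInit <- function(A, k) {
  s <- svd(A, nu = k, nv = k)
  W <- matrix(0, nrow(A), k)
  H <- matrix(0, k, ncol(A))
  W[, 1L] <- sqrt(s$d[1L]) * abs(s$u[, 1L])
  H[1L, ] <- sqrt(s$d[1L]) * abs(s$v[, 1L])
  if (k > 1L) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn && nup * nvp > 0) {
      sc <- sqrt(s$d[j] * nup * nvp)
      W[, j] <- sc * up / nup
      H[j, ] <- sc * vp / nvp
    } else if (nun * nvn > 0) {
      sc <- sqrt(s$d[j] * nun * nvn)
      W[, j] <- sc * un / nun
      H[j, ] <- sc * vn / nvn
    }
  }
  # fill locked zeros with the flat-factor magnitude sqrt(mean/k), which
  # scales like sqrt(c) under A -> c A and so keeps the whole fit
  # scale-equivariant
  fill <- sqrt(mean(A) / k)
  W[W == 0] <- fill
  H[H == 0] <- fill
  list(W = W, H = H)
}

#' Fit an NMF topic model by multiplicative updates
#'
#' Minimizes the squared Frobenius objective `||X - WH||_F^2` over
#' non-negative factors with the classical multiplicative update rules,
#' which never increase the objective. Iteration stops when the relative
#' loss change drops below `tol` or after `maxIter` updates. The default
#' initialization is a deterministic non-negative double-SVD (reproducible
#' with no seed sweep); `init = "random"` draws uniform factors under
#' `seed`.
#'
#' @param X non-negative numeric matrix (or [GeneTermMatrix-class], whose
#'   TF-IDF scores are used), genes x features.
#' @param k number of topics, `1 <= k <= min(dim(X))`. The package default
#'   of 30 suits panel-scale corpora; small synthetic studies use the
#'   planted topic count.
#' @param seed integer seed for `init = "random"` (ignored otherwise).
#' @param maxIter maximum iterations (default 500).
#' @param tol relative loss-change stopping tolerance (default 1e-4).
#' @param init `"nndsvd"` (default) or `"random"`.
#' @return a [TopicModel-class].
#' @export
fitNmf <- function(X, k = 30, seed = NA, maxIter = 500, tol = 1e-4,
                   init = c("nndsvd", "random")) {
  init <- match.arg(init)
  if (is(X, "GeneTermMatrix")) X <- tfidfScores(X)
  A <- as.matrix(X)
  if (any(A < 0)) stop("X must be non-negative")
  k <- as.integer(k)
  if (k < 1L || k > min(dim(A)))
    stop("k must satisfy 1 <= k <= min(n_genes, n_features)")
  if (init == "nndsvd") {
    f <- .nndsvdInit(A, k)
  } else {
    if (is.na(seed)) stop("random init requires a seed")
    f <- withSeed(seed, list(
      W = matrix(stats::runif(nrow(A) * k), nrow(A), k) * sqrt(mean(A)),
      H = matrix(stats::runif(k * ncol(A)), k, ncol(A)) * sqrt(mean(A))))
  }
  W <- f$W; H <- f$H
  eps <- .Machine$double.eps
  loss <- function(W, H) sum((A - W %*% H)^2)
  trace <- loss(W, H)
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    H <- H * crossprod(W, A) / (crossprod(W) %*% H + eps)
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- loss(W, H)
    prev <- trace[length(trace)]
    trace <- c(trace, cur)
    if (abs(prev - cur) / max(prev, eps) < tol) break
  }
  rownames(W) <- rownames(A)
  colnames(H) <- colnames(A)
  new("TopicModel", k = k, W = W, H = H, lossTrace = trace, nIter = it,
      seed = as.integer(if (is.na(seed)) NA else seed), init = init)
}

#' Top genes and features per topic
#'
#' For topic `j`, the `nTop` genes with the largest `W[, j]` loadings and
#' the `nTop` features with the largest `H[j, ]` loadings, in descending
#' order with ties broken by identifier.
#'
#' @param model a fitted [TopicModel-class].
#' @param nTop how many items per list (default 20). Values beyond a factor
#'   dimension are truncated with a warning; 0 gives empty summaries.
#' @return list of length `k`; each element holds `genes` and `features`
#'   `data.frame`s with columns `item`, `weight`.
#' @export
topicSummaries <- function(model, nTop = 20) {
  stopifnot(is(model, "TopicModel"), nTop >= 0)
  if (nTop > nrow(model@W) || nTop > ncol(model@H)) {
    warning("nTop exceeds a factor dimension; truncating")
    nTop <- min(nTop, nrow(model@W), ncol(model@H))
  }
  top <- function(w, ids) {
    ord <- order(-w, ids)[seq_len(nTop)]
    data.frame(item = ids[ord], weight = w[ord], stringsAsFactors = FALSE)
  }
  lapply(seq_len(model@k), function(j) {
    list(genes = top(model@W[, j], rownames(model@W)),
         features = top(model@H[j, ], colnames(model@H)))
  })
}

#' Export topic factors and summaries as TSV
#'
#' Writes `W.tsv` (gene x topic loadings), `H.tsv` (topic x feature
#' loadings), and `topic_summary.tsv` (`topic`, `rank`, `item_kind`,
#' `item`, `weight`).
#'
#' @param model a fitted [TopicModel-class].
#' @param dir output directory.
#' @param nTop items per topic in the summary (default 20).
#' @return `dir`, invisibly.
#' @export
writeTopicModel <- function(model, dir, nTop = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m) format(m, digits = 10, trim = TRUE, scientific = FALSE)
  utils::write.table(fmt(model@W), file.path(dir, "W.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(fmt(model@H), file.path(dir, "H.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  summ <- topicSummaries(model, nTop)
  rows <- do.call(rbind, lapply(seq_along(summ), function(j) {
    rbind(
      data.frame(topic = j, rank = seq_len(nrow(summ[[j]]$genes)),
                 item_kind = "gene", summ[[j]]$genes),
      data.frame(topic = j, rank = seq_len(nrow(summ[[j]]$features)),
                 item_kind = "feature", summ[[j]]$features))
  }))
  rows$weight <- sprintf("%.10g", rows$weight)
  utils::write.table(rows, file.path(dir, "topic_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
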