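# Panel-characteristic term-feature selection: an upper-tail hypergeometric
# test comparing a feature's presence among panel genes S against a
# background S' = panel genes + 500 randomly drawn non-panel matrix genes.

#' Build the panel + random background gene set S'
#'
#' S' is the union of the panel genes present in the matrix and `nRandom`
#' non-panel matrix genes drawn without replacement under `seed` (all of
#' them, with a warning, when fewer than `nRandom` are available).
#' Deterministic given the seed and independent of input ordering.
#'
#' @param matrixGenes character vector of the matrix's gene ids.
#' @param panel a [GenePanel-class].
#' @param nRandom number of random non-panel genes (default 500).
#' @param seed integer seed for the draw.
#' @return sorted character vector S'.
#' @export
buildBackground <- function(matrixGenes, panel, nRandom = 500, seed = 1) {
  inPanel <- sort(intersect(panel@genes, matrixGenes))
  if (length(inPanel) == 0L)
    stop("panel has no genes in common with the matrix")
  pool <- sort(setdiff(matrixGenes, inPanel))
  if (length(pool) <= nRandom) {
    if (length(pool) < nRandom)
      warning(sprintf("only %d non-panel genes available (< nRandom = %d); taking all",
                      length(pool), nRandom))
    samp <- pool
  } else {
    samp <- withSeed(seed, sample(pool, nRandom))
  }
  sort(c(inPanel, samp))
}

.checkHyper <- function(N, Ns, Nt, Nst = 0L) {
  if (Ns > N || Nt > N || Ns < 0L || Nt < 0L || N < 1L)
    stop("invalid hypergeometric parameters: need 0 <= Ns, Nt <= N")
  if (Nst < 0L || Nst > min(Ns, Nt))
    stop("Nst must satisfy 0 <= Nst <= min(Ns, Nt)")
}

#' Hypergeometric probability mass
#'
#' Probability that exactly `y` of the `Ns` panel genes contain the term
#' feature, when `Nt` of the `N` background genes contain it:
#' `choose(Nt, y) * choose(N - Nt, Ns - y) / choose(N, Ns)`. Computed in
#' log space; exactly 0 outside the support
#' `[max(0, Ns - (N - Nt)), min(Ns, Nt)]`.
#'
#' @param N background set size |S'|.
#' @param Ns panel size |S|.
#' @param Nt background genes containing the feature.
#' @param y count whose probability is wanted (vectorized).
#' @return numeric vector of probabilities.
#' @export
hypergeomPmf <- function(N, Ns, Nt, y) {
  .checkHyper(N, Ns, Nt)
  lo <- max(0L, Ns - (N - Nt))
  hi <- min(Ns, Nt)
  out <- numeric(length(y))
  ok <- y >= lo & y <= hi & y == round(y)
  out[ok] <- exp(lchoose(Nt, y[ok]) + lchoose(N - Nt, Ns - y[ok]) -
                   lchoose(N, Ns))
  out
}

#' Upper-tail hypergeometric p-value
#'
#' `P(y >= Nst)`: the sum of [hypergeomPmf()] from the observed `Nst` up to
#' `min(Ns, Nt)`, accumulated in log space to avoid underflow. Equals 1
#' whenever `Nst` is at or below the lower support bound.
#'
#' @inheritParams hypergeomPmf
#' @param Nst observed number of panel genes containing the feature.
#' @return p-value in (0, 1].
#' @export
hypergeomPvalue <- function(N, Ns, Nt, Nst) {
  .checkHyper(N, Ns, Nt, Nst)
  lo <- max(0L, Ns - (N - Nt))
  hi <- min(Ns, Nt)
  if (Nst <= lo) return(1)
  ys <- seq.int(Nst, hi)
  lp <- lchoose(Nt, ys) + lchoose(N - Nt, Ns - ys) - lchoose(N, Ns)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Select panel-characteristic term features by the hypergeometric test
#'
#' For every feature of the matrix, counts presence (`tf > 0`) in the
#' background S' (`Nt`) and in the panel S (`Nst`), computes the upper-tail
#' hypergeometric p-value, and retains features with `p <= alpha`. The
#' returned matrix keeps all gene rows with the columns restricted to the
#' selected features (the downstream classifier labels every gene).
#'
#' @param gtm a [GeneTermMatrix-class], already passed through
#'   [filterMinFeatures()].
#' @param panel a [GenePanel-class].
#' @param alpha selection threshold on raw p-values, in (0, 1]
#'   (default 0.05; no multiple-testing correction, matching the selection
#'   procedure this package implements — set `adjust = "BH"` for an
#'   optional Benjamini-Hochberg variant).
#' @param nRandom,seed background construction, see [buildBackground()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list with `matrix` (the column-filtered [GeneTermMatrix-class])
#'   and `table` (a `data.frame` with `featureId`, `category`, `Nt`, `Nst`,
#'   `pValue`, `selected`; attributes `alpha`, `seed`, `background`).
#' @export
selectFeatures <- function(gtm, panel, alpha = 0.05, nRandom = 500, seed = 1,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  genes <- geneIds(gtm)
  bg <- buildBackground(genes, panel, nRandom = nRandom, seed = seed)
  S <- intersect(panel@genes, genes)
  present <- gtm@counts[bg, , drop = FALSE] > 0
  Nt <- Matrix::colSums(present)
  Nst <- Matrix::colSums(present[rownames(present) %in% S, , drop = FALSE])
  N <- length(bg)
  Ns <- length(S)
  p <- vapply(seq_along(Nt),
              function(j) hypergeomPvalue(N, Ns, Nt[j], Nst[j]), 0)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sel <- p <= alpha
  tab <- data.frame(featureId = featureIds(gtm),
                    category = unname(featureCategories(gtm)),
                    Nt = as.integer(Nt), Nst = as.integer(Nst),
                    pValue = p, selected = sel, stringsAsFactors = FALSE)
  attr(tab, "alpha") <- alpha
  attr(tab, "seed") <- seed
  attr(tab, "background") <- bg
  if (!any(sel)) stop("no term feature passed the selection threshold")
  list(matrix = subsetFeatures(gtm, tab$featureId[sel]), table = tab)
}

#' Category proportions before and after feature selection
#'
#' The distribution of the five feature groups among all tested features
#' versus among the selected ones — the matrix-level summary of how
#' selection shifts composition toward the groups characteristic of the
#' panel.
#'
#' @param table selection table from [selectFeatures()].
#' @return `data.frame` with `category`, `before`, `after` (proportions).
#' @export
categoryProportions <- function(table) {
  lv <- .CATEGORIES
  before <- prop.table(table(factor(table$category, levels = lv)))
  after <- prop.table(table(factor(table$category[table$selected], levels = lv)))
  data.frame(category = lv, before = as.numeric(before),
             after = as.numeric(after), stringsAsFactors = FALSE)
}

#' Write a feature selection table as TSV
#' @param table selection table from [selectFeatures()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSelectionTable <- function(table, path) {
  out <- data.frame(feature_id = table$featureId, category = table$category,
                    Nt = table$Nt, Nst = table$Nst,
                    p_value = sprintf("%.12g", table$pValue),
                    selected = table$selected, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
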