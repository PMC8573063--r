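---
title: "Methods: text-mined gene context profiles for panel discovery"
author: "genecontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: text-mined gene context profiles for panel discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecontext)
```

## The problem

Clinical gene panels (MSK-IMPACT, the Oncomine Comprehensive Assay,
cardiovascular panels) are curated sets of genes sequenced together in one
assay. Designing or extending such a panel requires knowing, for every
candidate gene, which diseases, drugs, mutations and biological processes
the literature associates it with. `genecontext` builds that context
automatically from entity-annotated abstracts: each gene is represented by
the biomedical concepts that co-occur with it in a narrow textual window,
and those profiles drive feature selection, topic modeling, and
panel-membership prediction.

## The model, stage by stage

**Gene windows.** For every gene mention, the context is the sentence
containing the gene plus the previous and the next sentence, clipped at
document boundaries. The rationale is locality: the adjacent sentences are
the ones most likely to describe the gene's role. Windows of the same gene
with an identical clipped span within a document are collapsed, so a gene
mentioned twice in one sentence yields a single window; overlapping
windows from adjacent center sentences are deliberately kept separate,
each counting its own co-occurrences. A feature mentioned twice inside one
window counts twice (multiset semantics) — co-occurrence frequency, not
mere presence, carries the association strength. Other genes inside the
window are legitimate features of the focal gene and are grouped with the
phenotype category by default.

**MeSH tagging.** Named-entity annotations (genes, diseases, chemicals,
mutations, species) arrive with the corpus in the PubTator exchange
format. They are complemented by a thesaurus-driven tagger: starting from
the descriptors indexed for each article, the mapping set is expanded to
every descendant descriptor (strict dot-prefix extension of any tree
number), and each descriptor's entry terms are string-matched in the text.
Matching is case-insensitive, whole-token, hyphen/space-equivalent, and
constrained to a single sentence; pre-existing annotations take precedence
on overlapping spans, and among competing matches the longest span wins
with ties broken by smallest descriptor id. These choices make tagging
deterministic and idempotent. Concepts are merged by descriptor id, so
synonymous surface forms collapse into one feature.

**Feature categories.** Every feature falls into one of five groups:
mutation (Mutation-typed), drug (Chemical-typed), cancer (Disease-typed,
or MeSH under the neoplasms branch), genetic_phenomena (MeSH under the
genetic-phenomena branch), and phenotype (everything else). The branch
roots are configuration values — `C04` and `G05` match the real MeSH
trees — because category membership is a property of the thesaurus, not of
the algorithm.

**TF-IDF.** With `tf[g,t]` the total multiplicity of feature `t` over all
windows of gene `g`, `n` the number of genes, and `df[t]` the number of
genes containing `t` at least once:

$$\mathrm{TF} = \log(1 + tf), \qquad
  \mathrm{IDF} = \log(1 + n/df), \qquad
  \mathrm{score} = \mathrm{TF} \times \mathrm{IDF}.$$

Natural logarithms are used; any fixed base only rescales all scores by a
constant, so ranks are base-invariant. Genes with fewer than ten distinct
features are removed as too thinly described, after which `n` and `df`
are recomputed so the matrix stays self-consistent (features left with
`df = 0` are dropped).

**Hypergeometric feature selection.** Given a panel `S` and a background
`S'` consisting of the panel genes plus 500 randomly drawn non-panel
matrix genes, a feature present in `Nt` of the `N` background genes and
`Nst` of the `Ns` panel genes gets the upper-tail p-value

$$p = \sum_{y=N_{st}}^{\min(N_s, N_t)}
      \frac{\binom{N_t}{y}\binom{N-N_t}{N_s-y}}{\binom{N}{N_s}},$$

accumulated in log space to avoid underflow. Features with `p <= alpha`
are retained. The threshold defaults to `alpha = 0.05` on raw p-values
with no multiple-testing correction — selection here is a screening step,
not an inferential claim — and a Benjamini–Hochberg mode is available but
off by default. Presence (`tf > 0`), not score magnitude, defines the
counts, and all gene rows are kept in the filtered matrix (columns only
are restricted) because the downstream classifier labels every gene. The
background draw is seeded and recorded, making selection reproducible.

**Topic modeling.** The filtered score matrix `X` is factored as
`X ~ WH`, `W, H >= 0`, by minimizing the squared Frobenius norm with the
classical multiplicative updates, which never increase the objective.
TF-IDF scores (not raw counts) are factored, since the filtered score
matrix is the object the rest of the analysis consumes. Initialization is
a deterministic non-negative double SVD (zeros filled with the flat-factor
magnitude `sqrt(mean(X)/k)` so no entry is locked at zero and the fit is
scale-equivariant); a random initialization is available behind a seed.
Iteration stops at a relative loss change below `1e-4` or 500 iterations.
Thirty topics suit a corpus-scale analysis; small synthetic studies use
the planted topic count. Each topic is summarized by its top-20 genes and
features, descending by loading with identifier tie-breaks.

**Classification.** Genes are labeled target/non-target by panel
membership and seven classifier families are benchmarked: nearest
neighbors, linear SVM, Gaussian process, decision tree, random forest,
neural net, and naive Bayes, each with its library's default
hyperparameters. Folds are stratified (every fold holds both classes) and
metrics — accuracy, per-class precision/recall/F1 — are computed on pooled
out-of-fold predictions rather than fold averages, which keeps every gene
predicted exactly once and makes the confusion matrix sum to the gene
count. ROC curves come from a threshold sweep over each model's
continuous decision score (probability estimates where no margin exists);
tied scores are grouped into single ROC steps, so the trapezoidal AUC
equals the normalized Mann–Whitney U statistic with midrank ties. No class
reweighting is applied by default, since plain accuracy is the headline
metric.

**Landscape.** The cancer-category columns form the gene x cancer
submatrix; an optional descriptor-to-type mapping aggregates columns by
sum (no ontology is hard-coded). The per-gene literature frequency is
defined as the normalized row sums of this submatrix — the package's own
estimator, stated prominently because external comparisons depend on it —
and is compared with an external clinical frequency vector by cosine
similarity, aligned on the union of gene ids with zero fill. Year-sliced
matrices are produced by filtering the corpus by publication year and
re-running the pipeline.

## The synthetic study generator

Every statistical guarantee in the test suite is measured on corpora from
`generateCorpus()`, whose manifest records the planted truth. Each
document has one focal gene in its center sentence; each vocabulary
feature enters the three-sentence window with probability `pSignal` for
(panel gene, signal feature) pairs and `pBackground` otherwise; two
distractor mentions are planted outside the window to verify that window
boundaries are honoured. A configurable fraction of MeSH-typed mentions
is emitted *without* an entity annotation and is recoverable only through
the thesaurus tagger (sometimes indexed via the parent descriptor, which
exercises subtree expansion). Sentences are templated natural-language
strings, so sentence splitting and offset arithmetic are genuinely
exercised; the vocabulary is synthetic.

Reference conditions: 600 genes with a 100-gene panel (so the default
500-gene random background spans the remaining pool), five categories of
40 features, 20 cancer-category signal features (placing all signal in one
group makes the category-proportion shift measurable), 4 documents per
gene, 5 sentences per document, `pSignal = 0.6` against
`pBackground = 0.05` (a 12-fold enrichment, strong but not degenerate),
years 2011–2019 with an era switch at 2016 and two era-switched cancer
features per era. Setting `pSignal = pBackground` produces a null corpus
used for type-I calibration. These sizes keep a full study generation and
pipeline run within about a minute while leaving all rates in a regime
where binomial error bars are informative.

What the generator does **not** emulate: real token distributions,
polysemous entry terms, drifted annotation offsets (exercised separately
by handcrafted fixtures), citation-network structure, or corpus-scale
vocabulary (hundreds of features versus tens of thousands). Passing tests
therefore demonstrate the correctness of the machinery and calibration of
the statistics under controlled conditions, not performance on a real
PubMed harvest, whose headline numbers depend on a corpus this package
does not ship.

## Numerical and design choices

- Offsets are 0-based half-open over `title + " " + abstract`, the common
  PubTator dialect; the publication year travels in a `PMID|y|YYYY` line,
  a documented extension, since the exchange format has no year field.
- On a mention/offset mismatch the offsets are trusted and the mention
  recomputed, with a warning — real corpora contain drifted offsets, and
  silently dropping annotations would bias counts.
- Sentence splitting is rule-based with a fixed biomedical abbreviation
  stop-list ("e.g.", "i.e.", "Fig.", "et al.", ...), requiring the next
  character to be uppercase or a digit. Determinism was preferred over a
  learned splitter so that offsets are stable across machines.
- Genes are keyed by normalized concept id, never surface mention, so
  synonymous symbols aggregate.
- The hypergeometric tail is summed in log space (`lchoose` +
  log-sum-exp); p-values below roughly `1e-300` underflow to zero, which
  is irrelevant at screening thresholds.
- Degenerate inputs fail loudly: empty panels, features with zero document
  frequency, matrices emptied by the gene filter, single-class labelings,
  zero-norm frequency vectors, and inverted year ranges are all errors,
  not silent results.
- Row and column order is lexicographic by identifier everywhere, which
  makes MatrixMarket and TSV exports byte-stable across runs and input
  orderings.

## Limitations

Co-occurrence in a three-sentence window is not a relation: negated or
merely juxtaposed concepts count the same as causal ones. The TF-IDF
weighting favours well-studied diseases and genes, so rare-disease signals
are systematically under-weighted. Entry-term matching does not
disambiguate polysemous terms beyond longest-match. The window size is
fixed at three sentences by design; a configurable width exists only as an
expert option and is untested territory. Reported classifier metrics use
library-default hyperparameters; no tuning is attempted.
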