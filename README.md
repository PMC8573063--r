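# genecontext

Contextualizing genes with text-mined co-occurrence features, for gene
panel discovery.

Clinical gene panels — MSK-IMPACT (410 cancer genes), the Oncomine
Comprehensive Assay (161 genes), cardiovascular panels — are curated gene
sets sequenced together in one assay. `genecontext` builds a literature
profile for every gene from entity-annotated biomedical abstracts and uses
those profiles to characterize, validate, and extend such panels:

1. **Gene windows** — each gene mention's context is three sentences: the
   sentence containing the gene plus its neighbours.
2. **MeSH tagging** — concepts missed by named-entity annotation are
   recovered by expanding each article's indexed MeSH descriptors to their
   subtree and string-matching entry terms in the text.
3. **Gene × term-feature matrix** — co-occurrence counts `tf` are scored
   as `TF·IDF` with `TF = log(1 + tf)` and `IDF = log(1 + n_gene/df)`;
   genes with fewer than 10 distinct features are dropped.
4. **Hypergeometric feature selection** — against a background of the
   panel plus 500 random non-panel genes, each feature's upper-tail
   p-value `p = Σ_{y=Nst}^{min(Ns,Nt)} C(Nt,y)·C(N−Nt,Ns−y)/C(N,Ns)`
   screens for panel-characteristic features (default α = 0.05).
5. **Topics** — non-negative matrix factorization `X ≈ WH` minimizing
   `‖X − WH‖²_F`, summarized by top-20 genes/features per topic.
6. **Panel prediction** — seven classifier families (nearest neighbors,
   linear SVM, Gaussian process, decision tree, random forest, neural
   net, naive Bayes) benchmarked with stratified 5-fold cross-validation:
   accuracy, per-class precision/recall/F1, ROC/AUC on pooled
   out-of-fold predictions.
7. **Mutational landscape** — the gene × cancer-type submatrix, per-gene
   literature frequency, cosine-similarity validation against an external
   clinical frequency vector, and year-sliced matrices.

A fully synthetic study generator (`generateCorpus()`) emits
PubTator-format corpora with planted co-occurrence structure and a
ground-truth manifest; every statistical property of the pipeline is
validated against it.

## Worked example

```r
library(genecontext)

spec  <- syntheticSpec(nGenes = 120, nPanel = 30, docsPerGene = 3, seed = 42)
study <- tempfile("study")
gen   <- generateCorpus(spec, study)

res <- runPipeline(
  pubtator = gen$paths[["pubtator"]],  mesh    = gen$paths[["mesh"]],
  indexing = gen$paths[["indexing"]],  panel   = gen$paths[["panel"]],
  outDir   = file.path(study, "out"),  nRandom = 90, nTopics = 4,
  models   = c("linear_svm", "neural_net"), seed = 42,
  clinicalFreq = gen$paths[["clinical"]])

res$matrix
#> GeneTermMatrix: 120 genes x 25 term features (TF-IDF built)
#>   categories: cancer=20, drug=2, genetic_phenomena=0, mutation=1, phenotype=2

head(res$selection[order(res$selection$pValue), ], 5)
#>       featureId category Nt Nst   pValue selected
#> 102 MESH:DC0004   cancer 35  28 1.42e-18     TRUE
#> 9        D10017   cancer 43  30 2.15e-18     TRUE
#> 5        D10009   cancer 37  28 2.51e-17     TRUE
#> 106 MESH:DC0012   cancer 37  28 2.51e-17     TRUE
#> 1        D10001   cancer 42  29 1.18e-16     TRUE

res$reports$neural_net
#> ClassifierReport [neural_net]: accuracy 1.000, AUC 1.000 (5-fold, seed 42)

categoryProportions(res$selection)
#>            category before after
#> 1            cancer    0.2  0.80
#> 2              drug    0.2  0.08
#> 3 genetic_phenomena    0.2  0.00
#> 4          mutation    0.2  0.04
#> 5         phenotype    0.2  0.08

res$cosine
#> [1] 0.993
```

Reading the output: the 25 features surviving the hypergeometric screen
are dominated by the planted cancer-category signal (category share 0.20
→ 0.80), the most significant features are exactly the planted signal
concepts (p ≈ 1e-18 at a 120-gene background), panel membership is
perfectly predictable from the selected profile, and the text-mined gene
frequency agrees with the planted clinical stand-in at cosine 0.993.

A command-line wrapper over the same functions ships in
`inst/cli/genecontext.R`:

```sh
Rscript inst/cli/genecontext.R synth --out study --seed 1
Rscript inst/cli/genecontext.R run --pubtator study/corpus.pubtator \
  --mesh study/mesh.tsv --indexing study/indexing.tsv \
  --panel study/panel.txt --out study/out
```

## Documentation

The methods vignette (`vignettes/gene-context-methods.Rmd`) describes the
model stage by stage: the window and tagging rules, the TF-IDF and
hypergeometric formulas, the NMF and cross-validation conventions, what
the synthetic generator does and does not emulate, and the package's
numerical choices and limitations.
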