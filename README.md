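# meshrank

Automatic subject indexing of scientific abstracts against a hierarchical
controlled vocabulary (MeSH-style main headings), for text-mining and
literature-infrastructure work where thousands of new documents must be
annotated long before human indexers get to them.

Indexing is framed as **candidate generation + learning to rank + list
pruning** rather than flat multi-label classification:

1. **Candidates** are the union of three sources: descriptors annotated on
   the k nearest neighbour documents (tf-idf cosine over stemmed unigrams,
   k chosen dynamically in [10, 40] from the neighbourhood's mean
   similarity); labels fired by per-label cost-sensitive linear classifiers
   minimizing

   `λ/2‖w‖² + C₊ Σ_{y=+1} h(y(θ + w·x)) + C₋ Σ_{y=−1} h(y(θ + w·x))`

   with the modified Huber loss `h(z) = −4z (z ≤ −1); (1−z)² (−1 < z < 1);
   0 (z ≥ 1)` and `C₊ = 1.5 C₋`; and an optional external recommender.
2. **Ranking** is LambdaMART: gradient-boosted limited-depth regression
   trees driven by NDCG-weighted pairwise lambda gradients, over features
   covering neighbourhood frequency/similarity, term-name unigram/bigram
   overlap, IBM Model 1 translation probabilities, BM25 and
   translation-based query likelihood, synonym matches, classifier scores
   and external-recommendation flags.
3. **Pruning** injects age check tags detected near explicit age mentions,
   removes a term when a more specific descendant out-ranks it, and cuts
   the list at the smallest `i ≥ 2` with `S_{i+1} < S_i · ln(i) · λ`
   (λ = 0.3, capped at 25 terms).

A synthetic fixture generator (balanced 39-label hierarchy, mean 12.7
labels/document) makes the entire pipeline trainable and testable with no
downloads. Real MeSH descriptor XML and MEDLINE-style citation XML are
also read natively, alongside a plain TSV vocabulary dialect and JSONL
corpora.

## Worked example

```r
library(meshrank)

spec   <- fixture_spec(n_docs = 300, seed = 7)
vocab  <- make_vocabulary(spec)
corpus <- make_corpus(spec, vocab)
vocab
#> mesh_vocabulary: 39 descriptors, 6 check tags, 39 tree positions

cfg <- mesh_config(seed = 3, n_rank_docs = 150,
                   svm = svm_config(epochs = 8),
                   ranker = list(n_trees = 30, max_leaves = 10,
                                 learning_rate = 0.1, min_leaf_obs = 1))
model <- mesh_train(corpus[1:250], vocab, cfg, quiet = TRUE)
model
#> mesh_model: 250 training documents, 39 classifiers, 30 ranker trees

preds <- mesh_predict(model, corpus[251:300])
preds[["doc00251"]][1:5, ]
#>   rank descriptor_id     score
#> 1    1          D030 0.9672078
#> 2    2          D015 0.9672006
#> 3    3          D007 0.9671956
#> 4    4          D013 0.9671956
#> 5    5          D003 0.4622838

mesh_evaluate(preds, corpus[251:300])
#> mesh_eval_report over 50 documents
#>   example-based  P 0.986  R 0.584  F1 0.718
#>   micro-averaged P 0.987  R 0.537  F1 0.696
```

The scores are logistic-transformed ranker outputs; the gap between rank 4
(0.967) and rank 5 (0.462) is the kind of collapse the automatic cut-off
exploits. The same model ranked by neighbour frequency alone (the k-NN
baseline, identical pruning) reaches example-based F1 0.631 — the learned
ranker is worth +0.087 F1 even at this toy scale:

```r
baseline <- mesh_predict(model, corpus[251:300], baseline = "nbr_freq")
mesh_evaluate(baseline, corpus[251:300])$example
#> precision    recall        f1
#> 0.5631158 0.8107260 0.6307597
```

A thin CLI over the same functions lives in `inst/cli/meshrank`
(subcommands `train`, `predict`, `evaluate`, `make-fixture`).

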