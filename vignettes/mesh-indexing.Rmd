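---
title: "Ranking-based automatic subject indexing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking-based automatic subject indexing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshrank)
```

## The task and the model

meshrank assigns descriptors from a hierarchical controlled vocabulary
(MeSH-style main headings) to scientific abstracts. The task is treated as
ranking rather than flat multi-label classification: a high-recall candidate
set is generated per document, every candidate is described by a feature
vector, a learned ranking function orders the candidates, and a pruning
stage decides where the list ends.

Candidates come from three channels whose union is deduplicated with
provenance flags:

1. **k-nearest neighbours.** The central assumption is that documents
   similar in content share annotations. The index stores tf-idf weighted
   stemmed unigrams of title + abstract only — annotations never enter the
   similarity computation — and can be restricted to recently annotated
   documents (`date_floor`), since older articles carry outdated
   annotations and word statistics. Every unique descriptor of the
   neighbours becomes a candidate.
2. **Per-label classifiers.** One cost-sensitive linear model per frequent
   label, minimizing
   $\frac{\lambda}{2}\lVert w\rVert^2
   + C_+\sum_{i:y_i=1} h(y_i(\theta + w\cdot x_i))
   + C_-\sum_{i:y_i=-1} h(y_i(\theta + w\cdot x_i))$
   with the modified Huber loss $h(z) = -4z$ for $z\le-1$, $(1-z)^2$ for
   $-1<z<1$, $0$ for $z\ge 1$. $C_+ = r\,C_-$ with $r = 1.5$ counters the
   dominance of negatives. Positively classified labels become candidates;
   every model's decision value is kept as a feature.
3. **External recommendations.** An arbitrary per-document descriptor list
   (a production recommender in real deployments). The package ships a
   deterministic name-overlap pseudo-recommender so the channel is
   exercised without external services.

The ranker is LambdaMART: gradient-boosted limited-depth regression trees
whose pseudo-gradients are pairwise sigmoid terms weighted by the NDCG
change of swapping the pair, with Newton-step leaf values
$\sum\lambda/\sum h$. Relevance is binary: $y_i = 1$ iff the descriptor was
manually assigned. Post-processing then (a) injects age check tags detected
from explicit age mentions in the abstract, (b) removes a term when one of
its descendants out-ranks it (indexers prefer the most specific applicable
heading), and (c) truncates the list where scores collapse:
keep positions $1..i$ for the smallest $i\ge 2$ with
$S_{i+1} < S_i\cdot\ln(i)\cdot\lambda$, after a hard cap of $N$ terms.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k_min`, `k_max` | 10, 40 | neighbour count bounds; k rises linearly with the mean similarity of the probed neighbourhood |
| `sim_low`, `sim_high` | calibrated | anchors of the dynamic-k map; 10th/90th percentile of neighbour-mean similarity at index build |
| `cost_ratio_r` | 1.5 | $C_+/C_-$; raising it trades classifier precision for positive recall |
| `reg_lambda` | 1e-4 | L2 strength of the classifier cost |
| `n_classifier_labels` | 20,000 | classifiers are only trained for the most frequently annotated labels; the rest are rarely used |
| `n_rank_docs` | 5,000 | documents sampled to build ranker training lists |
| `n_trees`, `max_leaves`, `learning_rate` | 300, 10, 0.1 | boosting capacity; defaults mirror common boosted-ranker toolkit conventions |
| `lambda_cut`, `n_cap` | 0.3, 25 | pruning aggressiveness and hard cap; `lambda_cut` tunes the recall/precision balance |
| BM25 `k1`, `b` | 1.2, 0.75 | standard Okapi settings |
| `mix` | 0.5 | Jelinek–Mercer weight on the translation channel of the query likelihood |

## Numerical and design choices

Several points are open in the general method description; the package
resolves them as follows, and these are deliberate design decisions rather
than derived facts.

* **Similarity.** tf-idf cosine over stemmed unigrams with
  $\mathrm{idf} = \ln(1 + n/\mathrm{df})$ (strictly positive even for
  ubiquitous tokens). Eliteness-weighted related-article similarity would
  fit the same contract but is harder to verify against an independent
  oracle; cosine is reproducible and is what the tests check against a
  dense reimplementation.
* **Dynamic k.** Only the direction "lower mean similarity, fewer
  neighbours" is prescribed; the package uses the clamped linear
  interpolation between `sim_low` and `sim_high` described above, probing
  `k_max` candidates before choosing k.
* **Cut-off at i = 1.** The pruning inequality with $\ln(1) = 0$ would
  discard every term after the first whenever scores are positive, so the
  rule is evaluated from $i \ge 2$ (natural log). Ranker scores are
  unbounded, and the rule presumes positive scores, so the pipeline maps
  scores through a logistic before pruning; `score_cutoff()` itself applies
  the formula verbatim to whatever scores it receives.
* **Age rules.** Ranges follow NLM check-tag conventions and may overlap
  (Young Adult lies inside Adult); detection returns the union, matching
  the practice of co-assigning tags. The scan window is ±60 characters
  around "age"/"aged"/"ages"; both endpoints of a range expression
  contribute. Injected tags enter at the head of the list (current maximum
  + 1e-6) so pruning cannot immediately drop them; the pipeline only adds
  age tags, never deletes competing ones.
* **Specificity pruning** uses all ancestors (strict tree-number prefix),
  not only direct parents.
* **Classifier training sets.** All positives plus a seeded random sample
  of at most 10× as many negatives; each label derives its sampling stream
  from its id, so batteries are identical for any training order or worker
  count. Features are L2-normalized stemmed term frequencies, which
  stabilizes SGD step sizes across document lengths. The SGD schedule is
  inverse-t (`eta0 / (1 + eta0 * lambda * t)`); a deterministic full-batch
  mode with backtracking exists for descent-property verification.
* **Label frequency counting** is one per (document, descriptor), ignoring
  multiple tree positions.
* **IBM Model 1** conditions term tokens on document tokens, matching the
  direction needed by the translation query likelihood; EM runs 20
  iterations or until the log-likelihood gain drops below 1e-4. Column
  normalization is asserted after every iteration.
* **Overlap features** use the stemmed preferred name only; synonyms feed
  a single binary case-folded substring feature. (A per-synonym or count
  feature family would also be defensible; one binary keeps the schema
  fixed.) The translation feature is the product over name tokens of each
  token's best translation probability from the document, floored at 1e-9.
* **Ties.** Candidate ranking breaks score ties lexicographically by
  descriptor id; tree split search breaks gain ties by lowest feature
  index, then lowest threshold. Both make every artifact bit-reproducible.

## What the synthetic generator emulates — and what it does not

`make_vocabulary()` and `make_corpus()` build a balanced descriptor tree
(39 labels at the default depth 3 × branching 3) whose labels carry
disjoint signature-word sets. Documents draw their label count from a
truncated negative binomial with mean 12.7 — the observed mean annotation
count per article in large indexing corpora — and their text as a mixture
of signature words and background noise. Descriptor names are built from
signature words, giving the overlap, translation and synonym features
learnable signal; age-tagged documents embed explicit "aged N years"
phrases consistent with their tags; label popularity is mildly skewed so
frequency ranking is meaningful.

This makes the generator a *positive control*: the pipeline's assumptions
hold by construction, so passing tests show the machinery works, not that
real-corpus performance will match. Real abstracts differ in ways the
generator ignores: natural-language syntax, polysemy, label spaces three
orders of magnitude larger, annotation drift over time, and check tags
that depend on full text rather than the abstract. With only 39 labels and
~13 per document, label *coverage* measures saturate (a random set of 20
documents already covers most labels); the ranking quality comparison
against the neighbour-frequency baseline is the informative end-to-end
signal at this scale.

## Study sizes

The end-to-end synthetic study (used by the acceptance script and the
heaviest test) generates 2,000 documents, trains on 1,600 and evaluates on
400 held-out documents, samples 600 ranker-training lists, and boosts 100
trees (max 10 leaves, learning rate 0.1) — an ensemble comfortably past
the point where training NDCG plateaus on an 11-feature schema. All
module defaults remain at their reference values; the smaller ensemble and
list sample are the study's own size choices and are configurable.

## Known limitations

* The pseudo external recommender is a name-overlap matcher; it exercises
  the channel but is not a model of any production recommender's errors.
* Classifier scores are uncalibrated decision values; the ranker can use
  them ordinally but they are not probabilities.
* Subheadings/qualifiers, supplementary concept records and non-age check
  tag heuristics are out of scope.
* The specificity pruner is quadratic in list length; lists are capped at
  `n_cap`, so this is immaterial in practice.
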