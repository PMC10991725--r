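---
title: "Theme discovery in bibliographic corpora: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theme discovery in bibliographic corpora: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litthemes)
```

`litthemes` implements an unsupervised pipeline for mapping the research
themes of a scientific literature from titles and abstracts, and for
following those themes over time. This vignette is the package's account of
the underlying models, the tunable parameters, the numerical choices, and
the limits of what its tests demonstrate.

## The model

Each publication is represented by the concatenation of its title and
abstract. The pipeline assumes that thematically related publications share
vocabulary, and that this sharing is recoverable from weighted token
counts:

1. **Token space.** Tokenization splits text into words, numbers,
   punctuation and symbols; every non-whitespace character belongs to
   exactly one token. Runs of word characters joined by internal hyphens or
   underscores stay together, because identifiers such as `blaOXA-23` or
   `blaOXA_like` are exactly the tokens that discriminate themes in
   biomedical text. Lemmatization then folds inflections (*strains* →
   *strain*) so that morphological variation does not split a theme's
   vocabulary. Stop words are **not** removed before vectorization: common
   words get near-zero discriminative weight from the idf term anyway, and
   keeping the full token inventory keeps the representation faithful to
   the documents.

2. **tf-idf.** Cell $(d, t)$ of the document–term matrix is
   $\mathrm{tf}(d,t)\,\bigl(\ln\frac{1+N}{1+\mathrm{df}(t)}+1\bigr)$ with
   raw counts and L2 row normalization — the smoothed convention of the
   mainstream machine-learning vectorizers, chosen so that a model fitted
   here behaves like one fitted with those tools. `min_df` defaults to 1
   (no pruning): at study scale a corpus of a few thousand abstracts yields
   a vocabulary in the low tens of thousands, which the next step absorbs.

3. **Latent semantic analysis.** The matrix is projected onto its top
   $d$ right singular vectors ($d = 300$ at study scale, capped at
   $\min(n, V)$ for smaller corpora, with the effective value recorded in
   the configuration). The projection concentrates co-occurrence structure
   (synonymy, polysemy) in a few hundred directions and keeps Euclidean
   distances meaningful for the clustering step. The decomposition is
   computed by exact dense LAPACK SVD rather than a randomized or Lanczos
   scheme: at the matrix sizes this package targets the exact
   decomposition takes seconds, is bitwise deterministic, and removes a
   whole class of solver-tolerance questions. Sign indeterminacy is fixed
   by making each component's largest-magnitude entry positive.

4. **Clustering.** k-means in the reduced space, with greedy k-means++
   seeding: each new centroid is chosen among $2 + \lfloor\ln k\rfloor$
   candidates sampled proportionally to the squared distance to the
   nearest chosen centroid, keeping the candidate that minimises the
   potential $\sum_x D(x)^2$. Lloyd iterations run until assignments are
   stable or 300 iterations are reached. The number of clusters is chosen
   by sweeping a range (50–500 at study scale) and maximising the mean
   silhouette coefficient, computed with Euclidean distance in the same
   reduced space the clustering operates in, so the selection criterion
   evaluates exactly the geometry being optimised.

5. **Cluster description.** Two independent term lists describe each
   cluster: the 10 tokens of highest mean tf-idf weight over its members
   (centroid terms, computed in the original token space so they are
   nameable words rather than latent directions), and the representative
   terms of a per-cluster LDA over lemma unigrams plus ordered adjacent
   lemma pairs. The topic number is shared across clusters and selected by
   the most negative average UMass coherence — rare co-occurrence among a
   topic's top words indicates terms that summarise rather than merely
   collocate. With $T$ topics and the first two terms of each, a cluster
   receives at most $2T$ representative terms after de-duplication.

6. **Trends and prediction.** Per-cluster publications-per-year series
   expose emergent and defunct themes. New publications are embedded with
   the frozen vectorizer and basis and assigned to the nearest centroid;
   nothing is refitted, so repeated prediction calls implement continuous
   surveillance of a fixed theme map.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `vectorize.min_df` | 1 | Minimum documents containing a token (counts; 1 = keep all) |
| `vectorize.keep_nonword` | `TRUE` | Keep punctuation/number/symbol tokens |
| `vectorize.d` | 300 | LSA dimensions (capped at min(n, V)) |
| `cluster.k_min`–`k_max` | 50–500 | Silhouette sweep range (clusters) |
| `cluster.max_iter` | 300 | Lloyd iteration cap |
| `topics.t_min`–`t_max` | 1–10 | Topic-number sweep range |
| `topics.alpha` | `"auto"` = 50/T | Symmetric document–topic prior |
| `topics.beta` | 0.01 | Symmetric topic–word prior |
| `topics.gibbs_iters` | 1000 | Gibbs sweeps per LDA fit |
| `topics.coherence_top_m` | 10 | Top words per topic entering coherence |
| `topics.epsilon` | 1 | Coherence smoothing constant |
| `interpret.n_centroid_terms` | 10 | Centroid terms per cluster |
| `seed` | 1 | Global seed; all stage seeds derive from it |

The LDA priors are the canonical collapsed-Gibbs defaults. The coherence
variant is the UMass document-co-occurrence score with $\varepsilon = 1$
and document frequencies taken from the cluster's **own** documents; a
coherence computed against global document frequencies would mix
cross-cluster vocabulary into a per-cluster quality measure. A cluster's
coherence at a given $T$ is the unweighted mean over its $T$ topics, and
the selection curve is the unweighted mean over clusters, so small
clusters count as much as large ones — the selected $T$ must serve every
cluster, not just the big ones.

## Numerical choices and degenerate inputs

* **Ties** are always broken toward the lowest index: nearest-centroid
  ties to the lowest cluster id, equal silhouette scores to the smaller
  $k$, equal coherence averages to the smaller $T$, equal term weights to
  lexicographic order. Determinism everywhere makes refits byte-identical.
* **Empty clusters** during Lloyd iteration are refilled with the point
  farthest from its current centroid, so every cluster is non-empty by
  contract. The within-cluster sum of squares is recorded at every
  iteration and asserted non-increasing.
* **Singleton clusters** get silhouette 0 by convention (the coefficient
  is otherwise undefined for them).
* **Documents with no in-vocabulary tokens** transform to a zero tf-idf
  row; at prediction time they are assigned (to the centroid nearest the
  origin) and flagged rather than rejected, since new literature will
  always contain new vocabulary.
* **Records without a publication year** are clustered normally but
  excluded from trend series, where they are tallied separately — the year
  only matters to the temporal analysis.
* **Unparseable years** (a value present but not a number) drop the record
  on ingestion with a warning; records without a title are dropped too, as
  the title is the minimum text the pipeline requires. An empty abstract is
  retained as the empty string, so title-only records participate fully.
* The collapsed Gibbs sampler uses R's RNG, so a `set.seed()` makes runs
  bit-reproducible; per-cluster and per-$T$ seeds are derived
  deterministically from the global seed.

## The built-in lemmatizer

The study-scale analyses this package targets normally use a neural
lemmatizer; such engines are external, non-deterministic across versions,
and heavy. The package therefore ships a rule-based English lemmatizer
(irregular-form table plus suffix rules with a final-consonant undoubling
heuristic) as the reproducible default, and accepts any engine through the
`lemmatizer_plugin()` contract: a named, deterministic, length-preserving
token transform that is the identity on non-word tokens. The built-in
rules are deliberately conservative; they handle the plural/gerund/past
inflections that dominate scientific prose and leave rare forms
untouched. Idempotence (`lemmatize(lemmatize(x)) == lemmatize(x)`) is a
tested invariant.

## The synthetic corpus generator

`synthetic_spec()` plants $T$ themes with pairwise-disjoint signature
vocabularies (20 words each by default) inside a shared 500-word
background following a Zipf law with exponent 1.1 — a realistic heavy tail
that produces both very common and effectively rare background words.
Each token of a document is drawn i.i.d.: with probability 0.7 uniformly
from the document's theme signature, otherwise from the background.
Titles are 5–15 tokens, abstracts 50–200; years are uniform in per-theme
windows (a late window plants an emergent theme, an early-ending one a
defunct theme); journals are uniform over a small pool.

The i.i.d. mixture was chosen over a full LDA generative process because
it gives planted structure to *both* halves of the pipeline with
analytically known parameters: document-level separation for k-means
(documents of a theme concentrate around a common direction) and
word-level co-occurrence for the topic model. Under the default
conditions, sweeping $k$ over 2–10 recovers the planted theme count with
Adjusted Rand Index ≥ 0.9 in at least 9 of 10 seeds, and held-out
documents map back to their themes through the frozen model.

What the generator does **not** emulate — and therefore what passing
tests do not show about real corpora: English syntax and collocation
structure, overlapping theme vocabularies (real themes share words),
document-length/topic correlations, citation structure, and the soft,
hierarchical theme boundaries of real literatures. Results on the
generator demonstrate the machinery is correct, not that any particular
real corpus will cluster as cleanly; on real literatures, where themes
overlap heavily, mean silhouette values an order of magnitude lower than
on planted data are normal, and manual inspection of the term lists
remains essential.

## Design decisions taken where the design was open

* **Both directions of label agreement are reported.** When manual labels
  are evaluated against the automatic term lists, term-side fractions
  (share of LDA/centroid terms appearing in the normalised label phrase)
  and phrase-side coverage (share of label words covered by the
  intersection of both lists) answer different questions, and summaries of
  either direction appear in the literature; `evaluate_label_overlap()`
  computes both rather than guessing.
* **Sweep granularity.** One seeded k-means run per candidate $k$, with
  the per-$k$ seed derived from the global seed, makes the full sweep
  reproducible and its cost linear in the range; the sweep endpoints and
  step are configurable, and the range is inclusive at both ends (the
  50–500 default at step 1 is 451 runs).
* **Model persistence** is a directory of TSV files plus a JSON manifest
  (vocabulary and idf, LSA basis, centroids, assignments, term lists,
  effective configuration and its hash). Open formats keep the artifact
  inspectable and language-agnostic; numeric fields are written with 17
  significant digits so a reloaded model reproduces training assignments
  exactly. Every written table carries the configuration hash as a
  leading comment line.
* **Problem sizes in the shipped tests** are scaled to the structure being
  tested: corpora of 60–200 synthetic documents, sweeps over 2–10
  clusters and 1–4 topics, and Gibbs chains of 50–500 sweeps. These sizes
  exercise every contract (the algorithms are size-agnostic) while a full
  test run stays comfortably interactive.

## Known limitations

* k-means assumes roughly spherical clusters in the reduced space; a
  large non-spherical theme may split into sub-themes. The silhouette
  criterion shares this geometry.
* The topic number is global by design (comparability across clusters),
  which can under-fit unusually heterogeneous clusters.
* The built-in lemmatizer is English-only and rule-based; morphology
  outside its rules passes through unchanged.
* UMass coherence depends on the smoothing constant and the reference
  collection; absolute coherence values are not comparable across corpora
  or toolchains, only across $T$ within one sweep.
* Trend series count publications per calendar year; a partially covered
  final year shows an apparent decline that is an artifact of coverage,
  not of interest.

## A worked run

```{r example, eval = FALSE}
gen <- generate_corpus(synthetic_spec(n_themes = 3, docs_per_theme = 20,
                                      seed = 15))
cfg <- pipeline_config(cluster = list(k_min = 2, k_max = 8),
                       topics = list(t_min = 1, t_max = 3,
                                     gibbs_iters = 200),
                       seed = 7)
bundle <- run_fit(gen$corpus, cfg)
autoplot(bundle$k_sweep)
score_recovery(gen$gold, bundle$kmeans_model$assignments)
trend_series(gen$corpus, bundle$kmeans_model$assignments)
```

The README shows the printed output of this run.
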