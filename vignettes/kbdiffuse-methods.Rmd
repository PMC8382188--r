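---
title: "Methods: k-mer knowledge-bases, diffusion, and the benchmarking protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer knowledge-bases, diffusion, and the benchmarking protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbdiffuse)
```

## Overview

kbdiffuse treats every data type it manages — gene sets, ontology term
definitions, user notes — as text. A knowledge base is a set of named
collections of text items, one shared feature catalog of k-mers, one
unit-norm sparse vector per item, and one co-occurrence matrix per
collection. Two query mechanisms (nearest-neighbor search and greedy
decomposition) and one query transform (diffusion) operate on this
representation. This vignette records the model, the tunable
parameters, the design choices made where the design was genuinely
open, and what the synthetic fixtures do and do not establish.

## Encoding model

Tokenization lowercases (configurable), splits on whitespace, and
strips leading/trailing punctuation, so gene symbols and ontology
identifiers such as `MP:0001262` survive as single tokens. Words of
length at most k pass through whole; longer words become their
overlapping k-mers. k-merization is what makes matching robust to
morphology and spelling ("prostatitis" shares `prosta`/`rostat` with
"prostate").

A first corpus pass counts, per k-mer, the number of documents
containing it (n) out of N documents, and assigns weight
`w = c0 − c1·log10(n/N)`, clipped at zero. The two constants span the
useful regimes:

| parameter | default | meaning |
|---|---|---|
| `k` | 6 | k-mer length; 6 suits gene symbols and English morphology, 8 is a reasonable choice for large mixed-text instances |
| `c0`, `c1` | 0, 1 | information-content weighting; use `c0 = 1, c1 = 0` (uniform) for unweighted gene sets |
| `max_features` | 200,000 | catalog cap; beyond it the most document-frequent k-mers are kept, ties broken lexicographically so builds are deterministic |

Document values accumulate `(1 + log m) · w · a` per word occurring m
times, where the sublinear `1 + log m` term is the standard
log-frequency damping and `a = k/L` for words of length L > k. The k/L
factor is our concrete choice for down-weighting the overlapping,
content-sharing k-mers of a long word: it makes a word's total mass
roughly independent of its length, is trivially testable, and is
exposed as an implementation detail rather than a scientific claim —
other reasonable adjustments (e.g. 1/sqrt of the k-mer count) would
serve the same purpose. Encoded documents are normalized to unit L2
norm; queries are encoded raw and normalized only where cosine
comparability requires it.

## Store, tiers, and co-occurrence

Collections built by `kb_build()` are primary tier and immutable.
`kb_add_item()` writes only to user-tier collections, which keeps
provenance explicit, makes additions O(item length) regardless of
primary data size, and lets `kb_drop_collection()` restore the
original state exactly. The embedded store persists via a single file
(`kb_save()`/`kb_load()`); no database server is involved because the
store contract — keyed retrieval and collection scoping — does not
need one at desktop scale.

Each collection's co-occurrence matrix C is incremented per item by
`1/L` for every ordered pair of its L distinct features, including the
diagonal. "Length of the item" is interpreted as the number of distinct
catalog features; this makes the diagonal `c_ii` equal to the weighted
number of items containing feature i, which is exactly the denominator
row normalization needs. The update is symmetric, order-invariant, and
linear — properties the test suite asserts directly.

## Diffusion

The diffusion matrix of a collection is
`D_ij = (c_ij/c_ii) · 2 w_i w_j/(w_i + w_j)`. Row-normalizing by `c_ii`
puts every source feature on the same scale (unit diagonal); the
harmonic-mean factor lets informative k-mers participate in proportion
to their weight and annihilates transfer to or from zero-weight k-mers.
Rows with `c_ii = 0` are empty: a feature never seen in a collection
contributes nothing, and no smoothing prior is added.

`diffuse()` computes `q → q + Σ_d s_d D_d q` with the sources of every
`D_d` restricted to the support of the *original* query (1-step
diffusion). With several collections the transform is organized in two
passes — pass one computes each collection's imputation from the
original sources, pass two sums them into the query — so collections
interact additively and features imputed by one collection never source
diffusion from another. This is the conservative reading of multi-pass
semantics consistent with the 1-step restriction; iterated
(multi-step) diffusion is deliberately not offered, as it densifies
vectors and over-smooths. Strengths `s_d ≥ 0` are user-chosen per
query; all-zero strengths give the identity. There is no automatic
strength optimizer — `evaluate_translation()` makes manual sweeps over
`s` easy, which is the calibration mode we expect users to apply.

After diffusion, search and decomposition re-normalize the query to
unit norm. Stored items are unit vectors, so without re-normalization
the similarity scale (though not the ranking) would depend on `s`;
renormalization keeps scores interpretable as cosines.

## Search and decomposition

Search is exact brute-force cosine ranking with deterministic
tie-breaking by item id. An approximate index would only change speed,
not results; at the collection sizes this package targets (up to tens
of thousands of items) exact ranking is fast, deterministic, and
oracle-free, so no approximate backend is shipped.

Decomposition greedily selects the item most similar to the current
residual, then refits the coefficients of *all* selected items by
unconstrained least squares against the original query, then
recomputes the residual. Termination: the requested number of
components, any coefficient ≤ 0, a singular normal system, or a
residual below `1e-6` times the query norm (a numerical floor, not a
model parameter). Least-squares refitting is the simplest rule
consistent with "a linear combination that approximately reconstructs
the query"; a frozen-coefficient matching-pursuit variant is available
via `refit = FALSE`. The result is greedy and non-unique — it is a
readable explanation of the query, not an optimal sparse code. With
one component, decomposition and search coincide exactly.

## Gene-set benchmarking protocol

`generate_benchmarks()` builds synthetic query sets from a collection
by three recipes: the number of source components (1–4), the coverage
fraction transferred from each source set, and the signal fraction of
source genes in the final set. Choices made where the recipe left
room:

* coverage takes an exact rounded fraction of each source set, sampled
  without replacement (a Bernoulli per-gene mode exists as an option);
  exact fractions make the generated sets' composition reproducible
  and the coverage parameter literal;
* noise genes are drawn from the universe excluding all genes of the
  chosen source sets, so the realized signal fraction equals the
  parameter up to rounding;
* the full standard grid (4 component levels × 4 coverages × 4
  signals × 1000 replicates) enumerates 64,000 sets;
  `benchmark_grid_size()` verifies the bookkeeping without building
  them.

Scoring pairs ground-truth components one-to-one with reported hits
and sums Jaccard indexes; the score lies in [0, number of components]
and counts recovered constituents. Pairing defaults to the optimal
assignment (exhaustive over at most 4 components, hence exact), since
rank-positional pairing makes the score depend on an arbitrary
ordering of the ground-truth components; the positional mode is kept
for comparison. The Fisher baseline ranks sets by the one-sided
hypergeometric tail (`stats::phyper`), ties broken by id.

`genomic_window_sets()` tiles chromosomes with overlapping windows
(default step: half the window size) and assigns a gene to a window
when its start coordinate lies inside; genes straddling a boundary are
thus counted once per window rather than split, a simple rule that
keeps set membership unambiguous.

## Ontology translation protocol

`read_obo()` is a minimal OBO stanza parser (no installed R package in
this stack reads OBO). Items carry a term's name, definition, comment,
synonyms, parent names, and top-ancestor name, tying each term to its
meaning and hierarchy position. The evaluation graph uses is_a edges
only, undirected and unweighted — part_of and other relations are
excluded because mixing relation types would make path lengths
incomparable across ontologies. The top ancestor follows is_a edges
upward with smallest-id tie-breaking. Translation metrics are exact-id
precision at rank 1 and within the top 5, and the shortest-path error
of the rank-1 and best-of-top-5 hits; unreachable pairs are excluded
from mean path lengths and counted separately, since any finite
substitute value would be arbitrary.

## Synthetic fixtures: what they emulate, what they do not

The fixture generators define the study conditions for the tests:

* `make_set_collection()` — 500 sets of sizes 5–100 over a
  20,000-symbol universe emulates a filtered GO biological-process
  collection. `nesting_fraction` derives sets from earlier sets as
  subsets or supersets, emulating parent/child redundancy;
  `disjoint = TRUE` partitions the universe, the clean regime where
  exact multi-component recovery is possible. Gene symbols are
  fixed-width (`g00042`), so at k = 6 each symbol is one feature and
  set items behave as bags of genes.
* `make_toy_ontology_pair()` — two small ontologies with a known
  one-to-one translation. Easy pairs share a distinctive concept word;
  hard pairs share no vocabulary at all, and a bridge corpus of short
  snippets pairs each hard query word with its target-side
  counterpart. A single-word-per-document corpus puts the query
  vocabulary into the catalog without creating co-occurrence, so the
  *only* route from a hard query to its target is diffusion — which is
  precisely the property under test. Boilerplate words are placed in
  an intermediate fraction of target items so that, without diffusion,
  hard queries retrieve five positive-similarity distractors and the
  expected term genuinely sits outside the top 5 rather than tying at
  zero.
* `make_text_corpus()` — random pseudo-word documents with planted
  always-co-occurring word pairs, for co-occurrence and diffusion
  oracles.

Passing tests on these fixtures show that the algorithms have the
claimed behavior under controlled conditions: they do not show that
real GO term-size and overlap distributions, real ontology definition
styles, or a real natural-language frequency corpus would yield the
same precision numbers. In particular the published HP-to-MP
translation rates depend on those resources and on an external
reference mapping, and are out of scope here; the packaged evaluation
reproduces the *schema* and the qualitative rescue behavior, not those
percentages.

## Problem sizes and determinism

The test suite and the acceptance script run at reduced but
non-trivial sizes chosen to exercise the full stack: 500-set
collections with 100–200 benchmark replicates per regime, a
1000-document corpus for the search/oracle agreement check, and
catalogs up to 200 features for the dense diffusion oracle. Every
stochastic step derives from an explicit seed; identical seeds give
byte-identical fixtures, benchmarks, and rankings.

## Known limitations

* The catalog is frozen at build time: user-added snippets can only
  use k-mers already seen, so a bridge note introducing entirely new
  vocabulary on *both* sides has no effect. Building with a broad
  background corpus mitigates this.
* Exact search is O(items) per query; beyond ~10^5 items an
  approximate index would be the natural extension.
* Decomposition's least-squares refit solves a dense t × t system; it
  is intended for small component counts (t ≤ 10).
* The long-word k/L adjustment is one defensible choice among several;
  instances built with a different adjustment are not comparable.
* Mean path-length summaries exclude unreachable pairs, so they are
  conditional means and should be read alongside the reported
  unreachable count.
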