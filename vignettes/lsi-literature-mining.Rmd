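---
title: "Entity-centric literature mining with latent semantic indexing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entity-centric literature mining with latent semantic indexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litlsi)
```

## The problem

Curated databases that link biomedical entities such as microRNAs to
diseases and biological processes cannot keep pace with the literature.
`litlsi` treats the problem as vector-space information retrieval: every
entity is represented by one *entity document* — the concatenation of the
titles and abstracts of all citations that reference it — and entities,
terms and free-text queries are compared by the cosine of the angle
between their vectors in a reduced-rank concept space. Because the space
is built from word co-usage patterns across the whole collection, it
captures implicit associations (two entities studied in similar contexts
score high even if never co-cited), which pure co-occurrence counting
cannot.

## Corpus assembly

**Synonym expansion.** A microRNA appears in text under many spellings.
`expand_synonyms()` crosses the base tokens `mir`, `miR` and `microRNA`
with hyphenated and unhyphenated joins to the symbol's suffix
(`mir19a`, `mir-19a`, `microRNA19a`, ...). The base set is an argument
because the naming conventions in a given corpus are not enumerable once
and for all; the expansion always contains the input symbol and is closed
under hyphen removal. `build_query_string()` turns the set into a sorted
OR-joined query for a retrieval service; the package ships a file-backed
`mock_retrieval_client()` implementing the same `fetch_citation_ids()`
interface a live PubMed E-utilities client would.

**Nonspecific-citation filtering.** Citations that reference very many
entities (typically high-throughput screens) carry little
entity-specific signal and would glue unrelated entities together. The
cutoff is data-derived: with Q1 and Q3 the quartiles of the
citations-per-entity-count distribution, a count is a right outlier when
it exceeds `Q3 + 1.5 * IQR`, and the threshold is the smallest observed
outlier. Citations referencing *threshold or more* entities are removed
(the fence itself is strict, the removal rule inclusive — the natural
reading of "smallest right outlier" as the first disallowed value).
Quartiles use linear interpolation between order statistics (R's default
type 7); the convention is an argument of
`compute_citation_specificity_threshold()` because other conventions move
the fence slightly on small samples. If no count exceeds the fence, the
sentinel `NA` disables filtering.

**Concatenation.** Entity documents concatenate title then abstract per
citation, citations in ascending ID order, pieces joined by single
spaces. Order and separator are not meaningful for a bag-of-words model;
they are fixed purely so that rebuilds are byte-identical.

## Tokenization and weighting

`tokenize()` lowercases, preserves hyphens and underscores (gene and
miRNA symbols depend on them), replaces every other punctuation
character with a space — deletion would fuse unrelated words across
slashes and commas, e.g. `p53/MDM2` must yield two tokens — and drops
stop words and tokens without any alphanumeric character. No stemming is
applied, numeric tokens are kept (both are deliberate: stemming biomedical
term variants is error-prone, and dose/identifier tokens can be
discriminative); a generic English stop list ships with the package and
any file can be substituted.

Counts are weighted by `a_ij = log2(1 + f_ij) * g_i`, where the global
weight `g_i` is one minus the normalized entropy of the term's
distribution across documents: a term confined to one document gets
`g = 1`, a term spread perfectly evenly gets `g = 0` and drops out of the
model. Conventions: `0 log 0 = 0`; for a single-document corpus the
denominator `log2 n` vanishes and `g` is defined as 1. The computation
touches only the nonzero entries of the sparse matrix; tests assert
equality with a dense entrywise evaluation to 1e-12.

## Rank selection

The weighted matrix is factorized as `A = U S V'`. The truncation rank
is derived from the spectrum itself: with contributions
`C_i = sigma_i^2 / sum sigma^2` and normalized entropy
`E = -sum C_i log C_i / log r`, the retained rank is
`k = round(E * r)`, clamped to `[1, r]`. `E` is base-invariant (the base
cancels between numerator and normalizer; natural logs are used
internally) and measures how evenly variation spreads over the `r`
axes, so `E * r` estimates how many axes carry real structure. Rounding
is round-half-even (R's `round()`); the choice between flooring and
rounding moves `k` by at most one and no downstream result in this
package is sensitive to it. `r` is the numerical rank: singular values
below `1e-10` of the largest are excluded from the contribution vector,
since they are noise amplified into the entropy otherwise. The SVD sign
ambiguity is fixed by making the largest-magnitude component of each
left singular vector positive.

On desk-scale problems the dense LAPACK SVD via `svd()` is exact and
fast; the matrices this package targets (hundreds to a few thousand
entities) are well within its reach.

## Queries and ranking

A term query is the binary indicator `q0` over the vocabulary projected
as `q0' U_k` — the sum of the matched terms' `U_k` rows. Entities are
ranked by cosine against the rows of `V_k S_k`, the entity coordinates
scaled by the singular values. The entity-query direction is defined by
the symmetry of the factorization (`A' = V S U'`): the sum of the
queried entities' **unscaled** `V_k` rows, ranked against `U_k S_k` on
the term side. The unscaled choice mirrors `q0' U_k` exactly; summing
scaled rows instead reweights multi-entity queries toward
high-variance axes but leaves single-entity rankings unchanged (cosine
is scale-invariant). Ties are broken lexicographically by ID. Term
rankings are truncated to the top 300 by default — full vocabularies are
impractical to inspect — and entity rankings to the top 50 in the
pipeline outputs; both are configuration values, not constants.

Entities with a zero vector in the truncated space (possible when all
their terms load on discarded axes) are given cosine 0 rather than NaN
and flagged by the normalizing accessor.

## Evaluation

`roc_auc()` is the pairwise-ordering probability with ties counted half
(the Mann–Whitney convention, computed via midranks), equal to the area
under the ROC curve: 1 when all positives precede all negatives, 0.5 in
expectation for random rankings. `cohesion()` scores an entity set by
using each member in turn as a query against a universe *excluding that
member* — including it would add a guaranteed top-ranked positive and
inflate every AUC — and taking the median of the n leave-one-out AUCs.
The universe is an explicit parameter (defaulting to all model entities)
because gold standards often define their own rankable universe. The
co-occurrence baseline scores entity pairs by shared-citation counts;
`compare_cohesions()` applies a two-sided Wilcoxon rank-sum test to the
per-member AUC lists (normal approximation with tie correction, exact
for small tie-free samples). Corpus-construction quality is summarized
by `information_gain()` (relative citation surplus of retrieval over
curation, which can be negative) and `recall_against_curated()`.

## Network analysis

`pairwise_cosines()` gives the entity-entity similarity matrix; edges
connect pairs whose cosine is strictly above the 99th percentile of all
off-diagonal pairwise values (upper triangle only, each unordered pair
once; linear-interpolation percentile). The largest connected component
is clustered with standard k-means on the unit-normalized scaled LSI
vectors, fixed seed, 10 restarts, default k = 25. k-means cannot see the
graph, so "clusters are connected subgraphs" is treated as a property to
*report* (the `connected` flag per cluster when a graph is supplied),
not a constraint to enforce. The degenerate partitions k = 1 and
k = number-of-points are handled directly since the iterative algorithm
rejects them. Clusters are annotated by querying the model with all
their members and extracting the top 300 terms.

## The synthetic corpus generator

`generate_synthetic_corpus()` emulates the structure the pipeline is
built to detect: entities partitioned into topics, each topic owning a
disjoint specific vocabulary, each document mixing topic words with
shared background words. Defaults: 50 entities in 5 topics, 5 citations
per entity, Poisson document lengths of mean 60 tokens (title 8 tokens,
the remainder abstract), 60 % topic words, 40 topic words per topic, 120
background words. These are one-time choices representing a small,
clearly structured literature: group sizes of ten entities match typical
disease panels, five citations reflect the few-citations-per-entity
median of real collections, and a 60/40 topic/background mix leaves
enough shared vocabulary that recovery is non-trivial. Optional
background-only citations linked to many entities exercise the
specificity filter.

What the generator does *not* emulate: Zipfian word frequencies,
correlated topics, entities belonging to several topics, citation counts
spanning orders of magnitude, or negated statements. Passing
parameter-recovery tests therefore shows the machinery is correct on
separable structure, not that real-literature performance reaches any
particular level.

A note on spectra: a background-only corpus (no topics) concentrates its
entropy-weighted spectrum on a handful of accidentally skewed terms, so
spectrum entropy is *not* monotone in topic separation; the reliable
signatures of planted structure, asserted in the tests, are the dominance
of the top-t contributions and a selected k well below r.

## Problem sizes and determinism

Tests run on corpora of 30–50 entities and vocabularies of a few hundred
terms, where the full pipeline fits in seconds; oracle-equivalence
checks use random instances up to 200 terms x 50 entities against
brute-force loops. All randomness (corpus generation, k-means restarts)
flows through explicit seeds; identical configuration and seed reproduce
byte-identical corpora, models and reports. Model directories serialize
factors as text with full double precision, so a reloaded model ranks
identically to within 1e-10.

## Known limitations

Bag-of-words semantics cannot distinguish negated from affirmed
statements; very common domain words that are not in the stop list are
down-weighted but not removed; the entropy rule for k has no optimality
guarantee and alternative rank-selection strategies are out of scope;
k-means with a fixed k inherits k-means' sensitivity to initialization
(mitigated by restarts) and the choice of k is the user's.
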