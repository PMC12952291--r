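---
title: "Methods: description-similarity retrieval of expression series and its benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: description-similarity retrieval of expression series and its benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The retrieval model

geosift addresses a dataset-discovery problem: a researcher has already found
a handful of gene-expression series relevant to a topic (a *reference set*)
and wants to find more among thousands of candidates, using nothing but the
free-text descriptions submitters wrote — title, summary, and overall design.
The working assumption is that submitters' domain language is distinctive
enough that descriptions of series on the same topic resemble each other more
than they resemble descriptions of unrelated series.

Every backend reduces this to scoring each candidate against the reference
set and sorting:

* **Vector backends** (`hashed_tfidf`, `external:<id>`): each document is a
  fixed-length embedding; the reference set is represented by the unweighted
  element-wise mean of its members' embeddings, and candidates are ranked by
  cosine similarity to that mean. Cosine is used because it is cheap,
  interpretable, and invariant to vector magnitude.
* **`word_overlap`**: the Jaccard index of unique-token sets. The reference
  set is pooled into a single unique-token set; each candidate is scored as
  intersection-over-union against the pool. (Pooling is this package's
  extension: set-overlap has no native notion of averaging.)
* **`bm25` / `bm25plus`**: lucene-variant BM25 with the candidates as the
  indexed collection and the concatenation of all reference tokens as the
  query. `bm25plus` is the same scorer applied to stop-word-free, Porter-
  stemmed tokens; plain `bm25` deliberately keeps stop words, matching the
  two ways the algorithm is applied in practice.

Ties are broken by ascending accession, so a ranking is a deterministic
function of the corpus content, never of input order.

## Text cleaning

Cleaning steps run in a fixed order: strip HTML tags, strip URLs
(scheme-prefixed or `www.`-prefixed substrings up to whitespace), lower-case,
replace non-alphanumeric characters with spaces, collapse whitespace,
tokenise on spaces, remove stop words, stem. The order itself is a design
choice — the key constraints are that HTML/URL stripping must precede
punctuation removal (otherwise tag and URL fragments leak into tokens) and
stop-word matching must see fully normalised tokens. Non-alphanumerics are
*replaced by spaces* rather than deleted so `TNBC/ER-` yields two tokens
instead of one fused one. Because stop-word matching happens after
punctuation removal, the bundled stop list is expanded to its cleaned
fragments (`aren't` contributes `aren` and `t`). Cleaning with `stem = FALSE`
is idempotent; stemming is not guaranteed to be, which is why the idempotence
property is only claimed for stem-free policies.

The stop-word list is a fixed file shipped with the package
(`inst/extdata/stopwords_en.txt`), and the stemmer is a complete
implementation of the classic Porter algorithm, tested against the published
rule examples. Pinning both in the package keeps every result reproducible
against a versioned artifact rather than a floating third-party resource.

## BM25 parameters

The scorer is the lucene variant:
`IDF(t) = ln(1 + (N − df + 0.5)/(df + 0.5))` and
`TF(t,d) = f/(f + k1·(1 − b + b·|d|/avgdl))`, with defaults `k1 = 1.5`,
`b = 0.75` — the common defaults for this variant. `k1` controls how quickly
repeated terms saturate; `b` controls how strongly long documents are
penalised. Both are exposed on `bm25_index()`. The implementation is checked
against an independent straight-from-formula oracle to 1e-9 on a seeded
50-document corpus.

## Chunking

Long texts can be split into windows of 256 characters with 20 characters of
overlap, each window embedded, and the window vectors averaged (unweighted).
The 256-character threshold and 20-character overlap are the aggregation
contract; the window *length* reuses the threshold because that is the
minimal-assumption choice. Boundaries are character-exact and may split
words — chunking is defined over characters, not tokens. Averaging is
unweighted and operates on raw backend vectors (no per-chunk re-normalisation
before the mean); cosine similarity is computed after averaging.

## The deterministic hashed TF-IDF embedder

Neural sentence embedders are supported only through the external-vector
adapter (`read_vector_table()`); the package does not run them. To exercise
the full vector-retrieval geometry offline, `hashed_tfidf` embeds a document
by hashing each token to one of `dim` (default 256) buckets and accumulating
`tf · ln((N+1)/(df+1))` with a ±1 sign, then L2-normalising. Both the bucket
and the sign come from FNV-1a 32-bit hashes with the published constants
(offset basis 2166136261, prime 16777619; the sign hash salts the token). A
32-bit hash is used because its products fit exactly in double-precision
integers, giving byte-identical vectors on every platform without 64-bit
integer arithmetic. Signed hashing makes bucket collisions cancel in
expectation, so documents with disjoint vocabularies have near-orthogonal
vectors (|cos| < 0.2 at dim ≥ 256 for short documents). Zero vectors (empty
documents) are permitted; cosine against a zero vector is defined as 0 and
such candidates are flagged in the ranking.

## The benchmark protocol

For each condition, the annotated series are randomly permuted under a seed;
the first ⌈n/2⌉ become the reference set and the rest comparison set A (the
reference set takes the extra member when n is odd). Comparison set B is
everything else in the candidate pool — series annotated for other conditions
or none. Class imbalance is simulated by subsampling B to `ratio × |A|`
members, or keeping all of it. The ranking over A ∪ B is scored with:

* **AUPRC**, computed as *average precision* — the mean of precision at the
  rank of each relevant item. No trapezoidal interpolation is used: average
  precision is ranking-native and can be checked exhaustively against a
  brute-force precision@k enumeration (the test suite does this for every
  label pattern of every list length up to 12). A useful calibration fact:
  under a uniformly random ranking the expected average precision is *above*
  the prevalence of relevant items for short lists — for 5 relevant among 55
  it is 0.151 versus a prevalence of 0.091, a value the test suite verifies
  against the exact negative-hypergeometric closed form. Expected AP only
  approaches prevalence as the list grows.
* **Recall@n**, the fraction of relevant items in the top n, which is monotone
  non-decreasing in n by construction.
* **Median model rank**: within each condition backends are ranked by
  descending AUPRC (average ranks on ties) and each backend's median rank
  across conditions is reported — the aggregation to use when AUPRCs are not
  comparable across conditions.

`run_benchmark()` crosses conditions × backends × ratios × chunking settings.
Each cell's seed is derived by hashing the master seed with the cell
coordinates, so a single cell can be re-run in isolation and reproduce
exactly. A consequence (chosen deliberately, following the protocol's
independent-reproducibility requirement) is that different backends see
different reference/comparison splits of the same condition; comparisons
across backends are therefore over the split distribution, not a single
shared split.

## The synthetic corpus generator

The generator emulates the one structural property that makes
description-based retrieval work: condition-specific vocabulary embedded in
varying amounts of shared background language, across documents of varying
length. Tokens are pronounceable consonant-vowel pseudo-words from a seeded
generator; the alphabet deliberately excludes the letters that Porter suffix
rules act on, so stemming is the identity on synthetic tokens and vocabulary
disjointness survives every cleaning policy. Defaults mirror a six-condition
study design with 12 annotated series per condition and 100 distractors;
asymmetric condition sizes are available via `per_condition_sizes`.

`cross_condition_overlap` draws a fraction of each condition's vocabulary
from a single *confusable pool* shared by all conditions. A pool — rather
than borrowing from ring-neighbour conditions — was chosen because pooled
sharing makes between-condition document overlap increase monotonically in
the parameter all the way to 1 (where condition vocabularies coincide and
retrieval collapses toward chance); neighbour-borrowing is non-monotone at
the extremes (at full overlap each condition simply adopts a different
neighbour's vocabulary and conditions become disjoint again), which would
break the degradation experiment the parameter exists for.

`degrade_corpus()` injects HTML tags, URLs, random casing, and punctuation at
per-token rates. All injected material is removable by the default cleaning
policy, so degrade-then-clean restores the pristine token multisets exactly —
the property the cleaning tests rely on.

What the generator does *not* emulate: real biomedical prose statistics
(topic structure, synonymy, polysemy, misspellings), species or platform
diversity, SuperSeries/SubSeries text duplication, and annotation noise.
Passing the synthetic benchmark therefore demonstrates that the machinery —
splits, representations, ranking, metrics — is correct and deterministic, not
that any backend will reach a particular AUPRC on real repository metadata.

## Numerical and experimental choices

* Problem sizes: the test suite and acceptance script use corpora of 24–172
  series, a 50-document BM25 oracle corpus, 10,000 Monte-Carlo permutations,
  and 20 corpora per overlap level — sizes at which every property is stable
  yet the whole suite runs in well under a minute per file.
* The overlap-degradation experiment uses short documents (6–15 tokens) and a
  condition-token rate of 0.5. At the generator's realistic defaults the
  word-overlap AUPRC saturates at 1.0 for moderate overlap (a ceiling
  effect), which would make level means tie; the short-document design keeps
  the three overlap levels separated by several standard errors. The
  generator defaults themselves are unchanged.
* Empty cleaned documents score 0 and are flagged rather than dropped, so
  candidate counts are preserved.
* Chunking requires `threshold_chars ≥ chunk_size_chars` so a split text
  always fills its first window.
* All randomness goes through `withr::with_seed()`: no function disturbs the
  caller's RNG state, and equal seeds give byte-identical outputs (the CLI
  manifests record basenames only, for the same reason).

## Limitations

The package ranks candidates against the *mean* of the reference set; keeping
reference embeddings separate and training a discriminative ranker is out of
scope, as is running or fine-tuning any neural language model, querying live
repository services, and the inferential statistics one might apply to
benchmark output tables downstream.
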