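---
title: "Harvesting specialty term sets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harvesting specialty term sets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`termharvest` builds per-specialty term sets from specialty-labeled
title/abstract corpora and uses them as document features for multi-label
specialty classification. This vignette explains the method, the
assumptions behind it, the parameters that matter, and the design choices
made where the procedure is genuinely open.

## The pipeline

1. **Acquisition.** Documents arrive labeled with one or more clinical
   specialties (JSON-lines, `read_corpus_jsonl()`). For corpus building
   from a bibliographic service, `build_pubmed_query()` emits a
   deterministic boolean query per specialty descriptor (language
   restriction via `LA`; every specialty name across the fields TA, TIAB,
   CN, SI, OT, AD, MH:noexp, SH:noexp; "see also" headings restricted to
   MH). Retrieval itself sits behind a fetcher interface
   (`fixture_fetcher()` ships a canned implementation) so nothing in the
   package touches the network. Sub-specialty corpora are merged into
   their parents (`merge_sublevel_terminology()`), under-populated
   specialties are pruned (`filter_small_specialties()`, default
   `min_titles = 1000` — the only corpus-size threshold stated anywhere in
   the workflow, reused for the final level-1 pruning as well), duplicate
   specialties are collapsed to the lexicographically smallest identifier
   (`dedupe_specialties()` — an arbitrary but deterministic choice), and
   case reports are split off as the evaluation genre
   (`partition_case_reports()`, case-insensitive match on the publication
   type).

2. **Term extraction.** Texts are split into sentences at `.`, `;`, `?`,
   `!`; tokens are whitespace-separated after isolating punctuation
   (keeping `/` and `-` intact between digits so numeric dates survive as
   single tokens, where the date rule can catch them); candidates are all
   contiguous n-grams with n ≤ 3, never crossing sentence boundaries.
   Cleansing removes stopword/punctuation/digit unigrams, bigrams with any
   stopword or punctuation token, trigrams with two such tokens or a
   stopword in last position, and any n-gram containing a geographic name
   or a date/year token. Finally, terms are normalized to lowercase
   singular form by a Spanish suffix rule table (`-ces → -z`; drop `-es`
   after n/r/l/d/j; drop vowel-final `-s`; invariant-word and
   -itis/-osis exceptions). The rule table is deliberately modest — no
   accent restoration ("lesiones" becomes "lesion"), no irregular
   plurals — and is pluggable (`singularizer` argument) for users with a
   full lemmatizer. Cleansing runs before normalization so stopword
   matching sees surface tokens; the two stages are independent functions,
   so the opposite order is available by composition.

3. **Weighting.** `compute_term_stats()` populates, per term, the global
   occurrence count F (each text counted once), the containing-text count
   N_t, the specialty count E_t, and per specialty the credited
   occurrence count fe and containing-text count Nt_e. Multi-label texts
   are credited to every label, so `Σ_i fe_i ≥ F`; the TGM entropy sum is
   therefore normalized by `F* = Σ_i fe_i`, which collapses to F for
   single-label corpora. The three measures are TGM (entropy-derived
   global concentration, in [0, 1]), LPM (share-of-term + share-of-
   specialty, in [0, 2]) and LRM (share-of-term gated on the specialty's
   90th frequency percentile). The measures operate at specialty level,
   not text level — the design answer to corpora where nearly every
   within-text term frequency is 1 and TF-IDF carries no signal.

4. **Stop-n-gram filtering.** Candidates are terms in strictly more than
   `min_specialty_count` specialties (default `floor(0.9·k)`, "more than
   90% of the available specialties"); a candidate is removed when the
   standard deviation and the maximum of its LRM values, over the
   specialties where it appears, are both strictly below `threshold_sd`
   and `threshold_max`. The published sets are always disjoint from the
   stop list; the excluded rows are retained internally so scoring can
   reproduce both protocol variants (with / without stop n-grams).

5. **Classification.** A document's feature for specialty *s* is the sum
   of TGM values of its n-gram occurrences found in *s*'s term set
   (`specialty_score()`; occurrences count with multiplicity because the
   sum is indexed by the document's n-grams — a `unique_terms` switch is
   provided). Learners (random forest, decision tree, kNN, MLP) predict
   each label independently at threshold 0.5; evaluation pools true/false
   positives over all (document, label) pairs into micro-averaged
   precision, recall and F1.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `n_max` | 3 | longer n-grams are too rare to weight reliably |
| `min_titles` | 1000 | minimum corpus size for stable specialty statistics |
| percentile gate | P90, nearest-rank | deterministic; no interpolation convention to choose |
| `min_specialty_count` | `floor(0.9·k)` | candidacy = "more than 90% of specialties"; an explicit override exists because a deployment may prefer a hand-picked constant (e.g. 47 of 51) |
| `threshold_sd`, `threshold_max` | none — mandatory | no universal values exist; see below |
| TGM denominator | `log N` | as defined; see below |
| split fraction | 0.75 | 54,879 evaluation texts → 41,159 train / 13,720 test |
| MLP | 1 hidden layer, 100 units, lr 0.001 analogue | the reference network shape; scaled down on synthetic corpora (below) |

**Stop-filter thresholds.** `threshold_sd` and `threshold_max` have no
defaults by design: their natural scale is the uniform relevance share. A
term spread evenly over k specialties has LRM ≈ 1/k everywhere, so the
shipped example configuration (`example_filter_thresholds()`,
`inst/extdata/example_filter_config.json`) uses `threshold_max = 3/k` and
`threshold_sd = 0.4/k`, calibrated on the synthetic generator: uniform
planted terms sit comfortably below both bounds, while a term with even
one specialty of concentrated relevance exceeds `threshold_max`.

**TGM denominator.** As defined, the entropy sum is divided by `log N`
(total texts). Under that reading a term spread uniformly over k
specialties scores `1 − log k / log N`, which is 0 only when k = N — the
"uniform spread scores 0" intuition holds exactly only with a `log k`
denominator. The formula is implemented as defined (with clamping to
[0, 1]), and `tgm(..., denominator = "k")` exposes the variant; the
discrepancy is intentional and surfaced rather than silently "fixed".

## The synthetic generator

`generate_corpus()` emulates the corpus structure the measures assume:

- **exclusive terms** (per specialty, 1 occurrence per containing
  document) reproduce the rare-but-predictive regime; they should reach
  the top LPM decile of their home specialty and must never be flagged as
  stop n-grams;
- **shared terms** span a few related specialties (intermediate scores);
- **ubiquitous terms** are planted uniformly across all specialties
  (1 + Poisson(0.5) occurrences per containing document) and are the
  designed stop-n-gram targets;
- **fillers** are stopwords (which cleansing must remove entirely — the
  no-leakage property) plus pronounceable nonsense words drawn with
  Zipf-like weights.

Generation is a pure function of the spec, seed included. What the
generator does *not* model: Spanish morphology and grammar (documents are
bags of tokens with an occasional sentence boundary), thesaurus structure,
realistic label correlations, or abstracts with content beyond restated
title tokens. Passing recovery tests therefore demonstrates that the
measures and the filter behave as designed under their own assumptions —
not that any particular real corpus will yield the same rates.

**Problem sizes.** The validation corpus is 20 specialties × 200
documents (recovery, 5 seeds). The classification benchmark
(`benchmark_spec()`) is 10 specialties × 120 documents, 30 exclusive
terms per specialty with 2 per document, 30% multi-label, 40% case
reports; TF-IDF uses `min_df = 2` and `max_features = 150`, and the MLP
uses 16 hidden units with 100 optimizer iterations. These sizes keep a
full multi-seed comparison in the order of minutes on one CPU while
preserving the regime of interest: with a capped vectorizer vocabulary,
frequency-ranked feature selection crowds out the rare exclusive terms,
which is precisely where aggregated term-set features should (and do,
per the acceptance suite) help. The learner *contract* defaults stay at
the reference settings (100 hidden units, 100 trees, k = 5).

## Numerical and implementation choices

- `0·log 0 := 0` (entropy limit); natural logarithms (the ratio of two
  logs is base-invariant).
- Population (not sample) standard deviation in the stop filter:
  deterministic and well-defined on two-element profiles.
- Nearest-rank percentile: `sorted[ceiling(0.9·n)]`, over the distinct
  terms of the specialty.
- Train size of the seeded split is `floor(f·n)` — the arithmetic that
  reproduces the published 41,159/13,720 partition of 54,879 texts.
- TF-IDF follows the common vectorizer convention the reference settings
  come from: lowercase, stopword removal before n-gram formation, tokens
  of ≥ 2 alphanumeric characters, raw counts × `ln((1+N)/(1+df)) + 1`,
  L2 row normalization, vocabulary fitted on training data only. No
  text-mining package providing this was available as a dependency, so
  the vectorizer is implemented in-package on sparse matrices.
- In combined feature mode the specialty-score block is L2-normalized per
  document row (`normalize_scores = TRUE`): raw score sums grow with
  document length and would dominate the unit-norm TF-IDF block for
  distance-based learners.
- The MLP is a single `nnet` network with one sigmoid output per label
  under cross-entropy — the native multi-label form of a one-hidden-layer
  perceptron; the other learners use binary relevance (one binary model
  per label). `nnet` differs from the reference implementation in
  optimizer (BFGS, no early stopping) and hidden activation (logistic,
  not ReLU); `randomForest` splits on Gini rather than entropy (the
  decision tree does use the entropy criterion via
  `rpart(split = "information")`). All learners sit behind one contract
  and are pluggable.
- Specialty similarity (the method for which is an open choice) defaults
  to cosine over LRM-weighted term vectors, with a Jaccard set-overlap
  variant; empty specialties get similarity 0, including the diagonal,
  with a warning.

## Known limitations

- The singularizer is a suffix heuristic; it under-normalizes irregular
  plurals and drops no accents ("lesiones" → "lesion" rather than
  "lesión"). Idempotence is guaranteed; linguistic perfection is not.
- Acronym/expansion harvesting and part-of-speech-aware term chunking are
  out of scope.
- Real-corpus headline numbers depend on the retrieved collection;
  everything quantitative in the test suite and acceptance script is
  computed on the synthetic generator under the conditions above.
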