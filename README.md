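# termharvest

Tools for harvesting **clinical-specialty-specific term sets** ("interface
terminologies") from specialty-labeled collections of publication titles and
abstracts, and for using those term sets as features in multi-label
specialty classification.

Curated reference terminologies favour terms of wide-spread use and lack the
very specific vocabulary used inside a single specialty. `termharvest`
builds that vocabulary bottom-up from text: it extracts word n-grams
(n = 1–3) from titles/abstracts, cleans them against stopword and
geographic gazetteers, weights every term per specialty with three
specialty-aware measures, removes "stop n-grams" whose relevance profile is
flat across nearly all specialties, and assembles one weighted term set per
specialty. The intended users are biomedical text-mining / clinical NLP
researchers working with class-labeled corpora — the shipped resources
target Spanish, but every word list is pluggable.

## The measures

For a term *t*, with *N* texts overall, *N_e* texts in specialty *i*,
*F^t* occurrences of *t* (each text counted once), *N^t* texts containing
*t*, *fe^t_i* occurrences of *t* in texts of specialty *i* and *N^t_e_i*
texts of *i* containing *t*:

- **TGM** (term global measure) — an entropy derivative of the term's
  concentration across specialties:
  `TGM(t) = 1 + Σ_i (fe_i/F*) · log(fe_i/F*) / log N`, with
  `F* = Σ_i fe_i`. A term occurring in a single specialty scores exactly 1;
  evenly spread terms score low. Values are clamped to [0, 1].
- **LPM** (local precision measure) — specificity of *t* for *i*:
  `LPM(t,i) = N^t_e_i / N^t + N^t_e_i / N_e_i`, in [0, 2]; it is 2 exactly
  when the term occurs only in texts of *i* and in all of them. High LPM
  marks highly specific terms even when they are rare — the regime where
  per-document TF-IDF breaks down because nearly every term frequency is 1.
- **LRM** (local relevance measure) — descriptive capacity of *t* for *i*,
  gated on the specialty's 90th frequency percentile
  `L = P90({F^t : t ∈ i})`: `LRM(t,i) = N^t_e_i / N^t` if `F^t ≥ L`, else 0.

A term is a **stop n-gram** when it appears in more than 90% of the
specialties and the standard deviation *and* maximum of its LRM values
(over the specialties where it appears) both fall below configurable
thresholds — i.e. it is everywhere, and nowhere important. Documents can
then be scored against the resource: the feature for specialty *s* is the
sum of TGM values over the document's n-gram occurrences that belong to
*s*'s term set, giving one feature per specialty for classification.

Multi-label texts are first-class: a text with several specialty labels
contributes its occurrences to every label's counts, while the global
counts `F^t`, `N^t` count it once.

## Worked example

```r
library(termharvest)
library(dplyr)

# a synthetic corpus with known ground truth: 6 specialties x 80 documents
spec <- synthetic_spec(num_specialties = 6, docs_per_specialty = c(80, 80),
                       n_exclusive = 8, multilabel_fraction = 0, seed = 42)
gen <- generate_corpus(spec)
gen$corpus
#> <specialty_corpus> 480 documents, 6 specialties

cfg     <- default_cleansing_config()
ngrams  <- extract_corpus_ngrams(gen$corpus, cfg)
weights <- weigh_terms(compute_term_stats(ngrams, gen$corpus))

th    <- example_filter_thresholds(6)
stops <- detect_stop_ngrams(weights, th$threshold_sd, th$threshold_max)
resource <- build_resource(weights, stops, provenance = th)
resource
#> <term_resource> 5177 terms over 6 specialties; 23 stop n-grams

# most specific terms of one specialty: the planted exclusive terms,
# with TGM = 1 (single-specialty) and top-decile LRM = 1
weights %>% filter(specialty == "spec01") %>% arrange(desc(LPM)) %>%
  select(term, fe, F, E_t, TGM, LPM, LRM) %>% head(5)
#>   term      fe     F   E_t   TGM   LPM   LRM
#> 1 xebabi    27    27     1     1  1.34     1
#> 2 xebabo    26    26     1     1  1.31     1
#> 3 xebabe    22    22     1     1  1.27     1
#> 4 xebabu    21    21     1     1  1.26     1
#> 5 xebade    18    18     1     1  1.23     1

head(stops, 6)   # planted ubiquitous-uniform terms are flagged
#> [1] "kobaba" "kobaba kobabi" "kobabe" "kobabi" "kobabo" "kobabu"

# score a new document: one exclusive term of spec01, one of spec02,
# and a stop n-gram (which contributes nothing)
doc <- tibble(doc_id = "new", normalized = c("xebabu", "xebado", "kobaba"))
round(specialty_score(doc, resource)["new", ], 3)
#> spec01 spec02 spec03 spec04 spec05 spec06
#>      1      1      0      0      0      0
```

The real-data workflow is identical, starting instead from
`read_corpus_jsonl()` (one JSON document per line) or from query strings
produced by `build_pubmed_query()` and a user-supplied fetcher; see
`inst/cli/termharvest.R` for a shell front-end covering every step
(`extract`, `weigh`, `resource-build`, `similarity`, `filter-lexicon`,
`classify`, `simulate`).

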