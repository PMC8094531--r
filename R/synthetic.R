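# Synthetic specialty-labeled corpora with planted ground truth.
#
# The generator emulates the corpus structure the weighting measures
# assume: rare specialty-exclusive terms with high predictive power
# (typically one occurrence per containing text — the "TF = 1" regime of
# short titles), terms shared by a few related specialties, ubiquitous
# unspecific terms spread uniformly over all specialties (the stop-n-gram
# profile), and function-word fillers drawn from the stopword list plus
# pronounceable nonsense words. Every planted term's class is recorded so
# recovery can be checked end to end. It does not attempt Spanish grammar,
# thesaurus structure or real record XML.

.syllables <- c("ba", "be", "bi", "bo", "bu", "da", "de", "di", "do", "du",
                "ga", "go", "gu", "la", "le", "li", "lo", "lu", "ma", "me",
                "mi", "mo", "mu", "na", "ne", "ni", "no", "nu", "pa", "pe",
                "pi", "po", "pu", "ra", "re", "ri", "ro", "ru", "sa", "se",
                "si", "so", "su", "ta", "te", "ti", "to", "tu")

# deterministic pronounceable pseudo-words: prefix + 2 index-coded syllables
make_words <- function(n, prefix) {
  if (n == 0) return(character())
  ns <- length(.syllables)
  stopifnot(n <= ns * ns)
  i <- seq_len(n) - 1L
  paste0(prefix, .syllables[i %/% ns + 1L], .syllables[i %% ns + 1L])
}

#' Specification of a synthetic specialty corpus
#'
#' All knobs of the planted-term generator. Generation is a pure function
#' of the spec (the seed is part of it). Defaults describe the standard
#' validation corpus: 20 specialties of 200 documents, 30% of documents
#' carrying a second label, 10 exclusive terms per specialty (one
#' occurrence per containing document), 20 shared-rare terms spanning 4
#' specialties each, 15 ubiquitous terms present uniformly in a quarter of
#' all documents, and a filler pool of stopwords plus 120 pronounceable
#' nonsense words sampled with Zipf-like weights.
#'
#' @param num_specialties Number of specialties.
#' @param docs_per_specialty Length-2 integer vector (min, max) of
#'   documents drawn per specialty.
#' @param multilabel_fraction Probability that a document carries one
#'   additional label (up to `max_labels`).
#' @param max_labels Maximum labels per document.
#' @param n_exclusive Exclusive terms planted per specialty.
#' @param exclusive_per_doc How many of its specialty's exclusive terms a
#'   document contains (one occurrence each).
#' @param n_shared Shared-rare terms in total.
#' @param shared_breadth Number of specialties each shared term spans.
#' @param p_shared Per-document inclusion probability of an eligible
#'   shared term.
#' @param n_ubiquitous Ubiquitous-uniform terms.
#' @param p_ubiquitous Per-document inclusion probability of each
#'   ubiquitous term (identical in every specialty); occurrences per
#'   containing document are 1 + Poisson(0.5).
#' @param n_fillers Pronounceable filler words (stopword fillers are added
#'   on top, from `stopword_fillers`).
#' @param stopword_fillers How many stopwords to mix into the filler pool.
#' @param title_tokens Length-2 (min, max) token count of a title.
#' @param abstract_prob Probability a document has an abstract.
#' @param abstract_tokens Length-2 (min, max) token count of an abstract.
#' @param sentence_break_prob Probability a sentence boundary (".") is
#'   inserted mid-title.
#' @param case_report_fraction Fraction of documents tagged with the
#'   "Case Reports" publication type.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(num_specialties = 20L,
                           docs_per_specialty = c(200L, 200L),
                           multilabel_fraction = 0.3, max_labels = 2L,
                           n_exclusive = 10L, exclusive_per_doc = 2L,
                           n_shared = 20L, shared_breadth = 4L,
                           p_shared = 0.05,
                           n_ubiquitous = 15L, p_ubiquitous = 0.25,
                           n_fillers = 120L, stopword_fillers = 60L,
                           title_tokens = c(8L, 14L),
                           abstract_prob = 0.1,
                           abstract_tokens = c(25L, 40L),
                           sentence_break_prob = 0.3,
                           case_report_fraction = 0.25,
                           seed = 1L) {
  spec <- list(num_specialties = as.integer(num_specialties),
               docs_per_specialty = as.integer(docs_per_specialty),
               multilabel_fraction = multilabel_fraction,
               max_labels = as.integer(max_labels),
               n_exclusive = as.integer(n_exclusive),
               exclusive_per_doc = as.integer(exclusive_per_doc),
               n_shared = as.integer(n_shared),
               shared_breadth = as.integer(shared_breadth),
               p_shared = p_shared,
               n_ubiquitous = as.integer(n_ubiquitous),
               p_ubiquitous = p_ubiquitous,
               n_fillers = as.integer(n_fillers),
               stopword_fillers = as.integer(stopword_fillers),
               title_tokens = as.integer(title_tokens),
               abstract_prob = abstract_prob,
               abstract_tokens = as.integer(abstract_tokens),
               sentence_break_prob = sentence_break_prob,
               case_report_fraction = case_report_fraction,
               seed = as.integer(seed))
  counts <- unlist(spec[c("num_specialties", "n_exclusive", "n_shared",
                          "n_ubiquitous", "n_fillers", "stopword_fillers")])
  stopifnot(all(counts >= 0), spec$num_specialties >= 1)
  fracs <- unlist(spec[c("multilabel_fraction", "p_shared", "p_ubiquitous",
                         "abstract_prob", "sentence_break_prob",
                         "case_report_fraction")])
  stopifnot(all(fracs >= 0 & fracs <= 1))
  stopifnot(length(spec$docs_per_specialty) == 2,
            spec$docs_per_specialty[1] >= 1,
            diff(spec$docs_per_specialty) >= 0,
            spec$exclusive_per_doc <= spec$n_exclusive ||
              spec$n_exclusive == 0)
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic specialty corpus with ground truth
#'
#' Assembles documents from planted terms and fillers according to the
#' spec's distributions. Every document contains `exclusive_per_doc`
#' exclusive terms of each of its labels; ubiquitous and eligible shared
#' terms are added by independent coin flips; the remaining title length
#' is filled from the filler pool (Zipf-like weights), the token order is
#' shuffled and a sentence boundary is occasionally inserted. Byte-
#' identical output is guaranteed for identical specs.
#'
#' @param spec A [synthetic_spec].
#' @param stopwords Stopword list the stopword fillers are sampled from;
#'   defaults to the shipped Spanish list.
#' @return A list with elements `corpus` (a [specialty_corpus]) and
#'   `truth` (tibble `term`, `class` in exclusive/shared/ubiquitous/
#'   filler/filler_stopword, `specialty` — the home specialty of exclusive
#'   terms, `expected` — the expected downstream behavior).
#' @export
generate_corpus <- function(spec, stopwords = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(stopwords)) {
    stopwords <- read_wordlist(system.file("extdata", "stopwords_es.txt",
                                           package = "termharvest"))
  }
  withr::with_seed(spec$seed, generate_corpus_impl(spec, stopwords))
}

generate_corpus_impl <- function(spec, stopwords) {
  k <- spec$num_specialties
  specialties <- sprintf("spec%02d", seq_len(k))

  exclusive <- if (spec$n_exclusive > 0) {
    all_ex <- make_words(k * spec$n_exclusive, "xe")
    split(all_ex, rep(specialties, each = spec$n_exclusive))
  } else {
    stats::setNames(rep(list(character()), k), specialties)
  }
  shared <- make_words(spec$n_shared, "vi")
  shared_homes <- lapply(seq_len(spec$n_shared), function(i) {
    sample(specialties, min(spec$shared_breadth, k))
  })
  ubiquitous <- make_words(spec$n_ubiquitous, "ko")
  filler_words <- make_words(spec$n_fillers, "wa")
  filler_stop <- if (spec$stopword_fillers > 0) {
    sample(stopwords, min(spec$stopword_fillers, length(stopwords)))
  } else {
    character()
  }
  fillers <- c(filler_stop, filler_words)
  filler_w <- if (length(fillers)) 1 / seq_along(fillers) else numeric()

  shared_by_spec <- lapply(specialties, function(s) {
    shared[vapply(shared_homes, function(h) s %in% h, logical(1))]
  })
  names(shared_by_spec) <- specialties

  rows <- list()
  doc_no <- 0L
  for (s in specialties) {
    n_docs <- if (spec$docs_per_specialty[1] == spec$docs_per_specialty[2]) {
      spec$docs_per_specialty[1]
    } else {
      sample(spec$docs_per_specialty[1]:spec$docs_per_specialty[2], 1)
    }
    for (d in seq_len(n_docs)) {
      doc_no <- doc_no + 1L
      labs <- s
      extra <- stats::rbinom(1, spec$max_labels - 1L, spec$multilabel_fraction)
      if (extra > 0 && k > 1) {
        labs <- c(labs, sample(setdiff(specialties, s), min(extra, k - 1L)))
      }
      toks <- character()
      for (lab in labs) {
        ex <- exclusive[[lab]]
        if (length(ex)) {
          toks <- c(toks, sample(ex, min(spec$exclusive_per_doc, length(ex))))
        }
      }
      if (spec$n_ubiquitous > 0) {
        present <- stats::runif(spec$n_ubiquitous) < spec$p_ubiquitous
        reps <- 1L + stats::rpois(sum(present), 0.5)
        toks <- c(toks, rep(ubiquitous[present], reps))
      }
      elig_shared <- unique(unlist(shared_by_spec[labs]))
      if (length(elig_shared)) {
        present <- stats::runif(length(elig_shared)) < spec$p_shared
        toks <- c(toks, elig_shared[present])
      }
      target <- sample(spec$title_tokens[1]:spec$title_tokens[2], 1)
      n_fill <- max(target - length(toks), 0L)
      if (n_fill > 0) {
        if (!length(fillers)) {
          stop("infeasible spec: positive document length but empty filler pool")
        }
        toks <- c(toks, sample(fillers, n_fill, replace = TRUE, prob = filler_w))
      }
      toks <- sample(toks)
      title <- paste(toks, collapse = " ")
      if (length(toks) > 3 && stats::runif(1) < spec$sentence_break_prob) {
        cut <- sample(2:(length(toks) - 1), 1)
        title <- paste(paste(toks[1:cut], collapse = " "), ". ",
                       paste(toks[(cut + 1):length(toks)], collapse = " "),
                       sep = "")
      }
      abstract <- ""
      if (stats::runif(1) < spec$abstract_prob && length(fillers)) {
        alen <- sample(spec$abstract_tokens[1]:spec$abstract_tokens[2], 1)
        atoks <- sample(fillers, alen, replace = TRUE, prob = filler_w)
        # abstracts restate some of the title's planted content
        atoks <- sample(c(atoks, toks[seq_len(min(3, length(toks)))]))
        abstract <- paste(atoks, collapse = " ")
      }
      ptypes <- if (stats::runif(1) < spec$case_report_fraction) "Case Reports" else character()
      rows[[doc_no]] <- list(id = sprintf("doc%05d", doc_no), title = title,
                             abstract = abstract,
                             publication_types = ptypes,
                             specialties = labs)
    }
  }
  docs <- tibble(
    id = vapply(rows, `[[`, character(1), "id"),
    title = vapply(rows, `[[`, character(1), "title"),
    abstract = vapply(rows, `[[`, character(1), "abstract"),
    publication_types = lapply(rows, `[[`, "publication_types"),
    specialties = lapply(rows, `[[`, "specialties"),
    language = "es"
  )
  truth <- bind_rows(
    tibble(term = unlist(exclusive, use.names = FALSE),
           class = "exclusive",
           specialty = rep(specialties,
                           vapply(exclusive, length, integer(1))),
           expected = "high_lpm_in_home_specialty"),
    tibble(term = shared, class = "shared", specialty = NA_character_,
           expected = "intermediate"),
    tibble(term = ubiquitous, class = "ubiquitous", specialty = NA_character_,
           expected = "stop_ngram_candidate"),
    tibble(term = filler_words, class = "filler", specialty = NA_character_,
           expected = "unspecific_background"),
    tibble(term = filler_stop, class = "filler_stopword",
           specialty = NA_character_, expected = "removed_by_cleansing")
  )
  list(corpus = specialty_corpus(docs), truth = truth)
}

#' Standard synthetic benchmark conditions
#'
#' The fixed study conditions of the package's multi-label classification
#' benchmark: 10 specialties of 120 documents, 30 exclusive terms per
#' specialty with 2 planted per document (so each exclusive term is rare —
#' the "TF = 1" regime a capped TF-IDF vocabulary tends to miss, which is
#' exactly where aggregated term-set features should help), 30% of
#' documents with a second label, and 40% tagged as case reports so both
#' the build side and the evaluation side are well populated.
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec].
#' @export
benchmark_spec <- function(seed = 1L) {
  synthetic_spec(num_specialties = 10L, docs_per_specialty = c(120L, 120L),
                 n_exclusive = 30L, case_report_fraction = 0.4, seed = seed)
}

#' Generate a multi-label classification benchmark
#'
#' Generates a corpus with [generate_corpus()] and partitions it with
#' [partition_case_reports()]: the non-case-report documents form the
#' build set the term resource is harvested from; the case reports form
#' the evaluation benchmark, with their gold label sets returned
#' separately. The classifier-side 75/25 split is applied downstream with
#' [split_train_test()].
#'
#' @param spec A [synthetic_spec] with `multilabel_fraction > 0` and
#'   `case_report_fraction > 0`.
#' @param stopwords Passed to [generate_corpus()].
#' @return A list: `build_set` and `test_set` ([specialty_corpus]), `gold`
#'   (named list of label sets for the test documents) and `truth`.
#' @export
generate_multilabel_benchmark <- function(spec, stopwords = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$multilabel_fraction <= 0) {
    stop("benchmark generation requires multilabel_fraction > 0")
  }
  if (spec$case_report_fraction <= 0) {
    stop("benchmark generation requires case_report_fraction > 0")
  }
  gen <- generate_corpus(spec, stopwords)
  parts <- partition_case_reports(gen$corpus)
  if (is.null(parts$test_set) || is.null(parts$build_set)) {
    stop("degenerate partition: both build and test sets must be non-empty")
  }
  gold <- stats::setNames(parts$test_set$documents$specialties,
                          parts$test_set$documents$id)
  list(build_set = parts$build_set, test_set = parts$test_set,
       gold = gold, truth = gen$truth)
}
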