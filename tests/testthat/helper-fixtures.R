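# Small fixture builders shared across test files.

tiny_docs <- function(n, specialty = "derm", prefix = "d",
                      title = "piel lesión cutánea") {
  tibble::tibble(
    id = paste0(prefix, seq_len(n)),
    title = rep(title, n),
    specialties = replicate(n, specialty, simplify = FALSE)
  )
}

tiny_corpus <- function(n = 3, specialty = "derm", ...) {
  specialty_corpus(tiny_docs(n, specialty, ...))
}

# a corpus with explicit per-document titles and label sets
corpus_from <- function(titles, labels, ids = NULL, ptypes = NULL) {
  n <- length(titles)
  docs <- tibble::tibble(
    id = ids %||% sprintf("d%02d", seq_len(n)),
    title = titles,
    specialties = lapply(labels, identity)
  )
  if (!is.null(ptypes)) docs$publication_types <- lapply(ptypes, identity)
  specialty_corpus(docs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a weights-like table directly from per-term LRM profiles
weights_from_profiles <- function(profiles) {
  dplyr::bind_rows(lapply(names(profiles), function(t) {
    p <- profiles[[t]]
    tibble::tibble(term = t, specialty = names(p), fe = 1L, Nt_e = 1L,
                   F = 10L, N_t = 10L, E_t = length(p),
                   TGM = 0.5, LPM = 0.5, LRM = unname(p))
  }))
}

test_config <- function() {
  cleansing_config(
    stopwords = c("de", "en", "la", "el", "y", "con", "los", "las", "a"),
    gazetteer = c("españa", "madrid", "chileno", "estados unidos")
  )
}
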