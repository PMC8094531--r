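# N-gram pipeline: sentence splitting, tokenization, 1-3-gram generation,
# rule-based cleansing against stopword/gazetteer lists, and Spanish
# singular normalization.

#' Split text into sentences
#'
#' Sentence boundaries are the characters `.`, `;`, `?` and `!`; the
#' boundary characters are removed and empty or whitespace-only segments
#' are dropped. N-grams never cross these boundaries.
#'
#' @param text Character vector; each element is split independently.
#' @return A list (one element per input string) of character vectors of
#'   sentences, or a single character vector when `text` has length 1.
#' @export
#' @examples
#' split_sentences("Caso clínico. Mujer de 34 años; fiebre alta")
split_sentences <- function(text) {
  out <- lapply(strsplit(text, "[.;?!]"), function(s) {
    s <- trimws(s)
    s[nzchar(s)]
  })
  if (length(text) == 1) out[[1]] else out
}

#' Tokenize sentences
#'
#' Whitespace tokenization after separating punctuation and symbol
#' characters into standalone tokens. Unicode letters (including accented
#' Spanish characters) are kept intact; `/` and `-` between digits are kept
#' inside the token so numeric dates such as `12/05/2019` survive as one
#' token (and can then be matched by the date-removal rule).
#'
#' @param x Character vector of sentences.
#' @return A list of character token vectors, one per sentence.
#' @export
tokenize_text <- function(x) {
  # all punctuation/symbols except / and - become standalone tokens
  x <- gsub("([^\\P{P}/-]|\\p{S})", " \\1 ", x, perl = TRUE)
  # / and - split off unless flanked by digits on both sides
  x <- gsub("((?<![0-9])[/-])", " \\1 ", x, perl = TRUE)
  x <- gsub("([/-](?![0-9]))", " \\1 ", x, perl = TRUE)
  lapply(strsplit(trimws(x), "\\s+"), function(t) t[nzchar(t)])
}

#' Extract word n-grams from one sentence
#'
#' Term candidates are contiguous word n-grams with n between 1 and
#' `n_max`; a sentence of m tokens yields `m - n + 1` n-grams of size n
#' (none when m < n). N-grams are emitted in sentence order, unigrams
#' first.
#'
#' @param sentence A single sentence string, or an already-tokenized
#'   character vector of tokens.
#' @param n_max Largest n-gram size, 1 to 3.
#' @return A tibble with columns `n`, `tok1`, `tok2`, `tok3` (NA beyond
#'   position n) and `surface` (space-joined form).
#' @export
#' @examples
#' extract_ngrams("Manejo práctico de inmunosupresores en dermatología")
extract_ngrams <- function(sentence, n_max = 3L) {
  stopifnot(n_max %in% 1:3)
  tokens <- if (length(sentence) == 1 && !is.null(sentence)) {
    tokenize_text(sentence)[[1]]
  } else {
    as.character(sentence)
  }
  ngram_table(list(tokens), doc_id = NA_character_, n_max = n_max)[, -1]
}

# Build the (doc_id, n, tok1..tok3, surface) table for a list of token
# vectors; `doc_id` is recycled per sentence.
ngram_table <- function(tok_list, doc_id, n_max = 3L) {
  doc_id <- rep_len(doc_id, length(tok_list))
  pieces <- vector("list", n_max)
  for (n in seq_len(n_max)) {
    cnt <- pmax(lengths(tok_list) - n + 1L, 0L)
    ids <- rep(doc_id, cnt)
    cols <- lapply(seq_len(n), function(j) {
      unlist(lapply(tok_list, function(t) {
        m <- length(t)
        if (m < n) character() else t[j:(m - n + j)]
      }), use.names = FALSE)
    })
    t2 <- if (n >= 2) cols[[2]] else rep(NA_character_, length(ids))
    t3 <- if (n >= 3) cols[[3]] else rep(NA_character_, length(ids))
    pieces[[n]] <- tibble(doc_id = ids, n = rep(n, length(ids)),
                          tok1 = cols[[1]], tok2 = t2, tok3 = t3)
  }
  out <- bind_rows(pieces)
  out$surface <- ifelse(
    out$n == 1, out$tok1,
    ifelse(out$n == 2, paste(out$tok1, out$tok2),
           paste(out$tok1, out$tok2, out$tok3))
  )
  out
}

# ---- Cleansing ------------------------------------------------------------

#' Read a plain-text word list
#'
#' One entry per line, UTF-8, `#` starts a comment; entries are trimmed
#' and lowercased.
#'
#' @param path File path.
#' @return Character vector of lowercase entries.
#' @export
read_wordlist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- tolower(trimws(lines))
  unique(lines[nzchar(lines)])
}

#' Configuration for n-gram cleansing
#'
#' Bundles the linguistic resources the cleansing rules consult: a
#' stopword list, a geographic gazetteer (countries, regions,
#' nationalities; single- or multi-word entries) and date/year patterns.
#' All entries are lowercased; matching is case-insensitive.
#'
#' @param stopwords Character vector of stopwords.
#' @param gazetteer Character vector of geographic names/nationalities.
#' @param date_year_patterns Character vector of regular expressions a
#'   single token is matched against; defaults cover four-digit years
#'   1900-2099 and numeric dd/mm/yyyy and dd-mm-yyyy dates.
#' @return A list of class `cleansing_config`.
#' @export
cleansing_config <- function(stopwords, gazetteer = character(),
                             date_year_patterns = c(
                               "^(19|20)[0-9]{2}$",
                               "^[0-9]{1,2}[/-][0-9]{1,2}[/-][0-9]{2,4}$")) {
  stopifnot(length(stopwords) > 0)
  structure(
    list(stopwords = unique(tolower(stopwords)),
         gazetteer = unique(tolower(gazetteer)),
         date_year_patterns = date_year_patterns),
    class = "cleansing_config"
  )
}

#' Default cleansing configuration
#'
#' Uses the Spanish stopword list and geographic gazetteer shipped with
#' the package.
#'
#' @return A [cleansing_config].
#' @export
default_cleansing_config <- function() {
  cleansing_config(
    stopwords = read_wordlist(system.file("extdata", "stopwords_es.txt",
                                          package = "termharvest")),
    gazetteer = read_wordlist(system.file("extdata", "gazetteer_es.txt",
                                          package = "termharvest"))
  )
}

# per-token boolean flags used by the cleansing rules
token_flags <- function(tokens, config) {
  lower <- tolower(tokens)
  is_date <- rep(FALSE, length(tokens))
  for (pat in config$date_year_patterns) {
    is_date <- is_date | grepl(pat, tokens, perl = TRUE)
  }
  list(
    stop = lower %in% config$stopwords,
    punct = grepl("^[\\p{P}\\p{S}]+$", tokens, perl = TRUE),
    digit_punct = grepl("^[0-9\\p{P}\\p{S}]+$", tokens, perl = TRUE),
    date = is_date,
    geo = lower %in% config$gazetteer
  )
}

#' Remove non-term n-grams
#'
#' Applies five removal rules formulated for title/abstract term
#' candidates:
#' \enumerate{
#'   \item unigrams that are stopwords, punctuation marks or digits;
#'   \item bigrams containing at least one stopword or punctuation mark;
#'   \item trigrams containing at least two stopwords or punctuation
#'     marks, or whose last token is a stopword;
#'   \item n-grams containing a country, region or nationality name
#'     (single gazetteer tokens, or multi-word gazetteer entries matched
#'     on contiguous token spans);
#'   \item n-grams containing a date or year token.
#' }
#' Matching against the word lists is case-insensitive; survivors keep
#' their order. The operation is a pure filter, hence idempotent.
#'
#' @param ngrams A tibble as produced by [extract_ngrams()] /
#'   [ngram_table()] (columns `n`, `tok1`..`tok3`, `surface`).
#' @param config A [cleansing_config].
#' @return The filtered tibble.
#' @export
cleanse_ngrams <- function(ngrams, config) {
  stopifnot(inherits(config, "cleansing_config"))
  if (nrow(ngrams) == 0) return(ngrams)
  toks <- c(ngrams$tok1, ngrams$tok2, ngrams$tok3)
  uniq <- unique(toks[!is.na(toks)])
  fl <- token_flags(uniq, config)
  look <- function(col, flag) {
    v <- fl[[flag]][match(col, uniq)]
    v[is.na(v)] <- FALSE
    v
  }
  sp1 <- look(ngrams$tok1, "stop") | look(ngrams$tok1, "punct")
  sp2 <- look(ngrams$tok2, "stop") | look(ngrams$tok2, "punct")
  sp3 <- look(ngrams$tok3, "stop") | look(ngrams$tok3, "punct")
  sp_count <- sp1 + sp2 + sp3

  last_tok <- ifelse(ngrams$n == 1, ngrams$tok1,
                     ifelse(ngrams$n == 2, ngrams$tok2, ngrams$tok3))
  last_stop <- look(last_tok, "stop")

  geo <- look(ngrams$tok1, "geo") | look(ngrams$tok2, "geo") |
    look(ngrams$tok3, "geo")
  # multi-word gazetteer entries: check contiguous spans
  if (any(grepl(" ", config$gazetteer, fixed = TRUE))) {
    pair12 <- tolower(paste(ngrams$tok1, ngrams$tok2))
    pair23 <- tolower(paste(ngrams$tok2, ngrams$tok3))
    geo <- geo |
      (ngrams$n >= 2 & pair12 %in% config$gazetteer) |
      (ngrams$n == 3 & pair23 %in% config$gazetteer) |
      (ngrams$n == 3 & tolower(ngrams$surface) %in% config$gazetteer)
  }
  dated <- look(ngrams$tok1, "date") | look(ngrams$tok2, "date") |
    look(ngrams$tok3, "date")

  drop <- geo | dated |
    (ngrams$n == 1 & (look(ngrams$tok1, "stop") | look(ngrams$tok1, "digit_punct"))) |
    (ngrams$n == 2 & sp_count >= 1) |
    (ngrams$n == 3 & (sp_count >= 2 | last_stop))
  ngrams[!drop, , drop = FALSE]
}

# ---- Singular normalization ----------------------------------------------

# words (lowercase) left untouched by the plural-stripping rules
.singular_exceptions <- c(
  "lunes", "martes", "miércoles", "jueves", "viernes",
  "crisis", "dosis", "análisis", "síntesis", "génesis", "diagnosis",
  "prognosis", "tesis", "paréntesis", "diabetes", "herpes", "caries",
  "virus", "tórax", "tos", "mes", "gas", "más", "menos", "atlas",
  "pelvis", "cutis", "lupus", "fetus", "bilis", "apendicitis"
)

#' Normalize n-grams to singular form
#'
#' Token-wise rule-based Spanish singularization (e.g. "hematomas" →
#' "hematoma", "factores de riesgo" → "factor de riesgo"), followed by
#' lowercasing. The rules are: `-ces` → `-z`; drop `-es` after the
#' consonants n/r/l/d/j; drop a final `-s` after a vowel. Short tokens
#' (< 4 characters), a list of invariant words (days of the week,
#' "crisis", "dosis", ...) and medical forms ending in -itis/-osis/-asis
#' are left unchanged. The transformation is idempotent.
#'
#' The suffix table is deliberately pluggable: pass a different
#' `singularizer` to substitute a full lemmatizer.
#'
#' @param x Character vector of n-gram surface forms (tokens separated by
#'   spaces).
#' @param singularizer A function mapping a character vector of lowercase
#'   tokens to their singular forms; defaults to the built-in rule table.
#' @return Character vector of normalized (lowercase, singular) forms.
#' @export
#' @examples
#' normalize_singular(c("hematomas", "factores de riesgo"))
normalize_singular <- function(x, singularizer = singularize_es) {
  if (length(x) == 0) return(character())
  toks <- strsplit(tolower(x), " ", fixed = TRUE)
  lens <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  uniq <- unique(flat)
  mapped <- singularizer(uniq)
  flat <- mapped[match(flat, uniq)]
  vapply(split(flat, rep(seq_along(x), lens)), paste, character(1),
         collapse = " ", USE.NAMES = FALSE)
}

#' @rdname normalize_singular
#' @param tokens Character vector of lowercase tokens.
#' @export
singularize_es <- function(tokens) {
  out <- tokens
  nc <- nchar(tokens)
  keep <- nc < 4 | tokens %in% .singular_exceptions |
    grepl("(itis|osis|asis|esis|isis)$", tokens) |
    !grepl("s$", tokens)
  ces <- !keep & nc >= 5 & grepl("ces$", tokens)
  out[ces] <- sub("ces$", "z", tokens[ces])
  cons_es <- !keep & !ces & nc >= 5 & grepl("[nrldj]es$", tokens)
  out[cons_es] <- sub("es$", "", tokens[cons_es])
  vowel_s <- !keep & !ces & !cons_es & grepl("[aeiouáéíóú]s$", tokens)
  out[vowel_s] <- sub("s$", "", tokens[vowel_s])
  out
}

# ---- Whole-corpus extraction ----------------------------------------------

#' Extract, cleanse and normalize n-grams for every document in a corpus
#'
#' Runs the full candidate pipeline per document: title and abstract are
#' concatenated, split into sentences, tokenized, expanded into 1-`n_max`
#' grams (never crossing sentence boundaries), cleansed with
#' [cleanse_ngrams()] and singular-normalized.
#'
#' @param corpus A [specialty_corpus].
#' @param config A [cleansing_config]; `NULL` skips cleansing.
#' @param n_max Largest n-gram size (1-3).
#' @param normalize Add the `normalized` column (lowercase singular form).
#' @return A tibble with one row per surviving n-gram occurrence:
#'   `doc_id`, `n`, `surface`, `normalized`.
#' @export
extract_corpus_ngrams <- function(corpus, config = default_cleansing_config(),
                                  n_max = 3L, normalize = TRUE) {
  stopifnot(inherits(corpus, "specialty_corpus"))
  d <- corpus$documents
  text <- ifelse(nzchar(d$abstract), paste(d$title, d$abstract, sep = ". "), d$title)
  sent_list <- split_sentences(text)
  if (nrow(d) == 1) sent_list <- list(sent_list)
  sent_doc <- rep(d$id, lengths(sent_list))
  sentences <- unlist(sent_list, use.names = FALSE)
  if (length(sentences) == 0) {
    return(tibble(doc_id = character(), n = integer(),
                  surface = character(), normalized = character()))
  }
  tok_list <- tokenize_text(sentences)
  tab <- ngram_table(tok_list, doc_id = sent_doc, n_max = n_max)
  if (!is.null(config)) tab <- cleanse_ngrams(tab, config)
  out <- tab[, c("doc_id", "n", "surface")]
  if (normalize) out$normalized <- normalize_singular(out$surface)
  as_tibble(out)
}
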