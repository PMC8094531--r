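# Term weighting: the per-term / per-specialty count statistics and the
# three measures used to characterize a term's relation to the clinical
# specialties:
#   TGM  - entropy-derived global concentration measure, in [0,1];
#   LPM  - local precision (specificity) of a term for a specialty;
#   LRM  - local relevance, gated on the specialty's 90th frequency
#          percentile.
# The measures score a term by specialty rather than by text, so they
# remain informative when the within-text term frequency is almost always
# one (the "TF = 1" regime of short titles), and they credit multi-label
# texts to every one of their specialties.

#' Count statistics for every term in a corpus
#'
#' Computes, from the cleansed/normalized n-gram stream, the quantities
#' all three measures are built from: for each term t the total occurrence
#' count `F` (each text counted once, occurrences with multiplicity), the
#' number of texts containing t (`N_t`), the number of specialties
#' containing t (`E_t`), and for each specialty i the occurrence count
#' `fe` of t in texts of i and the number `Nt_e` of texts of i containing
#' t. A text with several labels contributes its occurrences to `fe` and
#' `Nt_e` of every label, while `F` and `N_t` count it once globally.
#'
#' @param ngrams A tibble with columns `doc_id` and `normalized` (one row
#'   per n-gram occurrence), as from [extract_corpus_ngrams()].
#' @param corpus The [specialty_corpus] the n-grams were extracted from.
#' @return A list of class `term_stats` with elements
#'   `corpus_stats` (list `N`, `N_e`, `k`),
#'   `terms` (tibble `term`, `F`, `N_t`, `E_t`) and
#'   `by_specialty` (tibble `term`, `specialty`, `fe`, `Nt_e`).
#' @export
compute_term_stats <- function(ngrams, corpus) {
  stopifnot(inherits(corpus, "specialty_corpus"))
  stopifnot(all(c("doc_id", "normalized") %in% names(ngrams)))
  unknown <- setdiff(unique(ngrams$doc_id), corpus$documents$id)
  if (length(unknown)) {
    stop("n-gram stream references unknown document ids: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  occ <- ngrams %>%
    count(.data$doc_id, term = .data$normalized, name = "n_occ")

  terms <- occ %>%
    group_by(.data$term) %>%
    summarise(F = sum(.data$n_occ), N_t = dplyr::n(), .groups = "drop")

  labels <- corpus_labels(corpus)
  by_spec <- occ %>%
    inner_join(labels, by = c(doc_id = "id"), relationship = "many-to-many") %>%
    group_by(.data$term, .data$specialty) %>%
    summarise(fe = sum(.data$n_occ), Nt_e = dplyr::n(), .groups = "drop")

  e_t <- by_spec %>% count(.data$term, name = "E_t")
  terms <- left_join(terms, e_t, by = "term")
  terms$E_t[is.na(terms$E_t)] <- 0L

  structure(
    list(
      corpus_stats = list(N = corpus$N, N_e = corpus$N_e, k = length(corpus$N_e)),
      terms = terms,
      by_specialty = by_spec
    ),
    class = "term_stats"
  )
}

#' @export
print.term_stats <- function(x, ...) {
  cat("<term_stats> ", nrow(x$terms), " terms over ",
      x$corpus_stats$k, " specialties (N = ", x$corpus_stats$N, ")\n", sep = "")
  invisible(x)
}

#' Term global measure (TGM)
#'
#' An entropy derivative quantifying how concentrated a term's occurrences
#' are across specialties:
#' \deqn{TGM(t) = 1 + \sum_i \frac{(fe_i/F^*)\,\log(fe_i/F^*)}{\log N}}
#' where \eqn{fe_i} is the term's occurrence count in specialty i and
#' \eqn{F^* = \sum_i fe_i}. A term occurring in a single specialty scores
#' exactly 1; terms spread evenly over many specialties score low. Zero
#' counts contribute 0 (the \eqn{x \log x \to 0} limit); the result is
#' clamped to `[0, 1]`. With multi-label texts \eqn{F^*} can exceed the
#' once-per-text global count F, so the within-sum distribution is
#' normalized by \eqn{F^*} to keep the entropy interpretation; with
#' single-label texts \eqn{F^* = F}.
#'
#' The printed denominator is \eqn{\log N} (total texts); with it a term
#' spread uniformly over k specialties scores \eqn{1 - \log k/\log N},
#' which is 0 only when k = N. `denominator = "k"` substitutes
#' \eqn{\log k}, making the uniform case exactly 0.
#'
#' @param fe Numeric vector of per-specialty occurrence counts of one term
#'   (zeros allowed).
#' @param N Total number of texts in the corpus (must be >= 2).
#' @param denominator `"N"` (as defined) or `"k"` (number of specialties).
#' @param k Number of specialties; required for `denominator = "k"`.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' tgm(c(A = 10), N = 100)            # exclusive term -> 1
#' tgm(c(5, 5), N = 100)              # 1 - log(2)/log(100)
tgm <- function(fe, N, denominator = c("N", "k"), k = length(fe)) {
  denominator <- match.arg(denominator)
  if (N < 2) stop("degenerate corpus: TGM needs N >= 2 (log N = 0 at N = 1)")
  f_star <- sum(fe)
  if (f_star <= 0) stop("term has no occurrences (sum(fe) = 0)")
  p <- fe[fe > 0] / f_star
  denom <- if (denominator == "N") log(N) else log(k)
  val <- 1 + sum(p * log(p)) / denom
  min(max(val, 0), 1)
}

#' Local precision measure (LPM)
#'
#' Specificity of a term for one specialty:
#' \deqn{LPM(t,i) = N^t_{e_i}/N^t + N^t_{e_i}/N_{e_i}}
#' The first summand is the share of the term's texts that belong to the
#' specialty; the second is the share of the specialty's texts containing
#' the term. The value lies in `[0, 2]` and equals 2 exactly when the term
#' occurs only in texts of the specialty and in every one of them. High
#' values mark terms highly specific for the specialty even when rare.
#'
#' @param nt_e Number of texts of the specialty containing the term
#'   (vectorized).
#' @param n_t Number of texts containing the term, corpus-wide (> 0).
#' @param n_e Number of texts belonging to the specialty (> 0).
#' @return Numeric value(s) in `[0, 2]`.
#' @export
lpm <- function(nt_e, n_t, n_e) {
  if (any(n_t <= 0)) stop("undefined term: N_t must be positive")
  if (any(n_e <= 0)) stop("empty specialty: N_e must be positive")
  nt_e / n_t + nt_e / n_e
}

#' Specialty frequency-percentile threshold
#'
#' The gate of the local relevance measure: the 90th percentile
#' (nearest-rank: the value at position `ceiling(p * n)` of the
#' ascending-sorted multiset) of the global frequencies F of the distinct
#' terms occurring in a specialty.
#'
#' @param f_values Numeric vector of global term frequencies `F`, one per
#'   distinct term of the specialty (non-empty).
#' @param prob Percentile, default 0.9.
#' @return The threshold L.
#' @export
percentile_threshold <- function(f_values, prob = 0.9) {
  if (length(f_values) == 0) stop("no terms in specialty: percentile undefined")
  v <- sort(f_values)
  v[max(1L, ceiling(prob * length(v)))]
}

#' Local relevance measure (LRM)
#'
#' A term's capacity to describe a specialty: the share of the term's
#' texts that belong to the specialty, but only for terms whose global
#' frequency reaches the specialty's 90th-percentile threshold L
#' (inclusive); below the threshold the measure is 0.
#'
#' @param f_t Global frequency of the term (vectorized).
#' @param l Threshold from [percentile_threshold()].
#' @param nt_e Number of the specialty's texts containing the term.
#' @param n_t Number of texts containing the term (> 0).
#' @return Numeric value(s) in `[0, 1]`.
#' @export
lrm <- function(f_t, l, nt_e, n_t) {
  if (any(n_t <= 0)) stop("undefined term: N_t must be positive")
  ifelse(f_t >= l, nt_e / n_t, 0)
}

#' Weighted-term table
#'
#' Assembles the full per-(term, specialty) table with all counts and the
#' three measures. Rows are ordered by specialty, then descending LRM,
#' then term, so output is deterministic.
#'
#' @param stats A `term_stats` object from [compute_term_stats()].
#' @param tgm_denominator Passed to [tgm()] (`"N"` or `"k"`).
#' @return A tibble with columns `term`, `specialty`, `fe`, `Nt_e`, `F`,
#'   `N_t`, `E_t`, `TGM`, `LPM`, `LRM`.
#' @export
weigh_terms <- function(stats, tgm_denominator = c("N", "k")) {
  stopifnot(inherits(stats, "term_stats"))
  tgm_denominator <- match.arg(tgm_denominator)
  cs <- stats$corpus_stats
  if (cs$N < 2) stop("degenerate corpus: need N >= 2")

  # TGM per term, vectorized over the long table
  tgm_tab <- stats$by_specialty %>%
    group_by(.data$term) %>%
    mutate(p = .data$fe / sum(.data$fe)) %>%
    summarise(ent = sum(.data$p * log(.data$p)),
              k_term = dplyr::n(), .groups = "drop")
  denom <- if (tgm_denominator == "N") log(cs$N) else log(cs$k)
  tgm_tab$TGM <- pmin(pmax(1 + tgm_tab$ent / denom, 0), 1)

  tab <- stats$by_specialty %>%
    left_join(stats$terms, by = "term") %>%
    left_join(tgm_tab[, c("term", "TGM")], by = "term")

  # per-specialty P90 threshold over that specialty's distinct terms
  thresholds <- tab %>%
    group_by(.data$specialty) %>%
    summarise(L = percentile_threshold(.data$F), .groups = "drop")
  tab <- left_join(tab, thresholds, by = "specialty")

  n_e <- unname(cs$N_e[tab$specialty])
  tab$LPM <- lpm(tab$Nt_e, tab$N_t, n_e)
  tab$LRM <- lrm(tab$F, tab$L, tab$Nt_e, tab$N_t)

  tab %>%
    select("term", "specialty", "fe", "Nt_e", "F", "N_t", "E_t",
           "TGM", "LPM", "LRM") %>%
    arrange(.data$specialty, desc(.data$LRM), .data$term)
}

#' Read / write a weighted-term table as TSV
#'
#' @param weights Tibble from [weigh_terms()].
#' @param path TSV file path.
#' @return `read_weights()` returns the tibble; `write_weights()` returns
#'   `path` invisibly.
#' @export
write_weights <- function(weights, path) {
  write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       encoding = "UTF-8", quote = ""))
}
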