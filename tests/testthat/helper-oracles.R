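# Independent brute-force implementations used as oracles. Everything here
# recounts from raw strings with plain loops and never calls the package's
# own counting/weighting code paths.

# naive n-gram extraction: sentence split, whitespace tokens, explicit
# window loops
oracle_ngrams <- function(text, n_max = 3) {
  out <- character()
  for (sent in strsplit(text, "[.;?!]")[[1]]) {
    toks <- strsplit(trimws(sent), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    m <- length(toks)
    for (n in seq_len(n_max)) {
      if (m < n) next
      for (i in seq_len(m - n + 1)) {
        out <- c(out, paste(toks[i:(i + n - 1)], collapse = " "))
      }
    }
  }
  tolower(out)
}

# brute-force count statistics from raw titles; docs is a data frame with
# columns id, title, and a list-column specialties
oracle_stats <- function(docs) {
  ngrams <- lapply(docs$title, oracle_ngrams)
  terms <- sort(unique(unlist(ngrams)))
  specialties <- sort(unique(unlist(docs$specialties)))
  n_e <- sapply(specialties, function(s) {
    sum(sapply(docs$specialties, function(l) s %in% l))
  })
  stats <- list()
  for (t in terms) {
    occ_per_doc <- sapply(ngrams, function(g) sum(g == t))
    fe <- nt_e <- sapply(specialties, function(s) 0)
    for (i in seq_len(nrow(docs))) {
      if (occ_per_doc[i] == 0) next
      for (s in docs$specialties[[i]]) {
        fe[s] <- fe[s] + occ_per_doc[i]
        nt_e[s] <- nt_e[s] + 1
      }
    }
    stats[[t]] <- list(F = sum(occ_per_doc), N_t = sum(occ_per_doc > 0),
                       E_t = sum(fe > 0), fe = fe, nt_e = nt_e)
  }
  list(N = nrow(docs), N_e = n_e, k = length(specialties),
       specialties = specialties, terms = stats)
}

oracle_tgm <- function(fe, N) {
  fe <- fe[fe > 0]
  p <- fe / sum(fe)
  v <- 1
  for (pi in p) v <- v + pi * log(pi) / log(N)
  min(max(v, 0), 1)
}

oracle_lpm <- function(nt_e_i, n_t, n_e_i) nt_e_i / n_t + nt_e_i / n_e_i

oracle_p90 <- function(f_values) {
  v <- sort(f_values)
  v[ceiling(0.9 * length(v))]
}

oracle_lrm <- function(f_t, l, nt_e_i, n_t) {
  if (f_t >= l) nt_e_i / n_t else 0
}

# full brute-force weighting for every (term, specialty with fe > 0)
oracle_weights <- function(os) {
  rows <- list()
  for (s in os$specialties) {
    f_in_s <- sapply(os$terms, function(st) {
      if (st$fe[s] > 0) st$F else NA
    })
    l <- oracle_p90(f_in_s[!is.na(f_in_s)])
    for (t in names(os$terms)) {
      st <- os$terms[[t]]
      if (st$fe[s] == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        term = t, specialty = s,
        TGM = oracle_tgm(st$fe, os$N),
        LPM = oracle_lpm(st$nt_e[s], st$N_t, os$N_e[s]),
        LRM = oracle_lrm(st$F, l, st$nt_e[s], st$N_t),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

oracle_stop_flags <- function(ow, min_count, th_sd, th_max) {
  flagged <- character()
  for (t in unique(ow$term)) {
    v <- ow$LRM[ow$term == t]
    if (length(v) <= min_count) next
    psd <- sqrt(sum((v - mean(v))^2) / length(v))
    if (psd < th_sd && max(v) < th_max) flagged <- c(flagged, t)
  }
  sort(flagged)
}

# per-document Eq.-style score against specialty term sets, loop form
oracle_score <- function(title, sets_df, specialties) {
  grams <- oracle_ngrams(title)
  out <- sapply(specialties, function(s) 0)
  for (s in specialties) {
    sub <- sets_df[sets_df$specialty == s, ]
    for (g in grams) {
      hit <- sub$TGM[sub$term == g]
      if (length(hit)) out[s] <- out[s] + hit[1]
    }
  }
  out
}

# micro P/R/F1 through incidence matrices (different route from the
# per-document set arithmetic in the package)
oracle_micro <- function(gold, pred) {
  labels <- sort(unique(c(unlist(gold), unlist(pred))))
  G <- t(sapply(gold, function(g) labels %in% g))
  P <- t(sapply(pred, function(p) labels %in% p))
  if (length(labels) == 1) { G <- t(G); P <- t(P) }
  tp <- sum(G & P); fp <- sum(!G & P); fn <- sum(G & !P)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1)
}

# random corpora of cleansing-neutral tokens (no stopwords, no
# punctuation, nothing the singularizer rewrites), for dual-route checks
random_oracle_corpus <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(3:6, 1)
    specialties <- paste0("sp", letters[1:k])
    n_docs <- sample(10:50, 1)
    vocab <- paste0("tok", sprintf("%02d", 1:25))
    docs <- tibble::tibble(
      id = sprintf("d%03d", 1:n_docs),
      title = replicate(n_docs, paste(sample(vocab, sample(3:8, 1),
                                             replace = TRUE), collapse = " ")),
      specialties = replicate(n_docs, {
        sample(specialties, 1 + stats::rbinom(1, 1, 0.2))
      }, simplify = FALSE)
    )
    docs
  })
}

# a deliberately tiny cleansing config whose lists never fire on the
# oracle corpora
neutral_config <- function() {
  cleansing_config(stopwords = "zzzstopzzz", gazetteer = "zzgeozz")
}
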