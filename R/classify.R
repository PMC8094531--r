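# Document scoring against a term resource, the multi-label specialty
# classification protocol, and micro-averaged evaluation.

#' Score documents against the per-specialty term sets
#'
#' Computes, for each document, one feature per specialty: the sum of the
#' TGM values of the document's n-gram occurrences whose normalized form
#' belongs to that specialty's term set. Occurrences count with
#' multiplicity by default (a term appearing twice contributes its TGM
#' twice); `unique_terms = TRUE` switches to counting each distinct term
#' once. Documents must be run through the same n-gram pipeline
#' configuration that built the resource.
#'
#' @param ngrams Tibble with columns `doc_id` and `normalized`, one row
#'   per n-gram occurrence (see [extract_corpus_ngrams()]).
#' @param resource A `term_resource`.
#' @param doc_ids Character vector fixing row order; defaults to the
#'   distinct `doc_id`s in `ngrams`. Documents without any resource term
#'   get an all-zero row.
#' @param unique_terms Count each distinct term once instead of per
#'   occurrence.
#' @param include_stop_ngrams Also score against the terms removed as stop
#'   n-grams (re-attaching `stop_table` to the sets).
#' @return A dense numeric matrix, rows = documents (rownames `doc_ids`),
#'   columns = `resource$specialties` in their fixed order.
#' @export
specialty_score <- function(ngrams, resource, doc_ids = NULL,
                            unique_terms = FALSE,
                            include_stop_ngrams = FALSE) {
  stopifnot(inherits(resource, "term_resource"))
  if (is.null(doc_ids)) doc_ids <- unique(ngrams$doc_id)
  sets <- resource$sets
  if (include_stop_ngrams) sets <- bind_rows(sets, resource$stop_table)
  specs <- resource$specialties
  out <- matrix(0, nrow = length(doc_ids), ncol = length(specs),
                dimnames = list(doc_ids, specs))
  if (nrow(ngrams) == 0 || nrow(sets) == 0) return(out)

  occ <- ngrams[, c("doc_id", "normalized")]
  if (unique_terms) occ <- distinct(occ)
  hits <- inner_join(occ, sets[, c("term", "specialty", "TGM")],
                     by = c(normalized = "term"),
                     relationship = "many-to-many") %>%
    group_by(.data$doc_id, .data$specialty) %>%
    summarise(score = sum(.data$TGM), .groups = "drop")
  hits <- hits[hits$doc_id %in% doc_ids, , drop = FALSE]
  out[cbind(match(hits$doc_id, doc_ids), match(hits$specialty, specs))] <- hits$score
  out
}

#' Seeded train/test split
#'
#' Uniform shuffle under the given seed, then a split with
#' `floor(train_fraction * n)` training elements — the arithmetic that
#' maps 54,879 case reports at 75% to 41,159 training and 13,720 test
#' texts. Partitions are disjoint and their union is the input.
#'
#' @param x A vector, data frame or [specialty_corpus] to split (n >= 2).
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return A list with elements `train` and `test`, the same type as `x`.
#' @export
split_train_test <- function(x, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- if (inherits(x, "specialty_corpus")) x$N
       else if (is.data.frame(x)) nrow(x) else length(x)
  if (n < 2) stop("need at least 2 elements to split")
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(train_fraction * n)
  take <- function(idx) {
    if (inherits(x, "specialty_corpus")) {
      specialty_corpus(x$documents[idx, , drop = FALSE])
    } else if (is.data.frame(x)) {
      x[idx, , drop = FALSE]
    } else x[idx]
  }
  list(train = take(sort(perm[seq_len(n_train)])),
       test = take(sort(perm[-seq_len(n_train)])))
}

# ---- TF-IDF vectorizer ----------------------------------------------------

# lowercased word tokens of >= 2 alphanumeric characters, stopwords
# removed, then 1..n_max grams per document
tfidf_terms <- function(corpus, stopwords, n_max = 3L) {
  d <- corpus$documents
  text <- tolower(ifelse(nzchar(d$abstract),
                         paste(d$title, d$abstract, sep = ". "), d$title))
  toks <- lapply(strsplit(text, "[^\\p{L}\\p{N}]+", perl = TRUE), function(t) {
    t <- t[nchar(t) >= 2]
    t[!t %in% stopwords]
  })
  tab <- ngram_table(toks, doc_id = d$id, n_max = n_max)
  tab[, c("doc_id", "surface")]
}

#' TF-IDF vectorizer over 1-3 grams
#'
#' Fits on a training corpus and transforms any corpus with the fitted
#' vocabulary, following the common vectorizer convention: lowercasing,
#' Spanish stopword removal before n-gram formation, raw term counts,
#' smoothed inverse document frequency `ln((1 + N)/(1 + df)) + 1` and L2
#' row normalization.
#'
#' @param train A [specialty_corpus] to fit on.
#' @param stopwords Character vector of stopwords (lowercase).
#' @param n_max Largest n-gram size (default 3, i.e. n-gram range (1,3)).
#' @param min_df Minimum training document frequency for a vocabulary
#'   term.
#' @param max_features Keep only this many terms, by descending total
#'   training count (ties broken alphabetically); `NULL` keeps all.
#' @return A list of class `tfidf_model` with `vocab`, `idf` and the
#'   settings; use [tfidf_transform()] to produce matrices.
#' @export
tfidf_fit <- function(train, stopwords, n_max = 3L, min_df = 1L,
                      max_features = NULL) {
  terms <- tfidf_terms(train, stopwords, n_max)
  stats <- terms %>%
    group_by(term = .data$surface) %>%
    summarise(count = dplyr::n(), df = n_distinct(.data$doc_id),
              .groups = "drop") %>%
    filter(.data$df >= min_df) %>%
    arrange(desc(.data$count), .data$term)
  if (!is.null(max_features) && nrow(stats) > max_features) {
    stats <- stats[seq_len(max_features), , drop = FALSE]
  }
  stats <- arrange(stats, .data$term)
  n_docs <- train$N
  structure(
    list(vocab = stats$term,
         idf = log((1 + n_docs) / (1 + stats$df)) + 1,
         stopwords = stopwords, n_max = n_max),
    class = "tfidf_model"
  )
}

#' @rdname tfidf_fit
#' @param model A fitted `tfidf_model`.
#' @param corpus A [specialty_corpus] to transform.
#' @return `tfidf_transform()` returns a sparse `dgCMatrix` (documents x
#'   vocabulary), rows L2-normalized.
#' @export
tfidf_transform <- function(model, corpus) {
  stopifnot(inherits(model, "tfidf_model"))
  terms <- tfidf_terms(corpus, model$stopwords, model$n_max)
  terms <- terms[terms$surface %in% model$vocab, , drop = FALSE]
  counts <- terms %>% count(.data$doc_id, .data$surface, name = "tf")
  ids <- corpus$documents$id
  m <- Matrix::sparseMatrix(
    i = match(counts$doc_id, ids),
    j = match(counts$surface, model$vocab),
    x = counts$tf * model$idf[match(counts$surface, model$vocab)],
    dims = c(length(ids), length(model$vocab)),
    dimnames = list(ids, model$vocab)
  )
  nrm <- sqrt(Matrix::rowSums(m^2))
  nrm[nrm == 0] <- 1
  out <- Matrix::Diagonal(x = 1 / nrm) %*% m
  dimnames(out) <- dimnames(m)
  out
}

#' Build train/test feature matrices
#'
#' Produces the document representations of the classification protocol:
#' `"tfidf"` is a lowercased, stopword-filtered 1-3-gram TF-IDF matrix
#' fitted on the training corpus only; `"specialty"` is the
#' per-specialty score vector of [specialty_score()] (one column per
#' specialty); `"tfidf+specialty"` concatenates the two column blocks.
#'
#' @param train,test [specialty_corpus] objects.
#' @param mode One of `"tfidf"`, `"specialty"`, `"tfidf+specialty"`.
#' @param resource A `term_resource`; required for the specialty-score
#'   modes.
#' @param config [cleansing_config] used for specialty scoring (must match
#'   the resource's pipeline).
#' @param include_stop_ngrams Score against stop n-grams too (the
#'   "with stop n-grams" protocol variant); `FALSE` scores against the
#'   stop-filtered sets.
#' @param stopwords Stopword list for the TF-IDF tokenizer; defaults to
#'   the cleansing config's list.
#' @param min_df,max_features Passed to [tfidf_fit()].
#' @param normalize_scores L2-normalize each document's specialty-score
#'   row (default), putting the score block on the same scale as the
#'   L2-normalized TF-IDF block and removing document-length effects.
#' @return List with dense/sparse matrices `train` and `test` (identical
#'   column order) and the `tfidf_model` (or `NULL`).
#' @export
build_feature_matrix <- function(train, test,
                                 mode = c("tfidf", "specialty", "tfidf+specialty"),
                                 resource = NULL,
                                 config = default_cleansing_config(),
                                 include_stop_ngrams = FALSE,
                                 stopwords = config$stopwords,
                                 min_df = 1L, max_features = NULL,
                                 normalize_scores = TRUE) {
  mode <- match.arg(mode)
  want_tfidf <- mode %in% c("tfidf", "tfidf+specialty")
  want_spec <- mode %in% c("specialty", "tfidf+specialty")
  if (want_spec && is.null(resource)) {
    stop("specialty-score features require a term resource")
  }
  blocks_train <- list()
  blocks_test <- list()
  model <- NULL
  if (want_tfidf) {
    model <- tfidf_fit(train, stopwords, min_df = min_df,
                       max_features = max_features)
    blocks_train$tfidf <- tfidf_transform(model, train)
    blocks_test$tfidf <- tfidf_transform(model, test)
  }
  if (want_spec) {
    sc_tr <- specialty_score(extract_corpus_ngrams(train, config),
                             resource, doc_ids = train$documents$id,
                             include_stop_ngrams = include_stop_ngrams)
    sc_te <- specialty_score(extract_corpus_ngrams(test, config),
                             resource, doc_ids = test$documents$id,
                             include_stop_ngrams = include_stop_ngrams)
    if (normalize_scores) {
      l2 <- function(m) {
        nrm <- sqrt(rowSums(m^2))
        nrm[nrm == 0] <- 1
        m / nrm
      }
      sc_tr <- l2(sc_tr)
      sc_te <- l2(sc_te)
    }
    colnames(sc_tr) <- colnames(sc_te) <- paste0("spec:", colnames(sc_tr))
    blocks_train$spec <- sc_tr
    blocks_test$spec <- sc_te
  }
  list(
    train = do.call(cbind, lapply(blocks_train, as.matrix)),
    test = do.call(cbind, lapply(blocks_test, as.matrix)),
    tfidf_model = model
  )
}

# ---- Multi-label learners -------------------------------------------------

#' Convert between label sets and a binary label matrix
#'
#' @param sets List of character vectors (one label set per document).
#' @param labels Character vector fixing column order; defaults to the
#'   sorted union of observed labels.
#' @return A logical matrix, documents x labels.
#' @export
labelsets_to_matrix <- function(sets, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(unlist(sets)))
  m <- matrix(FALSE, nrow = length(sets), ncol = length(labels),
              dimnames = list(NULL, labels))
  for (i in seq_along(sets)) m[i, intersect(sets[[i]], labels)] <- TRUE
  m
}

#' Train a multi-label specialty classifier and predict label sets
#'
#' The protocol's four learners, each behind the same contract:
#' \describe{
#'   \item{`"random-forest"`}{100 trees per label (binary relevance),
#'     via \pkg{randomForest}.}
#'   \item{`"decision-tree"`}{one \pkg{rpart} tree per label with the
#'     entropy ("information") split criterion.}
#'   \item{`"knn"`}{k-nearest neighbours per label, k = 5, uniform
#'     weights, via \pkg{class}.}
#'   \item{`"mlp"`}{a single network with one hidden layer (default 100
#'     units) and one sigmoid output per label, fitted with \pkg{nnet}
#'     under cross-entropy loss — the native multi-label form of the
#'     one-hidden-layer perceptron.}
#' }
#' Probabilistic outputs are thresholded at 0.5 per label. Labels with no
#' positive training example are never predicted (with a warning); labels
#' positive in every training document are always predicted. Given a seed
#' the predictions are deterministic.
#'
#' @param x_train,x_test Numeric feature matrices with identical columns.
#' @param y_train Logical/0-1 matrix (documents x labels, colnames =
#'   labels) or a list of label sets (converted with
#'   [labelsets_to_matrix()]).
#' @param learner One of `"mlp"`, `"knn"`, `"random-forest"`,
#'   `"decision-tree"`.
#' @param seed Integer seed.
#' @param hidden,maxit,decay MLP settings (hidden units, optimizer
#'   iterations, weight decay).
#' @param k Neighbour count for `"knn"`.
#' @param ntree Tree count for `"random-forest"`.
#' @return A list of character label-set vectors, one per test row.
#' @export
train_predict_multilabel <- function(x_train, y_train, x_test,
                                     learner = c("mlp", "knn", "random-forest",
                                                 "decision-tree"),
                                     seed = 1L, hidden = 100L, maxit = 200L,
                                     decay = 0, k = 5L, ntree = 100L) {
  learner <- match.arg(learner)
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  if (is.list(y_train) && !is.matrix(y_train)) {
    y_train <- labelsets_to_matrix(y_train)
  }
  y_train <- y_train > 0
  labels <- colnames(y_train)
  stopifnot(!is.null(labels), nrow(x_train) == nrow(y_train))

  pos <- colSums(y_train)
  if (any(pos == 0)) {
    warning("labels absent from training data are never predicted: ",
            paste(labels[pos == 0], collapse = ", "))
  }
  prob <- matrix(0, nrow = nrow(x_test), ncol = length(labels),
                 dimnames = list(NULL, labels))

  withr::with_seed(seed, {
    if (learner == "mlp") {
      trainable <- pos > 0 & pos < nrow(y_train)
      prob[, pos == nrow(y_train)] <- 1
      if (any(trainable)) {
        fit <- nnet::nnet(x = x_train, y = y_train[, trainable, drop = FALSE] * 1,
                          size = hidden, entropy = TRUE, maxit = maxit,
                          decay = decay, MaxNWts = 1e7, trace = FALSE)
        prob[, trainable] <- predict(fit, x_test)
      }
    } else {
      for (j in seq_along(labels)) {
        yj <- y_train[, j]
        if (all(yj) || all(!yj)) {
          prob[, j] <- as.numeric(all(yj))
          next
        }
        prob[, j] <- switch(
          learner,
          "random-forest" = {
            fit <- randomForest::randomForest(x = x_train, y = factor(yj),
                                              ntree = ntree)
            predict(fit, x_test, type = "prob")[, "TRUE"]
          },
          "decision-tree" = {
            df_tr <- data.frame(x_train)
            df_te <- data.frame(x_test)
            colnames(df_te) <- colnames(df_tr)
            df_tr$.y <- factor(yj)
            fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class",
                                parms = list(split = "information"))
            predict(fit, df_te, type = "prob")[, "TRUE"]
          },
          "knn" = {
            pr <- class::knn(train = x_train, test = x_test,
                             cl = factor(yj), k = min(k, nrow(x_train)),
                             prob = TRUE)
            p_win <- attr(pr, "prob")
            ifelse(pr == "TRUE", p_win, 1 - p_win)
          }
        )
      }
    }
  })
  apply(prob, 1, function(p) labels[p >= 0.5], simplify = FALSE)
}

# ---- Evaluation -----------------------------------------------------------

#' Micro-averaged multi-label precision, recall and F1
#'
#' Pools true positives, false positives and false negatives over all
#' (document, label) pairs, then reports precision, recall and their
#' harmonic mean as percentages, plus a per-label F1 table with support
#' counts. Zero-denominator metrics are reported as 0.
#'
#' @param gold,predicted Lists of character label sets, equal length.
#' @return A list of class `eval_report`: `micro` (named vector
#'   `precision`, `recall`, `f1`, in percent), `counts` (TP/FP/FN) and
#'   `per_label` (tibble `label`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `support`).
#' @export
micro_prf <- function(gold, predicted) {
  stopifnot(length(gold) == length(predicted))
  labels <- sort(unique(c(unlist(gold), unlist(predicted))))
  tp <- fp <- fn <- stats::setNames(numeric(length(labels)), labels)
  for (i in seq_along(gold)) {
    g <- unique(gold[[i]])
    p <- unique(predicted[[i]])
    for (l in intersect(g, p)) tp[l] <- tp[l] + 1
    for (l in setdiff(p, g)) fp[l] <- fp[l] + 1
    for (l in setdiff(g, p)) fn[l] <- fn[l] + 1
  }
  rate <- function(num, den) if (den == 0) 0 else num / den
  P <- rate(sum(tp), sum(tp) + sum(fp))
  R <- rate(sum(tp), sum(tp) + sum(fn))
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  per_label <- tibble(
    label = labels, tp = unname(tp), fp = unname(fp), fn = unname(fn),
    precision = unname(mapply(rate, tp, tp + fp)),
    recall = unname(mapply(rate, tp, tp + fn)),
    support = unname(tp + fn)
  )
  per_label$f1 <- ifelse(per_label$precision + per_label$recall == 0, 0,
                         2 * per_label$precision * per_label$recall /
                           (per_label$precision + per_label$recall))
  structure(
    list(micro = c(precision = 100 * P, recall = 100 * R, f1 = 100 * F1),
         counts = c(tp = sum(tp), fp = sum(fp), fn = sum(fn)),
         per_label = per_label),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("micro P = %.1f%%  R = %.1f%%  F1 = %.1f%%  (%d labels)\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"],
              nrow(x$per_label)))
  invisible(x)
}

#' Run one classification experiment
#'
#' Convenience wrapper over the whole protocol: split the evaluation
#' corpus 75/25 (seeded), build the requested feature representation,
#' train the learner and return the micro-averaged report.
#'
#' @param eval_corpus [specialty_corpus] of evaluation documents (e.g. the
#'   case-report partition).
#' @param resource `term_resource` (required for specialty-score modes).
#' @param mode,include_stop_ngrams Passed to [build_feature_matrix()].
#' @param learner,... Passed to [train_predict_multilabel()].
#' @param seed Seed for both the split and the learner.
#' @param train_fraction Train share of the split.
#' @param config Cleansing configuration for specialty scoring.
#' @param min_df,max_features TF-IDF vocabulary controls.
#' @return An `eval_report` with attribute `predictions`.
#' @export
classification_experiment <- function(eval_corpus, resource = NULL,
                                      mode = "tfidf", learner = "mlp",
                                      seed = 1L, train_fraction = 0.75,
                                      config = default_cleansing_config(),
                                      include_stop_ngrams = FALSE,
                                      min_df = 1L, max_features = NULL,
                                      normalize_scores = TRUE, ...) {
  parts <- split_train_test(eval_corpus, train_fraction, seed)
  feats <- build_feature_matrix(parts$train, parts$test, mode = mode,
                                resource = resource, config = config,
                                include_stop_ngrams = include_stop_ngrams,
                                min_df = min_df, max_features = max_features,
                                normalize_scores = normalize_scores)
  labels <- sort(unique(unlist(parts$train$documents$specialties)))
  y_train <- labelsets_to_matrix(parts$train$documents$specialties, labels)
  pred <- train_predict_multilabel(feats$train, y_train, feats$test,
                                   learner = learner, seed = seed, ...)
  rep <- micro_prf(parts$test$documents$specialties, pred)
  attr(rep, "predictions") <- stats::setNames(pred, parts$test$documents$id)
  rep
}
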