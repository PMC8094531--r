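make_resource <- function() {
  w <- tibble::tibble(
    term = c("angina", "angina", "soplo", "nefrona"),
    specialty = c("cardio", "nefro", "cardio", "nefro"),
    fe = 1L, Nt_e = 1L, F = 5L, N_t = 5L, E_t = c(2L, 2L, 1L, 1L),
    TGM = c(0.8, 0.8, 0.95, 0.9), LPM = 1, LRM = c(0.5, 0.5, 1, 1)
  )
  build_resource(w)
}

test_that("specialty scores sum TGM over matching occurrences", {
  res <- make_resource()
  ng <- tibble::tibble(doc_id = c("d1", "d1"),
                       normalized = c("angina", "soplo"))
  sc <- specialty_score(ng, res)
  expect_equal(unname(sc["d1", ]), c(0.8 + 0.95, 0.8))
  expect_equal(colnames(sc), c("cardio", "nefro"))

  # no matching terms: all-zero vector
  sc0 <- specialty_score(tibble::tibble(doc_id = "d2", normalized = "otro"),
                         res, doc_ids = "d2")
  expect_equal(unname(sc0["d2", ]), c(0, 0))

  # multiplicity counts twice; unique_terms collapses it
  ng2 <- tibble::tibble(doc_id = "d3", normalized = c("angina", "angina"))
  expect_equal(specialty_score(ng2, res)["d3", "cardio"], 1.6)
  expect_equal(specialty_score(ng2, res, unique_terms = TRUE)["d3", "cardio"], 0.8)

  # stop n-grams excluded from sets but recoverable on demand
  res_stop <- build_resource(res$sets, stop_ngrams = "angina")
  expect_equal(specialty_score(ng2, res_stop)["d3", "cardio"], 0)
  expect_equal(specialty_score(ng2, res_stop,
                               include_stop_ngrams = TRUE)["d3", "cardio"], 1.6)
})

test_that("seeded 75/25 split reproduces the benchmark arithmetic", {
  sp <- split_train_test(seq_len(100), 0.75, seed = 4)
  expect_length(sp$train, 75)
  expect_length(sp$test, 25)
  expect_setequal(c(sp$train, sp$test), 1:100)

  expect_identical(split_train_test(seq_len(50), 0.6, seed = 9),
                   split_train_test(seq_len(50), 0.6, seed = 9))

  big <- split_train_test(seq_len(54879), 0.75, seed = 1)
  expect_length(big$train, 41159)
  expect_length(big$test, 13720)

  corp <- tiny_corpus(8)
  spc <- split_train_test(corp, 0.75, seed = 2)
  expect_s3_class(spc$train, "specialty_corpus")
  expect_equal(spc$train$N + spc$test$N, 8)
  expect_error(split_train_test(1, 0.5, 1), "at least 2")
})

test_that("TF-IDF matches the hand-computed convention on a toy corpus", {
  corp <- corpus_from(c("gato perro", "gato"), list("s", "s"))
  model <- tfidf_fit(corp, stopwords = "de")
  X <- as.matrix(tfidf_transform(model, corp))
  expect_setequal(model$vocab, c("gato", "perro", "gato perro"))

  idf_gato <- log(3 / 3) + 1
  idf_rare <- log(3 / 2) + 1
  raw1 <- c(`gato` = idf_gato, `gato perro` = idf_rare, `perro` = idf_rare)
  expected1 <- raw1 / sqrt(sum(raw1^2))
  expect_equal(X["d01", names(expected1)], expected1, tolerance = 1e-12)
  expect_equal(unname(X["d02", "gato"]), 1)  # single-term doc, L2 norm 1
  expect_equal(unname(X["d02", "perro"]), 0)

  # vocabulary fitted on train only; unseen terms ignored at transform
  X2 <- tfidf_transform(model, corpus_from("lince gato", list("s")))
  expect_equal(unname(as.matrix(X2)[1, "gato"]), 1)
})

test_that("feature matrices concatenate blocks with fixed columns", {
  res <- make_resource()
  train <- corpus_from(c("angina estable", "soplo cardiaco", "nefrona renal"),
                       list("cardio", "cardio", "nefro"))
  test <- corpus_from("angina renal", list("nefro"), ids = "t1")
  cfg <- neutral_config()
  fm <- build_feature_matrix(train, test, mode = "tfidf+specialty",
                             resource = res, config = cfg)
  expect_equal(ncol(fm$train), length(fm$tfidf_model$vocab) + 2)
  expect_identical(colnames(fm$train), colnames(fm$test))

  # a document identical in train and test gets identical specialty columns
  test2 <- corpus_from("angina estable", list("cardio"), ids = "x9")
  fm2 <- build_feature_matrix(train, test2, mode = "specialty",
                              resource = res, config = cfg)
  expect_equal(unname(fm2$test["x9", ]), unname(fm2$train["d01", ]))

  expect_error(build_feature_matrix(train, test, mode = "specialty"),
               "resource")
})

test_that("multi-label learners honour the prediction contract", {
  withr::with_seed(99, {
    n <- 60
    x <- cbind(f1 = c(stats::runif(n / 2, 0, 0.2), stats::runif(n / 2, 0.8, 1)),
               f2 = stats::runif(n))
  })
  y <- list()
  for (i in seq_len(60)) y[[i]] <- if (x[i, "f1"] > 0.5) "pos" else "neg"
  ytr <- labelsets_to_matrix(y)

  for (lrn in c("mlp", "knn", "random-forest", "decision-tree")) {
    pred <- train_predict_multilabel(x, ytr, x, learner = lrn, seed = 3,
                                     hidden = 4, maxit = 100)
    acc <- mean(vapply(seq_along(pred), function(i) {
      setequal(pred[[i]], y[[i]])
    }, logical(1)))
    expect_gte(acc, 0.95)  # separable labels are recovered
    pred2 <- train_predict_multilabel(x, ytr, x, learner = lrn, seed = 3,
                                      hidden = 4, maxit = 100)
    expect_identical(pred, pred2)  # same seed, same predictions
  }

  # constant features: per-label majority behavior
  xc <- matrix(1, nrow = 20, ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  ymaj <- labelsets_to_matrix(c(rep(list("often"), 16),
                                rep(list("rare"), 4)),
                              labels = c("often", "rare"))
  predc <- train_predict_multilabel(xc, ymaj, xc[1:5, , drop = FALSE],
                                    learner = "decision-tree", seed = 1)
  expect_true(all(vapply(predc, function(p) setequal(p, "often"), logical(1))))

  # labels unseen in training are never predicted, with a warning
  yzero <- cbind(ymaj, ghost = FALSE)
  expect_warning(
    predg <- train_predict_multilabel(xc, yzero, xc[1:3, , drop = FALSE],
                                      learner = "knn", seed = 1),
    "never predicted")
  expect_false(any(vapply(predg, function(p) "ghost" %in% p, logical(1))))
})

test_that("micro-averaged metrics pool counts over document-label pairs", {
  perfect <- micro_prf(list(c("A", "B"), "C"), list(c("A", "B"), "C"))
  expect_equal(unname(perfect$micro), c(100, 100, 100))

  pooled <- micro_prf(list(c("A", "B"), "C"), list("A", c("B", "C")))
  expect_equal(unname(pooled$counts), c(2, 1, 1))
  expect_equal(unname(pooled$micro), rep(100 * 2 / 3, 3), tolerance = 1e-9)

  empty <- micro_prf(list("A", "B"), list(character(), character()))
  expect_equal(unname(empty$micro), c(0, 0, 0))

  # per-label table carries support and the F1 identity
  pl <- pooled$per_label
  expect_equal(pl$support[pl$label == "A"], 1)
  with_f1 <- pl$precision + pl$recall > 0
  expect_equal(pl$f1[with_f1],
               2 * pl$precision[with_f1] * pl$recall[with_f1] /
                 (pl$precision[with_f1] + pl$recall[with_f1]))

  # metric bounds and identity on random prediction sets
  withr::with_seed(17, {
    for (i in 1:20) {
      labs <- LETTERS[1:4]
      gold <- replicate(8, sample(labs, sample(1:2, 1)), simplify = FALSE)
      pred <- replicate(8, sample(labs, sample(0:2, 1)), simplify = FALSE)
      r <- micro_prf(gold, pred)
      expect_true(all(r$micro >= 0 & r$micro <= 100))
      expect_equal(unname(r$micro), unname(oracle_micro(gold, pred)),
                   tolerance = 1e-9)
    }
  })
})
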