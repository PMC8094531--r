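test_that("specialty_corpus validates documents and keeps counts consistent", {
  docs <- tibble::tibble(
    id = c("a", "b", "c"),
    title = c("t1", "t2", "t3"),
    specialties = list("x", c("x", "y"), "y")
  )
  corp <- specialty_corpus(docs)
  expect_equal(corp$N, 3)
  expect_equal(corp$N_e[["x"]], 2)
  expect_equal(corp$N_e[["y"]], 2)
  expect_setequal(corp$specialty_index$x, c("a", "b"))

  # recomputing bookkeeping from scratch matches stored values
  labs <- corpus_labels(corp)
  expect_equal(as.integer(table(labs$specialty)[names(corp$N_e)]),
               unname(corp$N_e))

  expect_error(specialty_corpus(tibble::tibble(
    id = "a", title = "  ", specialties = list("x"))), "empty title")
  expect_error(specialty_corpus(tibble::tibble(
    id = "a", title = "t", specialties = list(character()))), "no specialty")
  expect_error(specialty_corpus(tibble::tibble(
    id = c("a", "a"), title = c("t", "t"), specialties = list("x", "x"))),
    "duplicate")
})

test_that("JSONL corpus round-trips", {
  corp <- corpus_from(
    titles = c("Absceso renal con fiebre", "Úlcera cutánea"),
    labels = list(c("nefro", "uro"), "derma"),
    ptypes = list("Case Reports", character())
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, path)
  back <- read_corpus_jsonl(path)
  expect_equal(back$N, corp$N)
  expect_equal(back$documents$title, corp$documents$title)
  expect_equal(back$documents$specialties, corp$documents$specialties)
  expect_equal(back$documents$publication_types,
               corp$documents$publication_types)
})

test_that("descriptor TSV parsing and level invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "specialty_id\tlevel\tparent_id\tnames_primary\tnames_local\tsee_also",
    "cardio\t1\t\tcardiology\tcardiología\tHeart Diseases;Vascular Diseases",
    "pedcardio\t2\tcardio\tpediatric cardiology\t\t"
  ), path)
  ds <- read_specialty_descriptors(path)
  expect_length(ds, 2)
  expect_equal(ds$cardio$see_also, c("Heart Diseases", "Vascular Diseases"))
  expect_equal(ds$pedcardio$parent_id, "cardio")
  expect_error(specialty_descriptor("x", level = 2), "parent_id")
})

test_that("query builder covers all fields, names and see-also headings", {
  d <- specialty_descriptor("dermatology",
                            names_primary = "dermatology",
                            names_local = "dermatología",
                            see_also = "Skin Diseases")
  q <- build_pubmed_query(d, "SPA")
  expect_match(q, '"SPA"\\[LA\\]', perl = TRUE)
  for (f in c("TA", "TIAB", "CN", "SI", "OT", "AD", "MH:noexp", "SH:noexp")) {
    expect_true(grepl(sprintf('"dermatology"[%s]', f), q, fixed = TRUE))
    expect_true(grepl(sprintf('"dermatología"[%s]', f), q, fixed = TRUE))
  }
  expect_true(grepl('"Skin Diseases"[MH]', q, fixed = TRUE))

  # determinism: a pure function of the descriptor
  expect_identical(q, build_pubmed_query(d, "SPA"))

  # minimal descriptor: only the 8-field OR block
  q1 <- build_pubmed_query(specialty_descriptor("x", names_primary = "neumología"))
  clauses <- strsplit(sub("^.*AND \\((.*)\\)$", "\\1", q1), " OR ", fixed = TRUE)[[1]]
  expect_length(clauses, 8)
  expect_false(any(grepl("\\[MH\\]$", clauses)))

  # two see-also headings: the emitted string parses back into clauses
  # whose last two are MH-tagged
  d2 <- specialty_descriptor("x", names_primary = "cardiology",
                             see_also = c("Heart Diseases", "Vascular Diseases"))
  q2 <- build_pubmed_query(d2)
  cl2 <- strsplit(sub("^.*AND \\((.*)\\)$", "\\1", q2), " OR ", fixed = TRUE)[[1]]
  expect_length(cl2, 8 + 2)
  fields <- sub('^"(.*)"\\[(.*)\\]$', "\\2", cl2)
  terms <- sub('^"(.*)"\\[(.*)\\]$', "\\1", cl2)
  expect_equal(utils::tail(fields, 2), c("MH", "MH"))
  expect_equal(utils::tail(terms, 2), c("Heart Diseases", "Vascular Diseases"))

  expect_error(build_pubmed_query(specialty_descriptor("x")), "primary-language")
})

test_that("sub-specialty corpora merge into parents by document-id union", {
  hier <- list(
    specialty_descriptor("parent", level = 1),
    specialty_descriptor("child", level = 2, parent_id = "parent"),
    specialty_descriptor("child2", level = 2, parent_id = "parent")
  )
  parent <- tiny_corpus(10, "parent")
  child <- specialty_corpus(tiny_docs(5, "child", prefix = "c"))
  # one shared id between parent and child
  child$documents$id[1] <- "d1"
  child <- specialty_corpus(child$documents)
  merged <- merge_sublevel_terminology(list(parent = parent, child = child), hier)
  expect_equal(merged$parent$N,
               length(union(parent$documents$id, child$documents$id)))
  expect_equal(merged$parent$N, 14)
  expect_equal(merged$child$N, 5)  # children unchanged

  # childless parent untouched
  merged2 <- merge_sublevel_terminology(list(parent = parent),
                                        hier[1])
  expect_equal(merged2$parent$documents$id, parent$documents$id)

  # two children sharing a document contribute it once
  child2 <- specialty_corpus(tibble::tibble(
    id = c("c1", "zz"), title = c("t", "t"),
    specialties = list("child2", "child2")))
  merged3 <- merge_sublevel_terminology(
    list(parent = parent, child = child, child2 = child2), hier)
  expect_equal(merged3$parent$N,
               length(union(union(parent$documents$id, child$documents$id),
                            child2$documents$id)))

  # orphan level-2 specialty is a hierarchy error
  expect_error(
    merge_sublevel_terminology(
      list(orphan = child),
      list(specialty_descriptor("orphan", level = 2, parent_id = "ghost"))),
    "unknown parent")
})

test_that("small specialties are pruned with a strict threshold", {
  hier <- list(specialty_descriptor("big", level = 2, parent_id = "p"),
               specialty_descriptor("small", level = 2, parent_id = "p"),
               specialty_descriptor("p", level = 1))
  corpora <- list(big = tiny_corpus(1000, "big"),
                  small = tiny_corpus(999, "small"),
                  p = tiny_corpus(5, "p"))
  out <- filter_small_specialties(corpora, min_titles = 1000, level = 2,
                                  hierarchy = hier)
  expect_named(out, c("big", "p"))        # 999 < 1000 removed
  expect_equal(out$big$N, 1000)           # exactly 1000 retained
  expect_equal(names(filter_small_specialties(corpora, min_titles = 0)),
               names(corpora))            # identity at 0
})

test_that("duplicate specialties collapse to one lexicographic representative", {
  a <- specialty_corpus(tiny_docs(4, "gyn", prefix = "a"))
  b <- specialty_corpus(tiny_docs(3, "gyn", prefix = "b"))
  out <- dedupe_specialties(list(`gyn@repro` = a, `gyn@surg` = b),
                            list(c("gyn@repro", "gyn@surg")))
  expect_named(out, "gyn@repro")
  expect_equal(out$`gyn@repro`$N, 7)

  expect_equal(dedupe_specialties(list(x = a), list()), list(x = a))

  # disjoint groups conserve their union counts
  c1 <- specialty_corpus(tiny_docs(2, "s", prefix = "x"))
  c2 <- specialty_corpus(tiny_docs(2, "s", prefix = "y"))
  out2 <- dedupe_specialties(list(s1 = c1, s2 = c2, q1 = a, q2 = b),
                             list(c("s1", "s2"), c("q1", "q2")))
  expect_equal(out2$s1$N, 4)
  expect_equal(out2$q1$N, 7)

  expect_warning(
    dedupe_specialties(list(s1 = c1), list(c("s1", "ghost"))), "absent")
})

test_that("case-report partition is case-insensitive, disjoint and complete", {
  corp <- corpus_from(
    titles = paste("titulo", 1:10),
    labels = rep(list("s"), 10),
    ptypes = c(rep(list("Case Reports"), 2), list("case reports"),
               rep(list(c("Journal Article")), 7))
  )
  parts <- partition_case_reports(corp)
  expect_equal(parts$test_set$N, 3)
  expect_equal(parts$build_set$N, 7)
  expect_length(intersect(parts$build_set$documents$id,
                          parts$test_set$documents$id), 0)
  expect_setequal(c(parts$build_set$documents$id, parts$test_set$documents$id),
                  corp$documents$id)

  none <- partition_case_reports(
    corpus_from(paste("t", 1:4), rep(list("s"), 4)))
  expect_null(none$test_set)
  expect_equal(none$build_set$N, 4)
})

test_that("partition conservation holds on random corpora", {
  for (seed in 1:5) {
    docs <- random_oracle_corpus(seed)
    docs$publication_types <- replicate(nrow(docs), {
      if (stats::runif(1) < 0.3) "Case Reports" else character()
    }, simplify = FALSE)
    corp <- specialty_corpus(docs)
    parts <- partition_case_reports(corp)
    n_build <- if (is.null(parts$build_set)) 0 else parts$build_set$N
    n_test <- if (is.null(parts$test_set)) 0 else parts$test_set$N
    expect_equal(n_build + n_test, corp$N)
  }
})

test_that("fixture fetcher returns canned documents per specialty", {
  corpora <- list(derm = tiny_corpus(3, "derm"))
  fetch <- fixture_fetcher(corpora)
  expect_equal(nrow(fetch("any query", "derm")), 3)
  expect_equal(nrow(fetch("any query", "missing")), 0)
})
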