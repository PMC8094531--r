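#' Construct a specialty-labeled corpus
#'
#' A `specialty_corpus` wraps a tibble of document records together with the
#' corpus-level bookkeeping used throughout term weighting: the total text
#' count `N`, the per-specialty text counts `N_e`, and a specialty index
#' mapping each specialty to the ids of the documents that carry its label.
#' A multi-label document is counted once in `N` and once in `N_e[s]` for
#' each of its labels.
#'
#' @param documents A data frame with one row per document and columns
#'   `id` (character, unique), `title` (character, non-empty after
#'   trimming), `abstract` (character, optional — missing/`NA` treated as
#'   empty), `publication_types` (list-column of character vectors,
#'   optional), `specialties` (list-column of character vectors, each
#'   non-empty), and `language` (character, optional, default `"es"`).
#'
#' @return An object of class `specialty_corpus` with fields `documents`
#'   (tibble), `specialty_index` (named list of document-id vectors), `N`
#'   (integer) and `N_e` (named integer vector).
#' @export
#' @examples
#' docs <- tibble::tibble(
#'   id = c("d1", "d2"),
#'   title = c("Hematoma renal", "Carcinoma de piel"),
#'   specialties = list("nephrology", c("dermatology", "oncology"))
#' )
#' corp <- specialty_corpus(docs)
#' corp$N_e
specialty_corpus <- function(documents) {
  documents <- as_tibble(documents)
  stopifnot(all(c("id", "title", "specialties") %in% names(documents)))
  if (!"abstract" %in% names(documents)) documents$abstract <- ""
  if (!"publication_types" %in% names(documents)) {
    documents$publication_types <- replicate(nrow(documents), character(), simplify = FALSE)
  }
  if (!"language" %in% names(documents)) documents$language <- "es"
  documents$abstract[is.na(documents$abstract)] <- ""
  if (!is.list(documents$specialties)) documents$specialties <- as.list(documents$specialties)
  if (!is.list(documents$publication_types)) {
    documents$publication_types <- as.list(documents$publication_types)
  }
  documents$id <- as.character(documents$id)

  if (anyDuplicated(documents$id)) {
    stop("duplicate document ids: ",
         paste(unique(documents$id[duplicated(documents$id)]), collapse = ", "))
  }
  bad_title <- !nzchar(trimws(documents$title)) | is.na(documents$title)
  if (any(bad_title)) {
    stop("documents with empty title: ", paste(documents$id[bad_title], collapse = ", "))
  }
  n_lab <- vapply(documents$specialties, length, integer(1))
  if (any(n_lab == 0)) {
    stop("documents with no specialty label: ",
         paste(documents$id[n_lab == 0], collapse = ", "))
  }

  label_tbl <- tibble(
    id = rep(documents$id, n_lab),
    specialty = as.character(unlist(documents$specialties))
  )
  specialty_index <- split(label_tbl$id, label_tbl$specialty)
  specialty_index <- lapply(specialty_index, unique)

  structure(
    list(
      documents = documents,
      specialty_index = specialty_index,
      N = nrow(documents),
      N_e = vapply(specialty_index, length, integer(1))
    ),
    class = "specialty_corpus"
  )
}

#' @export
print.specialty_corpus <- function(x, ...) {
  cat("<specialty_corpus> ", x$N, " documents, ",
      length(x$N_e), " specialties\n", sep = "")
  invisible(x)
}

#' @export
length.specialty_corpus <- function(x) x$N

#' Long document-specialty label table
#'
#' One row per (document, specialty) pair; the shape most corpus-level
#' aggregations start from.
#'
#' @param corpus A [specialty_corpus].
#' @return A tibble with columns `id` and `specialty`.
#' @export
corpus_labels <- function(corpus) {
  stopifnot(inherits(corpus, "specialty_corpus"))
  n_lab <- vapply(corpus$documents$specialties, length, integer(1))
  tibble(
    id = rep(corpus$documents$id, n_lab),
    specialty = as.character(unlist(corpus$documents$specialties))
  )
}

#' Subset a corpus by document id
#'
#' @param corpus A [specialty_corpus].
#' @param ids Character vector of document ids to keep.
#' @return A [specialty_corpus] with counts recomputed.
#' @export
corpus_subset <- function(corpus, ids) {
  stopifnot(inherits(corpus, "specialty_corpus"))
  specialty_corpus(corpus$documents[corpus$documents$id %in% ids, , drop = FALSE])
}

# ---- JSON-lines corpus I/O ------------------------------------------------

#' Read / write a corpus as JSON lines
#'
#' One UTF-8 JSON object per line with fields `id`, `title`, `abstract`,
#' `publication_types`, `specialties`, `language`.
#'
#' @param path File path.
#' @return `read_corpus_jsonl()` returns a [specialty_corpus];
#'   `write_corpus_jsonl()` returns `path` invisibly.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  docs <- tibble(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    title = vapply(recs, function(r) as.character(r$title), character(1)),
    abstract = vapply(recs, function(r) {
      if (is.null(r$abstract)) "" else as.character(r$abstract)
    }, character(1)),
    publication_types = lapply(recs, function(r) {
      as.character(r$publication_types %||% character())
    }),
    specialties = lapply(recs, function(r) as.character(r$specialties)),
    language = vapply(recs, function(r) {
      if (is.null(r$language)) "es" else as.character(r$language)
    }, character(1))
  )
  specialty_corpus(docs)
}

#' @rdname read_corpus_jsonl
#' @param corpus A [specialty_corpus] to serialize.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "specialty_corpus"))
  d <- corpus$documents
  lines <- vapply(seq_len(nrow(d)), function(i) {
    jsonlite::toJSON(
      list(
        id = d$id[i], title = d$title[i], abstract = d$abstract[i],
        publication_types = I(d$publication_types[[i]]),
        specialties = I(d$specialties[[i]]), language = d$language[i]
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Specialty descriptors ------------------------------------------------

#' Create a specialty descriptor
#'
#' Descriptors drive query generation and the specialty hierarchy: a
#' level-1 descriptor is a top-level specialty; a level-2 descriptor is a
#' sub-specialty and must name its parent.
#'
#' @param specialty_id Identifier string.
#' @param level 1 or 2.
#' @param parent_id Parent specialty id (required at level 2).
#' @param names_primary Character vector of names in the primary catalog
#'   language (at least one required for query generation).
#' @param names_local Character vector of translated names.
#' @param see_also Character vector of related thesaurus headings to be
#'   searched as subject terms.
#' @return A list of class `specialty_descriptor`.
#' @export
specialty_descriptor <- function(specialty_id, level = 1L, parent_id = NA_character_,
                                 names_primary = character(), names_local = character(),
                                 see_also = character()) {
  level <- as.integer(level)
  stopifnot(level %in% c(1L, 2L))
  if (level == 2L && (is.na(parent_id) || !nzchar(parent_id))) {
    stop("level-2 descriptor '", specialty_id, "' must have a parent_id")
  }
  if (level == 1L) parent_id <- NA_character_
  structure(
    list(specialty_id = specialty_id, level = level, parent_id = parent_id,
         names_primary = as.character(names_primary),
         names_local = as.character(names_local),
         see_also = as.character(see_also)),
    class = "specialty_descriptor"
  )
}

#' Read specialty descriptors from TSV
#'
#' Expected columns: `specialty_id`, `level`, `parent_id`, `names_primary`,
#' `names_local`, `see_also`; the three name columns are `;`-separated.
#'
#' @param path TSV file path.
#' @return A list of [specialty_descriptor] objects named by id.
#' @export
read_specialty_descriptors <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    encoding = "UTF-8", na.strings = c("NA", ""))
  split_semi <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    specialty_descriptor(
      specialty_id = tab$specialty_id[i],
      level = tab$level[i],
      parent_id = if ("parent_id" %in% names(tab)) tab$parent_id[i] else NA_character_,
      names_primary = split_semi(tab$names_primary[i]),
      names_local = split_semi(tab$names_local[i]),
      see_also = split_semi(tab$see_also[i])
    )
  })
  names(out) <- tab$specialty_id
  out
}
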