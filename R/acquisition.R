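#' Build a deterministic PubMed-style query for one specialty
#'
#' Emits a boolean query that (i) restricts the document language with the
#' `LA` field, (ii) searches every specialty name (primary-language and
#' translated) across the record fields translated journal title (`TA`),
#' title/abstract (`TIAB`), corporate author (`CN`), secondary source
#' (`SI`), author keywords (`OT`), affiliation (`AD`), unexpanded subject
#' headings (`MH:noexp`) and subheadings (`SH:noexp`), and (iii) adds each
#' "see also" heading restricted to the subject-heading field (`MH`).
#' Output is a pure function of the descriptor: fields and terms are
#' emitted in the order listed above.
#'
#' @param descriptor A [specialty_descriptor] with at least one
#'   primary-language name.
#' @param language_tag Language code for the `LA` restriction, e.g. `"SPA"`.
#' @return A single query string.
#' @export
#' @examples
#' d <- specialty_descriptor("dermatology",
#'   names_primary = "dermatology", names_local = "dermatología",
#'   see_also = "Skin Diseases")
#' build_pubmed_query(d, "SPA")
build_pubmed_query <- function(descriptor, language_tag = "SPA") {
  stopifnot(inherits(descriptor, "specialty_descriptor"))
  if (length(descriptor$names_primary) == 0) {
    stop("invalid descriptor '", descriptor$specialty_id,
         "': at least one primary-language name is required")
  }
  fields <- c("TA", "TIAB", "CN", "SI", "OT", "AD", "MH:noexp", "SH:noexp")
  terms <- c(descriptor$names_primary, descriptor$names_local)
  name_clauses <- unlist(lapply(fields, function(f) {
    sprintf('"%s"[%s]', terms, f)
  }))
  see_clauses <- if (length(descriptor$see_also)) {
    sprintf('"%s"[MH]', descriptor$see_also)
  } else {
    character()
  }
  paste0('"', language_tag, '"[LA] AND (',
         paste(c(name_clauses, see_clauses), collapse = " OR "), ")")
}

#' Merge sub-specialty corpora into their parents
#'
#' Sub-specialties largely share the terminology of the specialty they
#' derive from, so each level-1 corpus is augmented with all documents of
#' its level-2 children (deduplicated by document id). Level-2 corpora are
#' returned unchanged.
#'
#' @param corpora Named list (by specialty id) of [specialty_corpus].
#' @param hierarchy List of [specialty_descriptor] covering every specialty
#'   in `corpora`.
#' @return Named list of [specialty_corpus].
#' @export
merge_sublevel_terminology <- function(corpora, hierarchy) {
  level <- vapply(hierarchy, function(d) d$level, integer(1))
  ids <- vapply(hierarchy, function(d) d$specialty_id, character(1))
  parents <- vapply(hierarchy, function(d) d$parent_id, character(1))
  names(level) <- names(parents) <- ids

  kids <- intersect(ids[level == 2L], names(corpora))
  orphan <- kids[!parents[kids] %in% ids[level == 1L]]
  if (length(orphan)) {
    stop("level-2 specialties with unknown parent: ", paste(orphan, collapse = ", "))
  }
  out <- corpora
  for (child in kids) {
    parent <- parents[[child]]
    if (!parent %in% names(out)) next
    merged <- bind_rows(out[[parent]]$documents, corpora[[child]]$documents)
    merged <- merged[!duplicated(merged$id), , drop = FALSE]
    out[[parent]] <- specialty_corpus(merged)
  }
  out
}

#' Drop specialties with too few documents
#'
#' Harvesting specialty-specific terms needs a minimum amount of text;
#' specialties at the given hierarchy level with fewer than `min_titles`
#' documents are removed (strictly-less-than). Applied at level 2 after
#' merging, and again at level 1 as the final pruning step.
#'
#' @param corpora Named list of [specialty_corpus].
#' @param min_titles Minimum document count to keep a specialty (default 1000).
#' @param level Hierarchy level to prune; `NULL` prunes every specialty in
#'   `corpora` regardless of level.
#' @param hierarchy List of [specialty_descriptor]; required when `level`
#'   is not `NULL`.
#' @return Named list of [specialty_corpus].
#' @export
filter_small_specialties <- function(corpora, min_titles = 1000L, level = NULL,
                                     hierarchy = NULL) {
  stopifnot(min_titles >= 0)
  at_level <- names(corpora)
  if (!is.null(level)) {
    stopifnot(!is.null(hierarchy))
    lv <- vapply(hierarchy, function(d) d$level, integer(1))
    names(lv) <- vapply(hierarchy, function(d) d$specialty_id, character(1))
    at_level <- names(corpora)[names(corpora) %in% names(lv)[lv == level]]
  }
  too_small <- at_level[vapply(corpora[at_level], function(cc) cc$N, integer(1)) < min_titles]
  corpora[setdiff(names(corpora), too_small)]
}

#' Collapse duplicate specialties
#'
#' A specialty occurring under more than one subtree of the source
#' hierarchy yields duplicate entries; each duplicate group is collapsed to
#' one representative — the lexicographically smallest id, for determinism —
#' whose corpus is the union (by document id) of the group's documents.
#'
#' @param corpora Named list of [specialty_corpus].
#' @param duplicate_groups List of character vectors, each naming the ids
#'   of one duplicate group. Members absent from `corpora` are skipped with
#'   a warning.
#' @return Named list of [specialty_corpus].
#' @export
dedupe_specialties <- function(corpora, duplicate_groups = list()) {
  for (group in duplicate_groups) {
    present <- intersect(group, names(corpora))
    missing <- setdiff(group, names(corpora))
    if (length(missing)) {
      warning("duplicate-group members absent from corpora, skipped: ",
              paste(missing, collapse = ", "))
    }
    if (length(present) < 2) next
    keep <- sort(present)[1]
    merged <- bind_rows(lapply(corpora[present], function(cc) cc$documents))
    merged <- merged[!duplicated(merged$id), , drop = FALSE]
    corpora[[keep]] <- specialty_corpus(merged)
    corpora[setdiff(present, keep)] <- NULL
  }
  corpora
}

#' Split off case reports as an evaluation benchmark
#'
#' Case reports use language close to clinical narratives and are held out
#' as the evaluation set; every other document stays in the build set used
#' for term harvesting. Matching on the publication type is
#' case-insensitive ("Case Reports" and "case reports" both route to the
#' test side).
#'
#' @param corpus A [specialty_corpus].
#' @param tag Publication-type tag marking case reports.
#' @return A list with elements `build_set` and `test_set`, both
#'   [specialty_corpus] (possibly with zero documents represented as `NULL`
#'   when a side is empty).
#' @export
partition_case_reports <- function(corpus, tag = "case reports") {
  stopifnot(inherits(corpus, "specialty_corpus"))
  is_case <- vapply(corpus$documents$publication_types, function(pt) {
    any(tolower(trimws(pt)) == tolower(tag))
  }, logical(1))
  mk <- function(rows) {
    if (!any(rows)) return(NULL)
    specialty_corpus(corpus$documents[rows, , drop = FALSE])
  }
  list(build_set = mk(!is_case), test_set = mk(is_case))
}

#' Fetcher interface for executing corpus queries
#'
#' Live retrieval sits behind a fetcher: a function taking a query string
#' and returning a document tibble (the `documents` shape accepted by
#' [specialty_corpus]). `fixture_fetcher()` returns a fetcher backed by an
#' in-memory corpus that matches queries by specialty id, so every
#' acquisition path is testable offline; a network-backed fetcher with the
#' same signature can be swapped in by the user.
#'
#' @param corpora Named list (by specialty id) of [specialty_corpus] used
#'   as the canned responses.
#' @return A function `(query, specialty_id)` returning a document tibble.
#' @export
fixture_fetcher <- function(corpora) {
  force(corpora)
  function(query, specialty_id) {
    if (!specialty_id %in% names(corpora)) {
      return(tibble(id = character(), title = character(),
                    specialties = list()))
    }
    corpora[[specialty_id]]$documents
  }
}
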