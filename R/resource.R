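# Stop-n-gram detection and assembly of the per-specialty term resource.
#
# The stop-n-gram filter encodes the hypothesis that an n-gram carries no
# specialty information if (a) it appears in nearly all specialties and
# (b) its local relevance (LRM) is both flat (low standard deviation) and
# nowhere high (low maximum) across the specialties where it appears.

#' Default candidacy threshold for stop-n-gram detection
#'
#' Candidates are terms appearing in *more than* 90% of the available
#' specialties; the returned count c is the largest integer such that the
#' candidacy condition `E_t > c` captures exactly the terms present in
#' more than 90% of specialties: `c = floor(0.9 * num_specialties)`.
#'
#' @param num_specialties Number of specialties in the resource (>= 1).
#' @return An integer candidacy threshold.
#' @export
#' @examples
#' default_min_specialty_count(51)  # 45
#' default_min_specialty_count(10)  # 9
default_min_specialty_count <- function(num_specialties) {
  stopifnot(num_specialties >= 1)
  as.integer(floor(0.9 * num_specialties))
}

#' Example stop-n-gram thresholds scaled to the specialty count
#'
#' No universal values for `threshold_sd` / `threshold_max` exist; the
#' natural scale is the uniform local-relevance share: a term spread
#' evenly over k specialties has LRM close to 1/k in each of them, with
#' near-zero dispersion. The example configuration therefore sets
#' `threshold_max = 3/k` (three times the uniform share) and
#' `threshold_sd = 0.4/k`, values calibrated on the synthetic corpus
#' generator and recorded in `inst/extdata/example_filter_config.json`
#' for its default 20-specialty setting.
#'
#' @param num_specialties Number of specialties k (>= 1).
#' @return A list with elements `threshold_sd` and `threshold_max`.
#' @export
example_filter_thresholds <- function(num_specialties) {
  stopifnot(num_specialties >= 1)
  list(threshold_sd = 0.4 / num_specialties,
       threshold_max = 3 / num_specialties)
}

#' Detect stop n-grams
#'
#' From the weighted-term table, selects candidate terms present in more
#' than `min_specialty_count` specialties and flags a candidate as a stop
#' n-gram when the standard deviation of its LRM values — over the
#' specialties where it appears — is below `threshold_sd` AND their
#' maximum is below `threshold_max` (both strict). The standard deviation
#' is the population form, for determinism on small sets.
#'
#' No universal threshold values exist; both must be supplied explicitly.
#' The shipped `inst/extdata/example_filter_config.json` documents values
#' calibrated on the synthetic corpus generator.
#'
#' @param weights Weighted-term table from [weigh_terms()].
#' @param threshold_sd Upper bound (strict) on the LRM standard deviation.
#' @param threshold_max Upper bound (strict) on the LRM maximum.
#' @param min_specialty_count Candidacy threshold; terms must appear in
#'   strictly more specialties than this. Defaults to
#'   [default_min_specialty_count()] of the number of specialties present
#'   in `weights`.
#' @return Character vector of stop n-gram terms (sorted).
#' @export
detect_stop_ngrams <- function(weights, threshold_sd, threshold_max,
                               min_specialty_count = NULL) {
  if (missing(threshold_sd) || missing(threshold_max) ||
      is.null(threshold_sd) || is.null(threshold_max)) {
    stop("threshold_sd and threshold_max must be supplied; ",
         "no defaults exist (see inst/extdata/example_filter_config.json)")
  }
  stopifnot(threshold_sd >= 0, threshold_max >= 0)
  if (is.null(min_specialty_count)) {
    min_specialty_count <- default_min_specialty_count(n_distinct(weights$specialty))
  }
  stopifnot(min_specialty_count >= 0)

  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  prof <- weights %>%
    group_by(.data$term) %>%
    summarise(E_t = dplyr::n(),
              lrm_sd = pop_sd(.data$LRM),
              lrm_max = max(.data$LRM), .groups = "drop") %>%
    filter(.data$E_t > min_specialty_count,
           .data$lrm_sd < threshold_sd,
           .data$lrm_max < threshold_max)
  sort(prof$term)
}

#' Assemble a per-specialty term resource
#'
#' Builds the publishable resource: one term set per specialty (term with
#' its TGM, LPM, LRM), excluding the detected stop n-grams, plus the stop
#' list itself and a provenance snapshot. The excluded rows are retained
#' internally (`stop_table`) so downstream scoring can optionally include
#' them; the published sets are always disjoint from the stop list.
#'
#' @param weights Weighted-term table from [weigh_terms()].
#' @param stop_ngrams Character vector from [detect_stop_ngrams()].
#' @param provenance Named list recorded verbatim (thresholds, n_max,
#'   word-list digests, ...).
#' @return An object of class `term_resource` with fields `sets` (tibble
#'   `term`, `specialty`, `TGM`, `LPM`, `LRM`), `stop_ngrams`,
#'   `stop_table`, `specialties` (ordered vector) and `provenance`.
#' @export
build_resource <- function(weights, stop_ngrams = character(),
                           provenance = list()) {
  cols <- c("term", "specialty", "TGM", "LPM", "LRM")
  stopifnot(all(cols %in% names(weights)))
  tab <- weights %>%
    select(dplyr::all_of(cols)) %>%
    arrange(.data$specialty, desc(.data$LRM), .data$term)
  is_stop <- tab$term %in% stop_ngrams
  structure(
    list(
      sets = tab[!is_stop, , drop = FALSE],
      stop_ngrams = sort(unique(stop_ngrams)),
      stop_table = tab[is_stop, , drop = FALSE],
      specialties = sort(unique(tab$specialty)),
      provenance = provenance
    ),
    class = "term_resource"
  )
}

#' @export
print.term_resource <- function(x, ...) {
  cat("<term_resource> ", n_distinct(x$sets$term), " terms over ",
      length(x$specialties), " specialties; ",
      length(x$stop_ngrams), " stop n-grams\n", sep = "")
  invisible(x)
}

#' Intersect a term resource with an external lexicon
#'
#' Keeps, in every specialty set, only the terms also present in the
#' lexicon (e.g. descriptions from a curated clinical terminology release,
#' normalized with the same pipeline as the resource). The per-specialty
#' retention fraction is attached as the `retention` attribute.
#'
#' @param resource A `term_resource`.
#' @param lexicon Character vector of normalized terms, one per entry.
#' @return A filtered `term_resource` with attribute `retention` (tibble
#'   `specialty`, `n_before`, `n_after`, `retention`).
#' @export
filter_by_lexicon <- function(resource, lexicon) {
  stopifnot(inherits(resource, "term_resource"))
  if (length(lexicon) == 0) {
    warning("empty lexicon: filtered resource has no terms")
  }
  before <- resource$sets %>% count(.data$specialty, name = "n_before")
  resource$sets <- resource$sets[resource$sets$term %in% lexicon, , drop = FALSE]
  after <- resource$sets %>% count(.data$specialty, name = "n_after")
  ret <- left_join(before, after, by = "specialty")
  ret$n_after[is.na(ret$n_after)] <- 0L
  ret$retention <- ret$n_after / ret$n_before
  attr(resource, "retention") <- ret
  resource$provenance$lexicon_filtered <- TRUE
  resource
}

#' Pairwise similarity between specialties
#'
#' Represents each specialty as a vector over the term universe — LRM
#' weights for `method = "cosine"`, set membership for
#' `method = "jaccard"` — and returns the symmetric similarity matrix.
#' Non-empty specialties have unit diagonal; a specialty with an empty
#' term set gets similarity 0 to everything (diagonal included) with a
#' warning.
#'
#' @param resource A `term_resource`.
#' @param method `"cosine"` (LRM-weighted, default) or `"jaccard"`.
#' @return A symmetric numeric matrix with values in `[0, 1]`, dimnames =
#'   specialties.
#' @export
specialty_similarity <- function(resource, method = c("cosine", "jaccard")) {
  stopifnot(inherits(resource, "term_resource"))
  method <- match.arg(method)
  sets <- resource$sets
  if (nrow(sets) == 0) stop("empty resource: no terms to compare")
  specs <- resource$specialties
  terms <- sort(unique(sets$term))
  m <- Matrix::sparseMatrix(
    i = match(sets$term, terms),
    j = match(sets$specialty, specs),
    x = if (method == "cosine") sets$LRM else 1,
    dims = c(length(terms), length(specs)),
    dimnames = list(terms, specs)
  )
  empty <- Matrix::colSums(m != 0) == 0
  if (any(empty)) {
    warning("specialties with empty term sets: ",
            paste(specs[empty], collapse = ", "))
  }
  if (method == "cosine") {
    cross <- as.matrix(Matrix::crossprod(m))
    nrm <- sqrt(diag(cross))
    nrm[nrm == 0] <- 1
    sim <- cross / outer(nrm, nrm)
  } else {
    inter <- as.matrix(Matrix::crossprod(m))
    sizes <- diag(inter)
    uni <- outer(sizes, sizes, "+") - inter
    sim <- ifelse(uni > 0, inter / uni, 0)
  }
  sim[empty, ] <- 0
  sim[, empty] <- 0
  diag(sim)[!empty] <- 1
  diag(sim)[empty] <- 0
  sim
}

# ---- Serialization --------------------------------------------------------

safe_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Write / read a term resource directory
#'
#' Directory layout: one `<specialty>.tsv` per specialty (columns `term`,
#' `TGM`, `LPM`, `LRM`), `stop_ngrams.txt` (one term per line),
#' `stop_table.tsv` (the excluded rows, kept for optional re-inclusion in
#' scoring) and `provenance.json` (config snapshot plus the specialty →
#' file index).
#'
#' @param resource A `term_resource`.
#' @param dir Directory path (created if needed).
#' @return `write_term_resource()` returns `dir` invisibly;
#'   `read_term_resource()` returns the `term_resource`.
#' @export
write_term_resource <- function(resource, dir) {
  stopifnot(inherits(resource, "term_resource"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- stats::setNames(paste0(safe_filename(resource$specialties), ".tsv"),
                           resource$specialties)
  if (anyDuplicated(files)) {
    files[] <- paste0(safe_filename(resource$specialties), "_",
                      seq_along(files), ".tsv")
  }
  for (s in resource$specialties) {
    sub <- resource$sets[resource$sets$specialty == s,
                         c("term", "TGM", "LPM", "LRM"), drop = FALSE]
    write.table(sub, file.path(dir, files[[s]]), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  writeLines(resource$stop_ngrams, file.path(dir, "stop_ngrams.txt"),
             useBytes = TRUE)
  write.table(resource$stop_table, file.path(dir, "stop_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(provenance = resource$provenance, files = as.list(files)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_term_resource
#' @export
read_term_resource <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "provenance.json"),
                             simplifyVector = FALSE)
  files <- meta$files
  sets <- bind_rows(lapply(names(files), function(s) {
    tab <- read.delim(file.path(dir, files[[s]]), sep = "\t",
                      stringsAsFactors = FALSE, encoding = "UTF-8", quote = "")
    if (nrow(tab) == 0) return(NULL)
    tab$specialty <- s
    tab
  }))
  stop_ngrams <- readLines(file.path(dir, "stop_ngrams.txt"),
                           encoding = "UTF-8", warn = FALSE)
  stop_ngrams <- stop_ngrams[nzchar(stop_ngrams)]
  stop_table <- as_tibble(read.delim(file.path(dir, "stop_table.tsv"),
                                     sep = "\t", stringsAsFactors = FALSE,
                                     encoding = "UTF-8", quote = ""))
  res <- build_resource(
    bind_rows(as_tibble(sets), stop_table),
    stop_ngrams = stop_ngrams,
    provenance = meta$provenance
  )
  res
}
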