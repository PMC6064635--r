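#' Build a multi-pattern term matcher
#'
#' Compiles all surface forms of a lexicon into a single scanner with a
#' fixed matching contract: matching is case-insensitive (text and forms are
#' NFC-normalised and case-folded), a match may not begin or end inside an
#' alphanumeric run (token boundaries are transitions between alphanumeric
#' and non-alphanumeric characters; hyphens inside a form such as "omega-3"
#' are literal), the longest surface form wins at each position, and matched
#' spans never overlap (the scan resumes after each match).
#'
#' @param lexicon A `term_lexicon` with at least one surface form.
#' @return A `term_matcher` object.
#' @export
build_matcher <- function(lexicon) {
  if (!inherits(lexicon, "term_lexicon")) abort("build_matcher() expects a term_lexicon")
  index <- lexicon$index
  if (nrow(index) == 0) abort("lexicon has zero surface forms")

  forms <- unique(index$surface)
  # longest-first alternation: PCRE tries alternatives in order, so the
  # longest form available at a position is the one matched
  forms <- forms[order(-nchar(forms), forms)]
  esc <- stringr::str_replace_all(forms, "([.^$*+?()\\[\\]{}|\\\\])", "\\\\\\1")
  esc <- gsub(" ", "[[:space:]]+", esc, fixed = TRUE)
  pattern <- paste0("(?<![[:alnum:]])(?:", paste(esc, collapse = "|"),
                    ")(?![[:alnum:]])")

  lookup <- split(index$term_id, index$surface)
  structure(list(pattern = pattern, lookup = lookup, n_forms = length(forms)),
            class = "term_matcher")
}

#' @export
print.term_matcher <- function(x, ...) {
  cat(sprintf("<term_matcher> %d surface forms\n", x$n_forms))
  invisible(x)
}

#' Tag a single text with lexicon terms
#'
#' Scans a plain text with the matcher and returns all term matches in
#' left-to-right order. Offsets are 0-based, half-open character positions
#' in the normalised (NFC, case-folded) text. A surface form shared by k
#' terms yields k rows with the same span.
#'
#' @param matcher A `term_matcher` from [build_matcher()].
#' @param text A single character string (may be empty or `NA`).
#' @return A tibble with columns `term_id`, `start`, `end`, `surface`.
#' @export
tag_text <- function(matcher, text) {
  empty <- tibble(term_id = character(0), start = integer(0),
                  end = integer(0), surface = character(0))
  if (is.na(text) || !nzchar(text)) return(empty)
  norm <- stringi::stri_trans_tolower(stringi::stri_trans_nfc(text))
  m <- gregexpr(matcher$pattern, norm, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surfaces <- substring(norm, starts, starts + lens - 1L)
  hits <- purrr::map(seq_along(starts), function(i) {
    ids <- matcher$lookup[[normalize_surface(surfaces[i])]]
    if (is.null(ids)) return(NULL)
    tibble(term_id = sort(ids),
           start = starts[i] - 1L,
           end = starts[i] + lens[i] - 1L,
           surface = surfaces[i])
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) empty else out
}

#' Tag a corpus of citations
#'
#' Applies the matcher to every abstract and reduces matches to per-document
#' term presence: a term counts at most once per abstract regardless of how
#' many times it is mentioned. Documents without an abstract (or with no
#' matches) are "not annotated" and contribute no rows.
#'
#' @param citations Tibble with columns `citation_id` and `abstract`.
#' @param matcher A `term_matcher`.
#' @return A tibble with columns `citation_id`, `term_id` (distinct pairs),
#'   with attribute `annotated_count` -- the number of documents in which at
#'   least one term was found.
#' @export
tag_corpus <- function(citations, matcher) {
  stopifnot(all(c("citation_id", "abstract") %in% names(citations)))
  texts <- citations$abstract
  norm <- ifelse(is.na(texts), "",
                 stringi::stri_trans_tolower(stringi::stri_trans_nfc(texts)))
  ms <- gregexpr(matcher$pattern, norm, perl = TRUE)
  rows <- purrr::map(seq_along(norm), function(i) {
    m <- ms[[i]]
    if (m[1] == -1L || !nzchar(norm[i])) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    surfaces <- normalize_surface(substring(norm[i], starts, starts + lens - 1L))
    ids <- unique(unlist(matcher$lookup[surfaces], use.names = FALSE))
    if (!length(ids)) return(NULL)
    tibble(citation_id = citations$citation_id[i], term_id = sort(ids))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(citation_id = character(0), term_id = character(0))
  }
  out <- distinct(out, .data$citation_id, .data$term_id)
  attr(out, "annotated_count") <- dplyr::n_distinct(out$citation_id)
  out
}

#' Number of annotated documents in a tagging result
#'
#' @param tags Result of [tag_corpus()].
#' @return Integer count of documents with at least one present term.
#' @export
annotated_count <- function(tags) {
  attr(tags, "annotated_count") %||% dplyr::n_distinct(tags$citation_id)
}

#' Write tagged documents as JSON lines
#'
#' One JSON object per annotated document (`citation_id`, `present_terms`),
#' for audit of the tagging stage.
#'
#' @param tags Result of [tag_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags_jsonl <- function(tags, path) {
  by_doc <- split(tags$term_id, tags$citation_id)
  lines <- purrr::imap_chr(by_doc, function(terms, id) {
    jsonlite::toJSON(list(citation_id = id, present_terms = terms),
                     auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}
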