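#' Build the search-cell x term presence-count table
#'
#' Crosses a tagged corpus with its cell assignments into a cells x terms
#' matrix of document-presence counts: `counts[cell, term]` is the number of
#' documents in the cell whose abstract contains the term at least once.
#' Per-cell totals of parsed documents (`n_docs`) and annotated documents
#' (`annotated_docs`, at least one term found) are recorded alongside; the
#' latter is the denominator of document-based normalisation.
#'
#' @param corpus Citation tibble with cell columns, as from [read_corpus()]
#'   (requires `citation_id`, `cell_id`, `disease_group`, `keyword_category`,
#'   `start_year`, `end_year`).
#' @param tags Tagging result from [tag_corpus()] for the same citations.
#' @param cells Optional cell tibble from [enumerate_cells()]; cells with no
#'   documents are then kept as all-zero rows. Defaults to the cells observed
#'   in `corpus`.
#' @return A `term_table` object.
#' @export
build_counts <- function(corpus, tags, cells = NULL) {
  need <- c("citation_id", "cell_id", "disease_group", "keyword_category",
            "start_year", "end_year")
  stopifnot(all(need %in% names(corpus)))
  if (nrow(corpus) == 0) abort("empty corpus: no citations to count")

  if (is.null(cells)) {
    cells <- corpus %>%
      distinct(.data$cell_id, .data$disease_group, .data$keyword_category,
               .data$start_year, .data$end_year) %>%
      arrange(.data$disease_group, .data$keyword_category, .data$start_year)
  } else {
    cells <- cells %>%
      select("cell_id", "disease_group", "keyword_category",
             "start_year", "end_year")
    stray <- setdiff(corpus$cell_id, cells$cell_id)
    if (length(stray)) {
      abort(paste0("corpus contains cell(s) absent from the grid: ",
                   paste(stray, collapse = ", ")))
    }
  }

  doc_cell <- distinct(corpus, .data$citation_id, .data$cell_id)
  if (anyDuplicated(doc_cell$citation_id)) {
    warn("some citations appear in more than one cell; they count in each")
  }

  hits <- tags %>%
    dplyr::inner_join(doc_cell, by = "citation_id",
                      relationship = "many-to-many")
  terms <- sort(unique(hits$term_id))
  counts <- matrix(0L, nrow = nrow(cells), ncol = length(terms),
                   dimnames = list(cells$cell_id, terms))
  if (nrow(hits)) {
    tab <- hits %>% count(.data$cell_id, .data$term_id)
    counts[cbind(match(tab$cell_id, cells$cell_id),
                 match(tab$term_id, terms))] <- tab$n
  }

  per_cell <- corpus %>%
    group_by(.data$cell_id) %>%
    summarise(n_docs = dplyr::n_distinct(.data$citation_id), .groups = "drop")
  annotated <- hits %>%
    group_by(.data$cell_id) %>%
    summarise(annotated_docs = dplyr::n_distinct(.data$citation_id),
              .groups = "drop")
  cells <- cells %>%
    left_join(per_cell, by = "cell_id") %>%
    left_join(annotated, by = "cell_id") %>%
    mutate(n_docs = ifelse(is.na(.data$n_docs), 0L, .data$n_docs),
           annotated_docs = ifelse(is.na(.data$annotated_docs), 0L,
                                   .data$annotated_docs))

  new_term_table(cells, counts)
}

new_term_table <- function(cells, counts, normalized = NULL,
                           norm_scope = NULL) {
  stopifnot(identical(cells$cell_id, rownames(counts)))
  structure(list(cells = as_tibble(cells), counts = counts,
                 normalized = normalized, norm_scope = norm_scope),
            class = "term_table")
}

#' @export
print.term_table <- function(x, ...) {
  cat(sprintf("<term_table> %d cells x %d terms; %s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "counts only"
              else sprintf("normalized (scope = %s)", x$norm_scope)))
  invisible(x)
}

#' @export
dim.term_table <- function(x) dim(x$counts)

#' Tidy a term table into long form
#'
#' @param x A `term_table`.
#' @param ... Unused.
#' @return A long tibble: one row per (cell, term) with cell metadata,
#'   `count` and (when computed) `normalized`.
#' @export
tidy.term_table <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "cell_id") %>%
    tidyr::pivot_longer(-"cell_id", names_to = "term_id", values_to = "count")
  if (!is.null(x$normalized)) {
    norm <- as_tibble(x$normalized, rownames = "cell_id") %>%
      tidyr::pivot_longer(-"cell_id", names_to = "term_id",
                          values_to = "normalized")
    long <- left_join(long, norm, by = c("cell_id", "term_id"))
  }
  left_join(x$cells, long, by = "cell_id")
}

#' @export
glance.term_table <- function(x, ...) {
  tibble(n_cells = nrow(x$counts), n_terms = ncol(x$counts),
         n_docs = sum(x$cells$n_docs),
         annotated_docs = sum(x$cells$annotated_docs),
         normalized = !is.null(x$normalized))
}

#' Remove rare terms
#'
#' Drops terms whose presence-hit total over all cells falls below
#' `min_total` (default 5, i.e. terms with fewer than five hits across all
#' searches are removed). The cell axis is unchanged.
#'
#' @param table A `term_table`.
#' @param min_total Minimum column sum required to keep a term.
#' @return The filtered `term_table`.
#' @export
filter_rare <- function(table, min_total = 5) {
  stopifnot(inherits(table, "term_table"))
  keep <- colSums(table$counts) >= min_total
  if (!any(keep)) {
    abort(sprintf("all %d terms fall below min_total = %s; lower the threshold",
                  ncol(table$counts), format(min_total)))
  }
  subset_table_terms(table, colnames(table$counts)[keep])
}

#' Document-based normalisation
#'
#' Divides each cell's presence counts by its number of annotated documents,
#' adjusting for the varying volume of literature across searches. With
#' `scope = "cell"` (default) the denominator is the cell's own annotated
#' count; with `scope = "group_yearpair"` it is the annotated total of all
#' cells sharing the cell's disease group and year pair (the keyword
#' categories pooled).
#'
#' @param table A `term_table`.
#' @param scope `"cell"` or `"group_yearpair"`.
#' @return The `term_table` with a `normalized` matrix attached.
#' @export
normalize_documents <- function(table, scope = c("cell", "group_yearpair")) {
  stopifnot(inherits(table, "term_table"))
  scope <- match.arg(scope)
  cells <- table$cells
  if (scope == "cell") {
    denom <- cells$annotated_docs
  } else {
    denom <- cells %>%
      group_by(.data$disease_group, .data$start_year) %>%
      mutate(denom = sum(.data$annotated_docs)) %>%
      ungroup() %>%
      pull("denom")
  }
  zero_bad <- denom == 0 & rowSums(table$counts) > 0
  if (any(zero_bad)) {
    abort(paste0("cell(s) with nonzero counts but zero annotated documents: ",
                 paste(cells$cell_id[zero_bad], collapse = ", ")))
  }
  safe <- ifelse(denom == 0, 1, denom)
  normalized <- table$counts / safe
  new_term_table(cells, table$counts, normalized = normalized,
                 norm_scope = scope)
}

#' Restrict a table to a term subset
#'
#' Column-subsets the table to the given term ids, in subset order. Unknown
#' ids are reported with a warning (available as attribute `unmatched`);
#' an empty intersection is an error.
#'
#' @param table A `term_table`.
#' @param subset Character vector of term ids (e.g. from
#'   [read_term_subset()]).
#' @return The subsetted `term_table`.
#' @export
select_terms <- function(table, subset) {
  stopifnot(inherits(table, "term_table"))
  found <- subset[subset %in% colnames(table$counts)]
  unmatched <- setdiff(subset, found)
  if (!length(found)) abort("none of the subset terms occur in the table")
  if (length(unmatched)) {
    warn(sprintf("select_terms(): %d subset id(s) not in the table", length(unmatched)))
  }
  out <- subset_table_terms(table, found)
  attr(out, "unmatched") <- unmatched
  out
}

subset_table_terms <- function(table, term_ids) {
  counts <- table$counts[, term_ids, drop = FALSE]
  normalized <- if (is.null(table$normalized)) NULL
                else table$normalized[, term_ids, drop = FALSE]
  new_term_table(table$cells, counts, normalized, table$norm_scope)
}

#' Default time intervals
#'
#' The four multi-year intervals used for interval-level differential
#' analysis: 1991-1998, 1999-2004, 2005-2010, 2011-2016.
#'
#' @return Tibble with columns `start`, `end`, `label`.
#' @export
default_intervals <- function() {
  tibble(start = c(1991L, 1999L, 2005L, 2011L),
         end = c(1998L, 2004L, 2010L, 2016L)) %>%
    mutate(label = paste0(.data$start, "-", .data$end))
}

#' Label cells with time intervals
#'
#' Assigns each cell's year pair to a time interval. Intervals must be
#' disjoint, cover every cell, and align with pair boundaries: a year pair
#' straddling an interval boundary is an error.
#'
#' @param table A `term_table`.
#' @param intervals Tibble with columns `start`, `end` (and optionally
#'   `label`); defaults to [default_intervals()].
#' @return The `term_table` with an `interval` column added to its cells.
#' @export
bin_intervals <- function(table, intervals = default_intervals()) {
  stopifnot(inherits(table, "term_table"))
  intervals <- as_tibble(intervals)
  if (!"label" %in% names(intervals)) {
    intervals$label <- paste0(intervals$start, "-", intervals$end)
  }
  iv <- arrange(intervals, .data$start)
  if (any(iv$end < iv$start)) abort("interval with end < start")
  if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
    abort("intervals overlap")
  }
  cells <- table$cells
  idx_start <- purrr::map_int(cells$start_year, function(y) {
    hit <- which(iv$start <= y & y <= iv$end)
    if (length(hit)) hit else NA_integer_
  })
  idx_end <- purrr::map_int(cells$end_year, function(y) {
    hit <- which(iv$start <= y & y <= iv$end)
    if (length(hit)) hit else NA_integer_
  })
  uncovered <- is.na(idx_start) | is.na(idx_end)
  if (any(uncovered)) {
    abort(paste0("cell(s) outside the intervals: ",
                 paste(cells$cell_id[uncovered], collapse = ", ")))
  }
  straddle <- idx_start != idx_end
  if (any(straddle)) {
    abort(paste0("year pair(s) straddling an interval boundary: ",
                 paste(cells$cell_id[straddle], collapse = ", ")))
  }
  cells$interval <- iv$label[idx_start]
  new_term_table(cells, table$counts, table$normalized, table$norm_scope)
}

#' Most frequent terms of a disease group
#'
#' Ranks terms by their aggregate normalised frequency -- the sum of
#' normalised values over all of the group's cells across the whole time
#' frame -- and returns the top `k` (default 20). Ties are broken
#' lexicographically by term id for reproducibility.
#'
#' @param table A normalised `term_table`.
#' @param group A disease-group label present in the table.
#' @param k Number of terms to return.
#' @return Tibble with columns `term_id`, `frequency`, `rank`.
#' @export
top_terms <- function(table, group, k = 20) {
  stopifnot(inherits(table, "term_table"))
  if (is.null(table$normalized)) abort("normalize_documents() must run before top_terms()")
  sel <- table$cells$disease_group == group
  if (!any(sel)) {
    abort(sprintf("unknown disease group '%s'; available: %s", group,
                  paste(unique(table$cells$disease_group), collapse = ", ")))
  }
  agg <- colSums(table$normalized[sel, , drop = FALSE])
  out <- tibble(term_id = names(agg), frequency = unname(agg)) %>%
    arrange(desc(.data$frequency), .data$term_id) %>%
    slice_head(n = k) %>%
    mutate(rank = row_number())
  out
}

#' Serialise a term table to TSV
#'
#' Writes the table as a wide TSV (rows = cells, columns = term ids) plus a
#' sidecar TSV of per-cell document totals. Normalised values are written
#' with six decimal places.
#'
#' @param table A `term_table`.
#' @param path Output path for the main table; the sidecar is written next
#'   to it with suffix `.cells.tsv`.
#' @param what `"counts"` or `"normalized"`.
#' @return `path`, invisibly.
#' @export
write_term_table <- function(table, path, what = c("counts", "normalized")) {
  what <- match.arg(what)
  m <- if (what == "counts") table$counts else table$normalized
  if (is.null(m)) abort("table has no normalized matrix; run normalize_documents()")
  df <- as_tibble(m, rownames = "cell_id")
  if (what == "normalized") {
    df <- mutate(df, dplyr::across(-"cell_id", ~ formatC(.x, digits = 6, format = "f")))
  }
  readr::write_tsv(df, path)
  readr::write_tsv(table$cells, paste0(path, ".cells.tsv"))
  invisible(path)
}

#' Read a term table written by [write_term_table()]
#'
#' @param path Path given to [write_term_table()].
#' @param what `"counts"` or `"normalized"` -- what the file contains.
#' @return A `term_table` (with `normalized` set when `what = "normalized"`;
#'   counts are then unavailable and set to the rounded product with the
#'   denominators only if recoverable, otherwise left as the read matrix).
#' @export
read_term_table <- function(path, what = c("counts", "normalized")) {
  what <- match.arg(what)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  cells <- readr::read_tsv(paste0(path, ".cells.tsv"), show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cell_id
  cells <- as_tibble(cells)
  if (what == "counts") {
    storage.mode(m) <- "integer"
    new_term_table(cells, m)
  } else {
    counts <- round(m * cells$annotated_docs)
    storage.mode(counts) <- "integer"
    new_term_table(cells, counts, normalized = m, norm_scope = "cell")
  }
}
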