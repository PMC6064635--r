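#' Read citations from MEDLINE (tagged) text
#'
#' Parses the MEDLINE "tagged" export format produced by PubMed's Citation
#' Manager: each record is a block of `TAG - value` lines (tag padded to four
#' characters), blocks separated by blank lines, with continuation lines
#' indented and folded into the preceding field with a single space.
#'
#' Only the fields the downstream workflow uses are kept: `PMID` (the
#' citation identifier), `TI` (title), `AB` (abstract) and the leading four
#' digits of `DP` (publication year). Records without an `AB` field are kept
#' with a missing abstract; an unparseable `DP` yields a missing year and a
#' warning.
#'
#' @param x Path to a MEDLINE file, or a character vector of lines, or a
#'   single string containing the whole document.
#' @param source_file Label recorded in the `source_file` column; defaults to
#'   the path when `x` is a path.
#'
#' @return A tibble with columns `citation_id`, `title`, `abstract`, `year`
#'   and `source_file`, one row per record.
#' @export
#' @examples
#' txt <- c("PMID- 12345", "TI  - A title", "AB  - An abstract", "DP  - 1999 Jan")
#' read_medline(txt)
read_medline <- function(x, source_file = NULL) {
  lines <- read_input_lines(x)
  if (is.null(source_file)) {
    source_file <- if (length(x) == 1 && file.exists(x)) x else NA_character_
  }

  # byte offset of the start of each line, for error reporting
  offsets <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))[seq_along(lines)]

  blank <- !nzchar(trimws(lines))
  block_id <- cumsum(blank & !c(TRUE, blank[-length(blank)]))
  block_id[blank] <- NA_integer_

  keep <- !is.na(block_id)
  if (!any(keep)) {
    return(empty_citations(source_file))
  }

  blocks <- split(seq_along(lines)[keep], block_id[keep])
  recs <- lapply(blocks, function(idx) {
    parse_medline_block(lines[idx], offsets[idx[1]], source_file)
  })
  out <- bind_rows(recs)
  dup <- duplicated(out$citation_id)
  if (any(dup)) {
    warn(sprintf("read_medline(): %d duplicate PMID(s) dropped (first occurrence kept)",
                 sum(dup)))
    out <- out[!dup, ]
  }
  out
}

parse_medline_block <- function(lines, byte_offset, source_file) {
  tag_re <- "^([A-Z0-9]{1,4})\\s*- "
  is_tag <- grepl(tag_re, lines)
  is_cont <- grepl("^\\s+\\S", lines) & !is_tag

  fields <- character(0)
  values <- character(0)
  for (i in seq_along(lines)) {
    if (is_tag[i]) {
      fields <- c(fields, sub(paste0(tag_re, ".*$"), "\\1", lines[i]))
      values <- c(values, sub(tag_re, "", lines[i]))
    } else if (is_cont[i] && length(values)) {
      values[length(values)] <- paste(values[length(values)],
                                      trimws(lines[i]))
    }
  }

  first <- function(tag) {
    hit <- which(fields == tag)
    if (length(hit)) trimws(values[hit[1]]) else NA_character_
  }

  pmid <- first("PMID")
  if (is.na(pmid) || !nzchar(pmid)) {
    abort(sprintf("MEDLINE block at byte offset %d has no PMID tag", byte_offset))
  }
  dp <- first("DP")
  year <- NA_integer_
  if (!is.na(dp)) {
    m <- regmatches(dp, regexpr("^\\d{4}", dp))
    if (length(m)) {
      year <- as.integer(m)
    } else {
      warn(sprintf("record %s: DP field '%s' has no leading 4-digit year", pmid, dp))
    }
  }
  tibble(
    citation_id = pmid,
    title = first("TI"),
    abstract = first("AB"),
    year = year,
    source_file = source_file %||% NA_character_
  )
}

#' Write citations to MEDLINE (tagged) text
#'
#' Inverse of [read_medline()] for the fields this package tracks. Long
#' abstracts can be wrapped onto indented continuation lines; because the
#' reader folds continuations with a single space, wrapping round-trips
#' exactly for single-spaced text.
#'
#' @param citations Tibble with columns `citation_id`, `title`, `abstract`,
#'   `year` (as returned by [read_medline()]).
#' @param path Optional file path; when `NULL` the lines are returned invisibly
#'   only.
#' @param wrap Width at which field values are wrapped, or `NULL` for no
#'   wrapping.
#' @return Invisibly, the character vector of lines written.
#' @export
write_medline <- function(citations, path = NULL, wrap = NULL) {
  fmt_field <- function(tag, value) {
    if (is.na(value)) return(character(0))
    tag4 <- formatC(tag, width = 4, flag = "-")
    if (is.null(wrap)) return(paste0(tag4, "- ", value))
    pieces <- strwrap(value, width = wrap)
    c(paste0(tag4, "- ", pieces[1]),
      if (length(pieces) > 1) paste0("      ", pieces[-1]))
  }
  blocks <- lapply(seq_len(nrow(citations)), function(i) {
    r <- citations[i, ]
    c(fmt_field("PMID", r$citation_id),
      fmt_field("TI", r$title),
      fmt_field("AB", r$abstract),
      fmt_field("DP", if (is.na(r$year)) NA_character_ else as.character(r$year)),
      "")
  })
  lines <- unlist(blocks)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read citations from BibTeX
#'
#' Parses a BibTeX export and keeps one record per entry whose PubMed
#' identifier can be resolved. The identifier is taken, in priority order,
#' from a `pmid` field, from a `note` field containing `PMID: <digits>`, or
#' from an entry key consisting entirely of digits. Entries with no
#' resolvable identifier are skipped with a warning reporting the count
#' (also available as the `skipped` attribute of the result).
#'
#' @inheritParams read_medline
#' @return A tibble with columns `citation_id`, `title`, `abstract`, `year`,
#'   `source_file`, with attribute `skipped` (number of entries dropped).
#' @export
read_bibtex <- function(x, source_file = NULL) {
  lines <- read_input_lines(x)
  if (is.null(source_file)) {
    source_file <- if (length(x) == 1 && file.exists(x)) x else NA_character_
  }
  text <- paste(lines, collapse = "\n")
  entries <- parse_bibtex_entries(text)

  skipped <- 0L
  recs <- list()
  for (e in entries) {
    flds <- e$fields
    id <- NA_character_
    if (!is.null(flds$pmid) && grepl("\\d", flds$pmid)) {
      id <- stringr::str_extract(flds$pmid, "\\d+")
    } else if (!is.null(flds$note) && grepl("PMID:?\\s*\\d+", flds$note, ignore.case = TRUE)) {
      id <- stringr::str_extract(flds$note, "(?i)(?<=PMID:)\\s*\\d+")
      id <- trimws(id)
    } else if (grepl("^\\d+$", e$key)) {
      id <- e$key
    }
    if (is.na(id)) {
      skipped <- skipped + 1L
      next
    }
    year <- suppressWarnings(as.integer(stringr::str_extract(flds$year %||% "", "\\d{4}")))
    recs[[length(recs) + 1L]] <- tibble(
      citation_id = id,
      title = flds$title %||% NA_character_,
      abstract = flds$abstract %||% NA_character_,
      year = year,
      source_file = source_file %||% NA_character_
    )
  }
  if (skipped > 0) {
    warn(sprintf("read_bibtex(): %d entr%s without a resolvable PMID skipped",
                 skipped, if (skipped == 1) "y" else "ies"))
  }
  out <- if (length(recs)) bind_rows(recs) else empty_citations(source_file)
  dup <- duplicated(out$citation_id)
  if (any(dup)) {
    warn(sprintf("read_bibtex(): %d duplicate PMID(s) dropped", sum(dup)))
    out <- out[!dup, ]
  }
  attr(out, "skipped") <- skipped
  out
}

# Minimal BibTeX reader: entries @type{key, name = {value}|"value"|bare, ...}.
# Brace-balanced values; @comment/@preamble/@string blocks are ignored.
parse_bibtex_entries <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  entries <- list()
  while (i <= n) {
    if (chars[i] != "@") { i <- i + 1L; next }
    j <- i + 1L
    while (j <= n && grepl("[A-Za-z]", chars[j])) j <- j + 1L
    type <- tolower(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
    while (j <= n && grepl("\\s", chars[j])) j <- j + 1L
    if (j > n || chars[j] != "{") abort("malformed BibTeX: expected '{' after entry type")
    # find matching close brace
    depth <- 1L; k <- j + 1L
    while (k <= n && depth > 0L) {
      if (chars[k] == "{") depth <- depth + 1L
      if (chars[k] == "}") depth <- depth - 1L
      k <- k + 1L
    }
    if (depth != 0L) abort("malformed BibTeX: unbalanced braces in entry")
    body <- substr(text, j + 1L, k - 2L)
    if (!type %in% c("comment", "preamble", "string")) {
      entries[[length(entries) + 1L]] <- parse_bibtex_body(body)
    }
    i <- k
  }
  entries
}

parse_bibtex_body <- function(body) {
  comma <- regexpr(",", body, fixed = TRUE)
  if (comma == -1L) {
    return(list(key = trimws(body), fields = list()))
  }
  key <- trimws(substr(body, 1L, comma - 1L))
  rest <- substr(body, comma + 1L, nchar(body))
  chars <- strsplit(rest, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  fields <- list()
  while (i <= n) {
    while (i <= n && grepl("[\\s,]", chars[i], perl = TRUE)) i <- i + 1L
    if (i > n) break
    j <- i
    while (j <= n && grepl("[A-Za-z0-9_-]", chars[j])) j <- j + 1L
    name <- tolower(paste(chars[i:(j - 1L)], collapse = ""))
    if (!nzchar(name)) abort("malformed BibTeX: empty field name")
    while (j <= n && grepl("\\s", chars[j])) j <- j + 1L
    if (j > n || chars[j] != "=") abort(sprintf("malformed BibTeX: expected '=' after field '%s'", name))
    j <- j + 1L
    while (j <= n && grepl("\\s", chars[j])) j <- j + 1L
    if (j > n) abort(sprintf("malformed BibTeX: field '%s' has no value", name))
    if (chars[j] == "{") {
      depth <- 1L; k <- j + 1L
      while (k <= n && depth > 0L) {
        if (chars[k] == "{") depth <- depth + 1L
        if (chars[k] == "}") depth <- depth - 1L
        k <- k + 1L
      }
      if (depth != 0L) abort("malformed BibTeX: unbalanced braces in field value")
      value <- paste(chars[(j + 1L):(k - 2L)], collapse = "")
      i <- k
    } else if (chars[j] == '"') {
      k <- j + 1L
      while (k <= n && chars[k] != '"') k <- k + 1L
      if (k > n) abort("malformed BibTeX: unterminated quoted value")
      value <- paste(chars[(j + 1L):(k - 1L)], collapse = "")
      i <- k + 1L
    } else {
      k <- j
      while (k <= n && !grepl("[,\\s]", chars[k], perl = TRUE)) k <- k + 1L
      value <- paste(chars[j:(k - 1L)], collapse = "")
      i <- k
    }
    value <- gsub("\\s+", " ", trimws(value))
    fields[[name]] <- value
  }
  list(key = key, fields = fields)
}

#' Enumerate the search-cell grid
#'
#' Builds every search cell of a disease-group x keyword-category x year-pair
#' grid, with consecutive non-overlapping pairs of years spanning
#' `first_year` to `last_year` (the span must cover an even number of years).
#' With the study's own grid -- four disease groups, three nutritional
#' keyword categories and the years 1991 to 2016 -- this yields 156 cells.
#'
#' @param groups Character vector of disease-group labels.
#' @param categories Character vector of keyword-category labels.
#' @param first_year,last_year Integer bounds of the timeline (inclusive).
#' @return A tibble of cells with columns `cell_id`, `disease_group`,
#'   `keyword_category`, `start_year`, `end_year` and `pair_index` (0-based
#'   index of the year pair within the timeline).
#' @export
#' @examples
#' nrow(enumerate_cells(c("CD", "UC", "CCD", "IBS"),
#'                      c("Diet", "Food", "Nutrition"), 1991, 2016))
enumerate_cells <- function(groups, categories, first_year, last_year) {
  stopifnot(length(groups) >= 1, length(categories) >= 1)
  span <- last_year - first_year + 1L
  if (span <= 0 || span %% 2L != 0L) {
    abort(sprintf(
      "year span %d-%d covers %d year(s); pairs of years need an even span - extend or trim the range",
      first_year, last_year, span))
  }
  starts <- seq(as.integer(first_year), as.integer(last_year), by = 2L)
  grid <- tidyr::expand_grid(
    disease_group = as.character(groups),
    keyword_category = as.character(categories),
    start_year = starts
  ) %>%
    mutate(
      end_year = .data$start_year + 1L,
      pair_index = match(.data$start_year, starts) - 1L,
      cell_id = cell_label(.data$disease_group, .data$keyword_category,
                           .data$start_year, .data$end_year)
    ) %>%
    select("cell_id", "disease_group", "keyword_category",
           "start_year", "end_year", "pair_index")
  if (anyDuplicated(grid$cell_id)) abort("duplicate cells in grid; labels must be unique")
  grid
}

cell_label <- function(group, category, start_year, end_year) {
  paste0(group, "|", category, "|", start_year, "-", end_year)
}

#' Read a corpus manifest
#'
#' The manifest is a TSV with columns `file_path`, `disease_group`,
#' `keyword_category`, `start_year`, `end_year`, mapping each citation file
#' to its search cell. Relative paths are resolved against the manifest's
#' directory. Every referenced file must exist and no file may be mapped to
#' two cells.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with the manifest columns plus `cell_id`.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("file_path", "disease_group", "keyword_category", "start_year", "end_year")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")))
  }
  base <- dirname(path)
  man$file_path <- ifelse(grepl("^(/|[A-Za-z]:)", man$file_path),
                          man$file_path,
                          file.path(base, man$file_path))
  gone <- !file.exists(man$file_path)
  if (any(gone)) {
    abort(paste0("manifest references missing file(s): ",
                 paste(man$file_path[gone], collapse = ", ")))
  }
  if (anyDuplicated(man$file_path)) {
    abort("manifest maps the same file to more than one cell")
  }
  if (any(man$end_year != man$start_year + 1L)) {
    abort("manifest cells must be consecutive year pairs (end_year = start_year + 1)")
  }
  man %>%
    mutate(cell_id = cell_label(.data$disease_group, .data$keyword_category,
                                .data$start_year, .data$end_year)) %>%
    as_tibble()
}

#' Infer search cells from file names
#'
#' Fallback when no manifest is available: files named
#' `<group>_<category>_<start>-<end>.<ext>` (extension `bib`, `txt` or `med`)
#' are mapped to their cells.
#'
#' @param paths Character vector of file paths.
#' @return A manifest-shaped tibble (see [read_manifest()]).
#' @export
cells_from_filenames <- function(paths) {
  re <- "^(.+)_(.+)_(\\d{4})-(\\d{4})\\.(bib|txt|med)$"
  base <- basename(paths)
  bad <- !grepl(re, base)
  if (any(bad)) {
    abort(paste0("file name(s) not matching '<group>_<category>_<start>-<end>.<ext>': ",
                 paste(base[bad], collapse = ", ")))
  }
  tibble(
    file_path = paths,
    disease_group = sub(re, "\\1", base),
    keyword_category = sub(re, "\\2", base),
    start_year = as.integer(sub(re, "\\3", base)),
    end_year = as.integer(sub(re, "\\4", base))
  ) %>%
    mutate(cell_id = cell_label(.data$disease_group, .data$keyword_category,
                                .data$start_year, .data$end_year))
}

#' Read a whole corpus described by a manifest
#'
#' Parses every file in the manifest (BibTeX for `.bib`, MEDLINE otherwise)
#' and returns one row per citation, carrying its search-cell assignment.
#' Duplicate citation ids within one cell are de-duplicated (first
#' occurrence wins, with a warning); the cell's year pair -- not the
#' record's own year -- is authoritative downstream.
#'
#' @param manifest A manifest tibble from [read_manifest()] or
#'   [cells_from_filenames()].
#' @return A tibble of citations with cell columns attached.
#' @export
read_corpus <- function(manifest) {
  parts <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    reader <- if (grepl("\\.bib$", row$file_path)) read_bibtex else read_medline
    recs <- reader(row$file_path)
    attr(recs, "skipped") <- NULL
    recs$cell_id <- row$cell_id
    recs$disease_group <- row$disease_group
    recs$keyword_category <- row$keyword_category
    recs$start_year <- row$start_year
    recs$end_year <- row$end_year
    recs
  })
  corpus <- bind_rows(parts)
  dup <- duplicated(corpus[, c("cell_id", "citation_id")])
  if (any(dup)) {
    warn(sprintf("read_corpus(): %d duplicate citation(s) within a cell dropped", sum(dup)))
    corpus <- corpus[!dup, ]
  }
  corpus
}

empty_citations <- function(source_file) {
  tibble(citation_id = character(0), title = character(0),
         abstract = character(0), year = integer(0),
         source_file = character(0))
}

read_input_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readr::read_lines(x)
  } else if (length(x) == 1 && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}
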