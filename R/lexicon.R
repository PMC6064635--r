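#' Supported ontology namespace codes
#'
#' Integer switches identifying the nine ontology namespaces the tagger
#' understands: organisms (-2), environments (-27), diseases/phenotypes
#' (-26), tissues (-25), biological process (-21), molecular function (-22),
#' cellular component (-23), genes/proteins (0) and small molecules (-1).
#'
#' @return Named integer vector of valid namespace codes.
#' @export
ontology_namespaces <- function() {
  c(organisms = -2L, environments = -27L, diseases_phenotypes = -26L,
    tissues = -25L, biological_process = -21L, molecular_function = -22L,
    cellular_component = -23L, genes_proteins = 0L, small_molecules = -1L)
}

#' Load an ontology term lexicon
#'
#' Reads a lexicon TSV with columns `term_id`, `namespace_code`,
#' `canonical_name`, `synonyms` (pipe-separated; `#` lines are comments) and
#' builds a surface-form index used by the tagger. Surface forms (canonical
#' name plus synonyms) are case-folded and whitespace-normalised; the same
#' surface form may be shared by several terms -- the ambiguity is resolved
#' at tagging time by crediting every owning term.
#'
#' @param x Path to a lexicon TSV, or a data frame with the same columns.
#' @param namespaces `"all"` (default) or an integer vector of namespace
#'   codes from [ontology_namespaces()]; only matching rows are loaded.
#' @return A `term_lexicon` object: list with `terms` (tibble) and `index`
#'   (tibble of `surface`, `term_id`).
#' @export
read_lexicon <- function(x, namespaces = "all") {
  if (is.data.frame(x)) {
    raw <- as_tibble(x)
  } else {
    raw <- readr::read_tsv(x, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(
                             term_id = readr::col_character(),
                             namespace_code = readr::col_integer(),
                             canonical_name = readr::col_character(),
                             synonyms = readr::col_character()))
  }
  need <- c("term_id", "namespace_code", "canonical_name", "synonyms")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("lexicon lacks column(s): ", paste(missing, collapse = ", ")))
  }
  valid <- unname(ontology_namespaces())
  bad_ns <- setdiff(unique(raw$namespace_code), valid)
  if (length(bad_ns)) {
    abort(sprintf("lexicon contains unknown namespace code(s) %s; valid codes: %s",
                  paste(bad_ns, collapse = ", "), paste(valid, collapse = ", ")))
  }
  if (!identical(namespaces, "all")) {
    namespaces <- as.integer(namespaces)
    unknown <- setdiff(namespaces, valid)
    if (length(unknown)) {
      abort(sprintf("unknown namespace code(s) in selection: %s; valid codes: %s",
                    paste(unknown, collapse = ", "), paste(valid, collapse = ", ")))
    }
    raw <- raw[raw$namespace_code %in% namespaces, ]
  }
  if (anyDuplicated(raw$term_id)) {
    abort(paste0("duplicate term_id(s) in lexicon: ",
                 paste(unique(raw$term_id[duplicated(raw$term_id)]), collapse = ", ")))
  }
  if (any(!nzchar(trimws(raw$canonical_name)))) {
    abort("lexicon rows with empty canonical_name")
  }

  terms <- raw %>%
    mutate(
      synonyms = purrr::map(.data$synonyms, function(s) {
        if (is.na(s) || !nzchar(trimws(s))) character(0)
        else trimws(strsplit(s, "|", fixed = TRUE)[[1]])
      })
    ) %>%
    select("term_id", "namespace_code", "canonical_name", "synonyms")

  index <- terms %>%
    mutate(surface = purrr::map2(.data$canonical_name, .data$synonyms,
                                 function(cn, syn) unique(normalize_surface(c(cn, syn))))) %>%
    select("term_id", "surface") %>%
    tidyr::unnest("surface") %>%
    filter(nzchar(.data$surface)) %>%
    distinct(.data$surface, .data$term_id)

  orphan <- setdiff(terms$term_id, index$term_id)
  if (length(orphan)) {
    abort(paste0("term(s) with no usable surface form: ", paste(orphan, collapse = ", ")))
  }

  structure(list(terms = terms, index = index), class = "term_lexicon")
}

#' Normalise a surface form
#'
#' The projection applied to every lexicon surface form and to matched text
#' before index lookup: Unicode NFC, case folding, and whitespace squashed to
#' single spaces. Applying it twice gives the same result as applying it
#' once.
#'
#' @param x Character vector.
#' @return Normalised character vector.
#' @export
normalize_surface <- function(x) {
  stringr::str_squish(stringi::stri_trans_tolower(stringi::stri_trans_nfc(x)))
}

#' @export
print.term_lexicon <- function(x, ...) {
  cat(sprintf("<term_lexicon> %d terms, %d surface forms, namespaces: %s\n",
              nrow(x$terms), nrow(x$index),
              paste(sort(unique(x$terms$namespace_code)), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.term_lexicon <- function(x, ...) {
  x$terms %>%
    mutate(synonyms = purrr::map_chr(.data$synonyms, paste, collapse = "|"))
}

#' Write a lexicon back to TSV
#'
#' @param lexicon A `term_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  readr::write_tsv(tidy(lexicon), path)
  invisible(path)
}

#' Resolve a term-subset file against a lexicon
#'
#' Reads a plain-text file with one entry per line (blank and `#` lines
#' ignored); each entry is a `term_id` or a canonical name (resolved
#' case-insensitively). Used to restrict the analysis to a curated subset,
#' such as a manually selected list of nutrition-related terms.
#'
#' @param x Path to the subset file, or a character vector of entries.
#' @param lexicon A `term_lexicon`.
#' @return Character vector of resolved term ids, with attribute
#'   `unresolved` (the entries that did not resolve). Errors if the file is
#'   empty or more than half the entries fail to resolve.
#' @export
read_term_subset <- function(x, lexicon) {
  lines <- read_input_lines(x)
  entries <- trimws(lines)
  entries <- entries[nzchar(entries) & !startsWith(entries, "#")]
  if (!length(entries)) abort("term-subset file is empty")

  by_name <- setNames(lexicon$terms$term_id,
                      normalize_surface(lexicon$terms$canonical_name))
  ids <- ifelse(entries %in% lexicon$terms$term_id,
                entries,
                unname(by_name[normalize_surface(entries)]))
  unresolved <- entries[is.na(ids)]
  if (length(unresolved) > length(entries) / 2) {
    abort(sprintf(
      "%d of %d subset entries did not resolve - is this the right lexicon?",
      length(unresolved), length(entries)))
  }
  if (length(unresolved)) {
    warn(sprintf("%d of %d subset entries did not resolve", length(unresolved),
                 length(entries)))
  }
  out <- unique(ids[!is.na(ids)])
  attr(out, "unresolved") <- unresolved
  out
}

#' A small bundled nutrition-flavoured lexicon
#'
#' Builds a ~40-term lexicon of nutrition and gastrointestinal-disease
#' vocabulary (wheat, gliadin, fibre, lactose, butyrate, short-chain fatty
#' acids, omega-3 fatty acids, vitamin D, obesity, growth, ...), with
#' synonyms including British/American spelling variants listed explicitly.
#' Used throughout the examples and as the default vocabulary of the
#' synthetic-corpus generator.
#'
#' @return A `term_lexicon`.
#' @export
toy_lexicon <- function() {
  rows <- list(
    c("NUTR:0001", -1, "wheat", "triticum"),
    c("NUTR:0002", -1, "gliadin", ""),
    c("NUTR:0003", -1, "gluten", ""),
    c("NUTR:0004", -1, "rye", "secale"),
    c("NUTR:0005", -1, "barley", "hordeum"),
    c("NUTR:0006", -1, "oats", "oat"),
    c("NUTR:0007", -1, "fibre", "fiber|dietary fibre|dietary fiber"),
    c("NUTR:0008", -1, "lactose", "milk sugar"),
    c("NUTR:0009", -1, "butyrate", "butyric acid"),
    c("NUTR:0010", -1, "short-chain fatty acids", "scfa|scfas|short chain fatty acids"),
    c("NUTR:0011", -1, "fatty acids", ""),
    c("NUTR:0012", -1, "omega-3 fatty acids", "omega-3|n-3 fatty acids"),
    c("NUTR:0013", -1, "n-6 fatty acids", "omega-6 fatty acids|omega-6"),
    c("NUTR:0014", -1, "vitamin d", "cholecalciferol|calciferol"),
    c("NUTR:0015", -1, "vitamin b12", "cobalamin"),
    c("NUTR:0016", -1, "folate", "folic acid"),
    c("NUTR:0017", -1, "iron", ""),
    c("NUTR:0018", -1, "zinc", ""),
    c("NUTR:0019", -1, "calcium", ""),
    c("NUTR:0020", -1, "curcumin", "turmeric extract"),
    c("NUTR:0021", -1, "glucose", "dextrose"),
    c("NUTR:0022", -1, "fructose", ""),
    c("NUTR:0023", -1, "sucrose", "table sugar"),
    c("NUTR:0024", -1, "starch", ""),
    c("NUTR:0025", -1, "casein", ""),
    c("NUTR:0026", -1, "whey", ""),
    c("NUTR:0027", -1, "polyphenols", "polyphenol"),
    c("NUTR:0028", -1, "probiotics", "probiotic"),
    c("NUTR:0029", -1, "prebiotics", "prebiotic"),
    c("NUTR:0030", -1, "fodmap", "fodmaps"),
    c("PHEN:0001", -26, "obesity", "obese"),
    c("PHEN:0002", -26, "growth", "growth retardation"),
    c("PHEN:0003", -26, "malnutrition", "undernutrition"),
    c("PHEN:0004", -26, "wheat allergy", ""),
    c("PHEN:0005", -26, "anaemia", "anemia"),
    c("PHEN:0006", -26, "diarrhoea", "diarrhea"),
    c("PROC:0001", -21, "fermentation", ""),
    c("PROC:0002", -21, "inflammation", "inflammatory response"),
    c("ORG:0001", -2, "bifidobacterium", "bifidobacteria"),
    c("ORG:0002", -2, "lactobacillus", "lactobacilli")
  )
  df <- tibble(
    term_id = purrr::map_chr(rows, 1),
    namespace_code = as.integer(purrr::map_chr(rows, 2)),
    canonical_name = purrr::map_chr(rows, 3),
    synonyms = purrr::map_chr(rows, 4)
  )
  read_lexicon(df)
}
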