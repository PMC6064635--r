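#' Configuration for the synthetic-corpus generator
#'
#' Describes a hermetic test corpus over the same disease-group x
#' keyword-category x year-pair grid as a real literature search. Each term
#' is planted in each document independently with probability
#' `p = plogis(baseline_logit + group_effect + time_slope * pair_index)`,
#' where `pair_index` is the 0-based index of the cell's year pair. An
#' anchor term with `p = 1` in every document makes the number of annotated
#' documents per cell deterministic, so normalisation denominators are exact
#' in expected-value tests.
#'
#' @param lexicon A `term_lexicon`; defaults to [toy_lexicon()].
#' @param groups,categories,first_year,last_year The search grid (defaults:
#'   four disease groups, three nutritional keyword categories, 1991-2016).
#' @param docs_per_cell Documents generated per cell (default 20, giving
#'   4 x 3 x 13 x 20 = 3120 documents on the default grid).
#' @param baseline_logit Scalar or per-term named vector of baseline logits.
#' @param group_effects Optional tibble with columns `term_id`, `group`,
#'   `effect` (logit shift in that group).
#' @param time_slopes Scalar or per-term named vector: logit change per year
#'   pair.
#' @param anchor_term Term id planted with probability 1 (default: the
#'   lexicon's first term). `NULL` disables the anchor.
#' @param filler_vocabulary Words used as non-term text; must be disjoint,
#'   as whole tokens, from every surface-form token of the lexicon.
#' @param tokens_per_doc Number of filler tokens per abstract.
#' @param seed Integer seed; documents and all randomness are fully
#'   determined by it.
#' @return A `corpus_config` object.
#' @export
corpus_config <- function(lexicon = toy_lexicon(),
                          groups = c("CCD", "CD", "IBS", "UC"),
                          categories = c("Diet", "Food", "Nutrition"),
                          first_year = 1991, last_year = 2016,
                          docs_per_cell = 20,
                          baseline_logit = -1.5,
                          group_effects = NULL,
                          time_slopes = 0,
                          anchor_term = lexicon$terms$term_id[1],
                          filler_vocabulary = default_filler(),
                          tokens_per_doc = 25,
                          seed = 20180726L) {
  stopifnot(inherits(lexicon, "term_lexicon"), docs_per_cell >= 1)
  term_ids <- lexicon$terms$term_id

  expand_per_term <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) {
      return(setNames(rep(as.numeric(x), length(term_ids)), term_ids))
    }
    out <- setNames(rep(0, length(term_ids)), term_ids)
    unknown <- setdiff(names(x), term_ids)
    if (length(unknown)) {
      abort(paste0(what, " names not in lexicon: ", paste(unknown, collapse = ", ")))
    }
    out[names(x)] <- as.numeric(x)
    out
  }
  beta0 <- expand_per_term(baseline_logit, "baseline_logit")
  delta <- expand_per_term(time_slopes, "time_slopes")

  gamma <- matrix(0, nrow = length(term_ids), ncol = length(groups),
                  dimnames = list(term_ids, groups))
  if (!is.null(group_effects)) {
    ge <- as_tibble(group_effects)
    stopifnot(all(c("term_id", "group", "effect") %in% names(ge)))
    bad <- setdiff(ge$term_id, term_ids)
    if (length(bad)) abort(paste0("group_effects term(s) not in lexicon: ",
                                  paste(bad, collapse = ", ")))
    bad_g <- setdiff(ge$group, groups)
    if (length(bad_g)) abort(paste0("group_effects group(s) not in grid: ",
                                    paste(bad_g, collapse = ", ")))
    gamma[cbind(ge$term_id, ge$group)] <- ge$effect
  }

  if (!is.null(anchor_term) && !anchor_term %in% term_ids) {
    abort(sprintf("anchor_term '%s' is not in the lexicon", anchor_term))
  }

  # filler words must not be able to assemble any surface form
  form_tokens <- unique(unlist(strsplit(lexicon$index$surface, "[^[:alnum:]]+")))
  form_tokens <- form_tokens[nzchar(form_tokens)]
  clash <- intersect(normalize_surface(filler_vocabulary), form_tokens)
  if (length(clash)) {
    abort(paste0("filler vocabulary collides with surface-form token(s): ",
                 paste(clash, collapse = ", ")))
  }

  cells <- enumerate_cells(groups, categories, first_year, last_year)
  structure(list(
    lexicon = lexicon, groups = groups, categories = categories,
    first_year = first_year, last_year = last_year,
    docs_per_cell = as.integer(docs_per_cell),
    beta0 = beta0, gamma = gamma, delta = delta,
    anchor_term = anchor_term,
    filler_vocabulary = filler_vocabulary,
    tokens_per_doc = as.integer(tokens_per_doc),
    seed = as.integer(seed), cells = cells
  ), class = "corpus_config")
}

#' @export
print.corpus_config <- function(x, ...) {
  cat(sprintf("<corpus_config> %d groups x %d categories x %d year pairs, %d docs/cell (%d documents), seed %d\n",
              length(x$groups), length(x$categories),
              max(x$cells$pair_index) + 1L, x$docs_per_cell,
              nrow(x$cells) * x$docs_per_cell, x$seed))
  invisible(x)
}

#' Default filler vocabulary
#'
#' Generic methods-section words guaranteed not to overlap, as whole
#' tokens, with the surface forms of [toy_lexicon()].
#'
#' @return Character vector of words.
#' @export
default_filler <- function() {
  c("study", "patients", "clinical", "results", "analysis", "methods",
    "cohort", "trial", "randomized", "outcomes", "baseline", "symptoms",
    "treatment", "therapy", "remission", "assessment", "evaluation",
    "review", "report", "evidence", "findings", "conclusion", "background",
    "objective", "measured", "observed", "increased", "decreased",
    "compared", "versus", "placebo", "protocol", "duration", "severity",
    "score", "population", "recruited", "participants", "intervention",
    "screening")
}

#' True presence probabilities of a generator configuration
#'
#' @param config A `corpus_config`.
#' @return Tibble with one row per (term, group, pair_index): the planted
#'   presence probability `p`.
#' @export
true_probabilities <- function(config) {
  term_ids <- config$lexicon$terms$term_id
  taus <- sort(unique(config$cells$pair_index))
  grid <- tidyr::expand_grid(term_id = term_ids, group = config$groups,
                             pair_index = taus)
  p <- plogis(config$beta0[grid$term_id] +
                config$gamma[cbind(grid$term_id, grid$group)] +
                config$delta[grid$term_id] * grid$pair_index)
  if (!is.null(config$anchor_term)) {
    p[grid$term_id == config$anchor_term] <- 1
  }
  grid$p <- unname(p)
  grid
}

#' Expected normalised frequency table of a configuration
#'
#' Under the generator model the expected presence count of a term in a
#' cell is `docs_per_cell * p`; with the anchor term guaranteeing that every
#' document is annotated, the expected normalised frequency equals `p`
#' exactly.
#'
#' @param config A `corpus_config`.
#' @return Tibble with one row per (cell, term): `p`, `expected_count`,
#'   `expected_normalized`.
#' @export
expected_table <- function(config) {
  probs <- true_probabilities(config)
  config$cells %>%
    left_join(probs, by = c("disease_group" = "group", "pair_index"),
              relationship = "many-to-many") %>%
    mutate(expected_count = config$docs_per_cell * .data$p,
           expected_normalized = .data$p) %>%
    select("cell_id", "term_id", "p", "expected_count", "expected_normalized")
}

# Phase-1 randomness: Bernoulli presence draws for the whole corpus, fully
# determined by config$seed and independent of the text-layout randomness.
draw_presence <- function(config) {
  term_ids <- config$lexicon$terms$term_id
  probs <- true_probabilities(config)
  key <- paste(probs$term_id, probs$group, probs$pair_index)
  p_of <- setNames(probs$p, key)
  cells <- config$cells
  with_seed(config$seed, {
    lapply(seq_len(nrow(cells)), function(i) {
      p <- unname(p_of[paste(term_ids, cells$disease_group[i], cells$pair_index[i])])
      m <- matrix(runif(config$docs_per_cell * length(term_ids)),
                  nrow = config$docs_per_cell)
      present <- sweep(m, 2, p, "<")
      colnames(present) <- term_ids
      present
    })
  })
}

#' Simulate presence counts without generating text
#'
#' Draws the same Bernoulli presence indicators as [generate_corpus()] (the
#' two share the seeded presence stream, so the counts agree exactly for a
#' given configuration) and tabulates them directly into a `term_table`,
#' skipping text generation and tagging. Intended for replicate simulation
#' studies where only the count table matters.
#'
#' @param config A `corpus_config`.
#' @return A `term_table` with counts, per-cell document totals, and terms
#'   restricted to those observed at least once (as tagging would produce).
#' @export
simulate_counts <- function(config) {
  presence <- draw_presence(config)
  cells <- config$cells
  counts <- t(vapply(presence, colSums, numeric(ncol(presence[[1]]))))
  storage.mode(counts) <- "integer"
  rownames(counts) <- cells$cell_id
  annotated <- vapply(presence, function(m) sum(rowSums(m) > 0), numeric(1))
  cells$n_docs <- config$docs_per_cell
  cells$annotated_docs <- as.integer(annotated)
  observed <- colnames(counts)[colSums(counts) > 0]
  new_term_table(select(cells, -"pair_index"),
                 counts[, sort(observed), drop = FALSE])
}

#' Generate a synthetic literature corpus
#'
#' Writes one MEDLINE (tagged) file per search cell, a manifest TSV mapping
#' files to cells, and returns the planted ground truth. Every planted term
#' appears in the document text as one uniformly chosen surface form
#' inserted between filler tokens, so an exact tagger must recover the
#' planted presence sets perfectly. Runs are byte-identical for a fixed
#' configuration.
#'
#' @param config A `corpus_config`.
#' @param dir Output directory (created if needed).
#' @return List with `manifest` (path), `files`, `truth` (tibble
#'   `citation_id`, `term_id` of planted terms), `probabilities`
#'   (tibble from [true_probabilities()]), and `config`.
#' @export
generate_corpus <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  presence <- draw_presence(config)
  cells <- config$cells
  lex <- config$lexicon
  forms_of <- setNames(
    purrr::map2(lex$terms$canonical_name, lex$terms$synonyms, c),
    lex$terms$term_id)

  pmid_next <- 100001L
  files <- character(nrow(cells))
  truth <- vector("list", nrow(cells))

  text_seed <- (config$seed + 1L) %% .Machine$integer.max
  with_seed(text_seed, {
    for (i in seq_len(nrow(cells))) {
      m <- presence[[i]]
      n_docs <- nrow(m)
      ids <- as.character(seq(pmid_next, length.out = n_docs))
      pmid_next <- pmid_next + n_docs
      abstracts <- character(n_docs)
      planted <- vector("list", n_docs)
      for (j in seq_len(n_docs)) {
        terms_j <- colnames(m)[m[j, ]]
        planted[[j]] <- terms_j
        # each surface goes into its own gap between filler tokens, so two
        # planted surfaces can never sit adjacent and merge into a longer
        # lexicon form
        n_fill <- max(config$tokens_per_doc, length(terms_j))
        tokens <- sample(config$filler_vocabulary, n_fill, replace = TRUE)
        if (length(terms_j)) {
          gaps <- sort(sample.int(n_fill + 1L, length(terms_j)) - 1L,
                       decreasing = TRUE)
          surfs <- vapply(terms_j, function(tid) {
            f <- forms_of[[tid]]
            f[sample.int(length(f), 1)]
          }, character(1))
          for (k in seq_along(gaps)) {
            tokens <- append(tokens, surfs[length(gaps) - k + 1L],
                             after = gaps[k])
          }
        }
        abstracts[j] <- paste0(paste(tokens, collapse = " "), ".")
      }
      recs <- tibble(citation_id = ids,
                     title = paste("Synthetic citation", ids),
                     abstract = abstracts,
                     year = cells$start_year[i])
      fname <- sprintf("%s_%s_%d-%d.txt", cells$disease_group[i],
                       cells$keyword_category[i], cells$start_year[i],
                       cells$end_year[i])
      files[i] <- file.path(dir, fname)
      write_medline(recs, files[i])
      truth[[i]] <- tibble(citation_id = rep(ids, lengths(planted)),
                           term_id = unlist(planted) %||% character(0))
    }
  })

  manifest <- cells %>%
    mutate(file_path = basename(files)) %>%
    select("file_path", "disease_group", "keyword_category",
           "start_year", "end_year")
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path)

  list(manifest = manifest_path, files = files,
       truth = bind_rows(truth), probabilities = true_probabilities(config),
       config = config)
}

#' Write generator ground truth as JSON
#'
#' @param generated Result of [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(generated, path) {
  jsonlite::write_json(
    list(doc_terms = generated$truth, probabilities = generated$probabilities),
    path, dataframe = "columns", digits = NA)
  invisible(path)
}
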