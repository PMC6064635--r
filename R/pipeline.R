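#' Run the end-to-end annotation and analysis workflow
#'
#' Orchestrates the full pipeline: parse the citation files of a manifest,
#' tag abstracts against a lexicon, build the cell x term presence table,
#' remove rare terms, optionally restrict to a curated term subset,
#' normalise by annotated documents, and run the multivariate and
#' differential statistics (NMDS on Bray-Curtis, PERMANOVA by disease group
#' and by year pair, per-group LCBD time series, per-interval
#' between-disease scans, per-group temporal scans, top-k term rankings).
#' All randomness is governed by `seed`; a rerun with identical inputs
#' produces identical numbers.
#'
#' @param manifest Path to a manifest TSV (see [read_manifest()]), a
#'   manifest tibble, or `NULL` when `input_dir` is given.
#' @param lexicon Path to a lexicon TSV or a `term_lexicon`.
#' @param input_dir Directory of citation files named
#'   `<group>_<category>_<start>-<end>.<ext>`; used when `manifest` is
#'   `NULL`.
#' @param onto_types `"all"` or integer namespace codes to load.
#' @param subset Optional term-subset file path or character vector of
#'   entries, resolved with [read_term_subset()].
#' @param min_total Rare-term threshold passed to [filter_rare()].
#' @param denominator_scope Passed to [normalize_documents()].
#' @param intervals Passed to [bin_intervals()].
#' @param alpha Significance threshold for the differential scans.
#' @param n_perm PERMANOVA permutations.
#' @param nmds_k,nmds_starts NMDS dimensionality and number of starts.
#' @param top_k Terms per group in the frequency ranking.
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, all tables are written as
#'   TSV plus a JSON run summary and a plain-text run log.
#' @param verbose Emit progress messages.
#' @return A `pipeline_result` list: `table` (the normalised `term_table`),
#'   `nmds`, `permanova_group`, `permanova_yearpair`, `lcbd`,
#'   `diff_by_group` (one scan per interval), `diff_by_time` (one scan per
#'   group), `significance` (per-group summary), `top_terms`, `log`.
#' @export
run_pipeline <- function(manifest = NULL, lexicon, input_dir = NULL,
                         onto_types = "all", subset = NULL, min_total = 5,
                         denominator_scope = c("cell", "group_yearpair"),
                         intervals = default_intervals(), alpha = 0.05,
                         n_perm = 999, nmds_k = 2, nmds_starts = 20,
                         top_k = 20, seed = 20180726L, out_dir = NULL,
                         verbose = TRUE) {
  denominator_scope <- match.arg(denominator_scope)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  say("ontotag pipeline (package version %s), seed %d",
      as.character(utils::packageVersion("ontotag")), as.integer(seed))

  man <- stage("manifest", {
    if (is.null(manifest)) {
      if (is.null(input_dir)) abort("either manifest or input_dir is required")
      paths <- list.files(input_dir, pattern = "\\.(bib|txt|med)$",
                          full.names = TRUE)
      cells_from_filenames(paths)
    } else if (is.character(manifest)) {
      read_manifest(manifest)
    } else {
      as_tibble(manifest)
    }
  })

  lex <- stage("lexicon", {
    if (inherits(lexicon, "term_lexicon")) {
      if (identical(onto_types, "all")) lexicon
      else read_lexicon(tidy(lexicon), namespaces = onto_types)
    } else {
      read_lexicon(lexicon, namespaces = onto_types)
    }
  })
  say("lexicon: %d terms, %d surface forms", nrow(lex$terms), nrow(lex$index))

  corpus <- stage("parse", read_corpus(man))
  say("parsed %d citations from %d files in %d cells",
      nrow(corpus), nrow(man), dplyr::n_distinct(corpus$cell_id))

  tags <- stage("tag", tag_corpus(corpus, build_matcher(lex)))
  say("annotated %d of %d documents (at least one term found)",
      annotated_count(tags), nrow(corpus))

  tbl <- stage("counts", build_counts(corpus, tags))
  say("count table: %d cells x %d terms", nrow(tbl$counts), ncol(tbl$counts))

  tbl <- stage("rare-filter", filter_rare(tbl, min_total = min_total))
  say("%d terms survive the rare-term filter (>= %d total hits)",
      ncol(tbl$counts), as.integer(min_total))

  if (!is.null(subset)) {
    ids <- stage("subset", read_term_subset(subset, lex))
    tbl <- stage("subset", select_terms(tbl, ids))
    say("restricted to %d subset terms", ncol(tbl$counts))
  }

  tbl <- stage("normalize", normalize_documents(tbl, scope = denominator_scope))
  tbl <- stage("intervals", bin_intervals(tbl, intervals))

  d_bc <- stage("distance", bray_curtis(tbl))
  ord <- stage("nmds", nmds(d_bc, k = nmds_k, n_starts = nmds_starts,
                            seed = seed))
  say("NMDS: stress = %.4g in %d dimensions", ord$stress, ord$k)

  pg <- stage("permanova", permanova(d_bc, tbl$cells$disease_group,
                                     n_perm = n_perm, seed = seed))
  say("PERMANOVA (disease group): R2 = %.3f, p = %.4g", pg$R2, pg$p)
  py <- stage("permanova", permanova(
    d_bc, paste0(tbl$cells$start_year, "-", tbl$cells$end_year),
    n_perm = n_perm, seed = seed))
  say("PERMANOVA (year pair): R2 = %.3f, p = %.4g", py$R2, py$p)

  lcbd_tab <- stage("lcbd", lcbd_series(tbl))

  groups <- unique(tbl$cells$disease_group)
  ivs <- unique(tbl$cells$interval)

  diff_by_group <- stage("diff-by-group", {
    res <- lapply(ivs, function(iv) {
      differential_scan(tbl, factor = "disease_group",
                        stratum = c(interval = iv), alpha = alpha)
    })
    setNames(res, ivs)
  })
  diff_by_time <- stage("diff-by-time", {
    res <- lapply(groups, function(gr) {
      differential_scan(tbl, factor = "time_interval",
                        stratum = c(disease_group = gr), alpha = alpha)
    })
    setNames(res, groups)
  })

  significance <- stage("significance", {
    bind_rows(lapply(groups, function(gr) {
      sel <- tbl$cells$disease_group == gr
      subset_size <- sum(colSums(tbl$counts[sel, , drop = FALSE]) > 0)
      summarize_significance(diff_by_time[[gr]], subset_size = subset_size,
                             label = gr, alpha = alpha)
    }))
  })
  for (i in seq_len(nrow(significance))) {
    say("temporally changing terms in %s: %d of %d (%.2f%%)",
        significance$group[i], significance$n_significant[i],
        significance$subset_size[i], significance$percentage[i])
  }

  tops <- stage("top-terms", {
    setNames(lapply(groups, function(gr) top_terms(tbl, gr, k = top_k)), groups)
  })

  result <- structure(list(
    table = tbl, nmds = ord, permanova_group = pg, permanova_yearpair = py,
    lcbd = lcbd_tab, diff_by_group = diff_by_group,
    diff_by_time = diff_by_time, significance = significance,
    top_terms = tops, n_documents = nrow(corpus),
    annotated_documents = annotated_count(tags), seed = as.integer(seed),
    log = log_lines
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    stage("write", write_pipeline_outputs(result, out_dir))
    say("outputs written to %s", out_dir)
    result$log <- log_lines
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d documents (%d annotated), %d cells x %d terms\n",
              x$n_documents, x$annotated_documents,
              nrow(x$table$counts), ncol(x$table$counts)))
  cat(sprintf("  PERMANOVA by disease group: R2 = %.3f, p = %.4g\n",
              x$permanova_group$R2, x$permanova_group$p))
  cat(sprintf("  PERMANOVA by year pair:     R2 = %.3f, p = %.4g\n",
              x$permanova_yearpair$R2, x$permanova_yearpair$p))
  cat(sprintf("  NMDS stress: %.4g\n", x$nmds$stress))
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- result$table
  write_term_table(tbl, file.path(out_dir, "counts.tsv"), what = "counts")
  write_term_table(tbl, file.path(out_dir, "normalized.tsv"), what = "normalized")
  readr::write_tsv(tidy(result$nmds), file.path(out_dir, "nmds.tsv"))
  readr::write_tsv(result$lcbd, file.path(out_dir, "lcbd.tsv"))
  readr::write_tsv(bind_rows(
    mutate(tidy(result$permanova_group), factor = "disease_group"),
    mutate(tidy(result$permanova_yearpair), factor = "year_pair")),
    file.path(out_dir, "permanova.tsv"))
  readr::write_tsv(result$significance, file.path(out_dir, "significance.tsv"))
  for (iv in names(result$diff_by_group)) {
    readr::write_tsv(flatten_scan(result$diff_by_group[[iv]]),
                     file.path(out_dir, paste0("diff_groups_", iv, ".tsv")))
  }
  for (gr in names(result$diff_by_time)) {
    readr::write_tsv(flatten_scan(result$diff_by_time[[gr]]),
                     file.path(out_dir, paste0("diff_time_", gr, ".tsv")))
  }
  for (gr in names(result$top_terms)) {
    readr::write_tsv(result$top_terms[[gr]],
                     file.path(out_dir, paste0("top_terms_", gr, ".tsv")))
  }
  jsonlite::write_json(list(
    n_documents = result$n_documents,
    annotated_documents = result$annotated_documents,
    n_cells = nrow(tbl$counts), n_terms = ncol(tbl$counts),
    permanova_group = glance(result$permanova_group),
    permanova_yearpair = glance(result$permanova_yearpair),
    nmds = glance(result$nmds), seed = result$seed
  ), file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
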