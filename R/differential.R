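#' Kruskal-Wallis rank test
#'
#' Rank-based comparison of a numeric response across `a >= 2` groups, with
#' midranks over the pooled values, the standard tie correction, and a
#' chi-square reference distribution on `a - 1` degrees of freedom (via
#' [stats::kruskal.test()]). The fully tied case (all observations equal) is
#' reported as `H = 0`, `p = 1`.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (each group non-empty; total n >= 3).
#' @return Tibble with columns `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (length(values) < 3) abort("kruskal_wallis(): need at least 3 observations")
  tab <- table(groups)
  if (length(tab) < 2) abort("kruskal_wallis(): need at least 2 groups")
  if (any(tab == 0)) abort("kruskal_wallis(): empty group")
  a <- length(tab)
  if (length(unique(values)) == 1) {
    return(tibble(H = 0, df = a - 1L, p = 1))
  }
  kt <- kruskal.test(values, factor(groups))
  tibble(H = unname(kt$statistic), df = as.integer(unname(kt$parameter)),
         p = kt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction: with the p-values sorted
#' ascending, `adj_(i) = min over j >= i of min(1, p_(j) * m / j)`, returned
#' in the original input order (via [stats::p.adjust()]). Inputs must lie in
#' \[0, 1\].
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("bh_adjust(): p-values must be in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Dunn's post hoc pairwise comparisons
#'
#' Rank-based pairwise z tests following a Kruskal-Wallis test: with
#' midranks over the pooled sample, for groups i and j,
#' `z = (meanrank_i - meanrank_j) / sqrt((N(N+1)/12 -
#' sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j))`, with two-sided p-values from
#' the standard normal, adjusted across the `a(a-1)/2` comparisons. When the
#' pooled sample is fully tied the variance term vanishes and every
#' comparison reports `z = 0`, `p = 1`.
#'
#' @inheritParams kruskal_wallis
#' @param adjust Multiplicity adjustment across the pairwise family
#'   (default `"BH"`; any [stats::p.adjust()] method).
#' @return Tibble with columns `group_a`, `group_b`, `z`, `p_raw`, `p_adj`.
#' @export
dunn <- function(values, groups, adjust = "BH") {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) abort("dunn(): need at least 2 groups")
  lev <- names(tab)
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  var_core <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))

  pairs <- utils::combn(lev, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(k) {
    gi <- pairs[1, k]; gj <- pairs[2, k]
    se2 <- var_core * (1 / tab[[gi]] + 1 / tab[[gj]])
    z <- if (se2 <= 0) 0 else (mean_rank[[gi]] - mean_rank[[gj]]) / sqrt(se2)
    tibble(group_a = gi, group_b = gj, z = z,
           p_raw = if (se2 <= 0) 1 else 2 * pnorm(-abs(z)))
  }) %>% bind_rows()
  out$p_adj <- p.adjust(out$p_raw, method = adjust)
  out
}

#' Per-term differential analysis of a frequency table
#'
#' Runs a Kruskal-Wallis test per term across the levels of one factor --
#' disease group, time interval or individual year pair -- with the
#' normalised values of all (category x year-pair) cells at a level serving
#' as that level's replicates. Benjamini-Hochberg correction is applied
#' across all terms tested in the scan (one family per scan); Dunn's
#' pairwise comparisons are computed for terms with `p_adj < alpha`. Terms
#' with zero variance across all replicates are skipped and reported in the
#' `skipped` attribute.
#'
#' @param table A normalised `term_table`; interval-labelled (see
#'   [bin_intervals()]) when `factor = "time_interval"`.
#' @param factor `"time_interval"` (default), `"disease_group"` or
#'   `"year_pair"` -- which factor's levels are compared.
#' @param stratum Optional named value fixing a level of the other factor,
#'   e.g. `c(disease_group = "CD")` or `c(interval = "1991-1998")`; only
#'   cells at that level enter the scan.
#' @param alpha Adjusted-significance threshold gating the Dunn step.
#' @return A tibble with one row per tested term: `term_id`, `H`, `df`,
#'   `p_raw`, `p_adj`, `means` (list column of per-level mean normalised
#'   frequency) and `pairwise` (list column, `NULL` unless `p_adj < alpha`).
#'   Attributes: `skipped` (zero-variance term ids), `factor`, `stratum`.
#' @export
differential_scan <- function(table, factor = c("time_interval", "disease_group", "year_pair"),
                              stratum = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "term_table"))
  factor <- match.arg(factor)
  if (is.null(table$normalized)) abort("normalize_documents() must run before differential_scan()")
  cells <- table$cells
  if (factor == "time_interval" && !"interval" %in% names(cells)) {
    abort("bin_intervals() must run before a time_interval scan")
  }

  keep <- rep(TRUE, nrow(cells))
  if (!is.null(stratum)) {
    stopifnot(!is.null(names(stratum)), length(stratum) == 1)
    col <- names(stratum)
    if (!col %in% names(cells)) abort(sprintf("unknown stratum column '%s'", col))
    keep <- cells[[col]] == stratum[[1]]
    if (!any(keep)) abort(sprintf("no cells with %s = '%s'", col, stratum[[1]]))
  }
  cells <- cells[keep, ]
  norm <- table$normalized[keep, , drop = FALSE]

  level <- switch(factor,
    time_interval = cells$interval,
    disease_group = cells$disease_group,
    year_pair = paste0(cells$start_year, "-", cells$end_year))
  tab <- base::table(level)
  if (length(tab) < 2) abort("differential_scan(): fewer than 2 factor levels after stratification")
  small <- names(tab)[tab < 2]
  if (length(small)) {
    abort(paste0("factor level(s) with fewer than 2 replicate cells: ",
                 paste(small, collapse = ", ")))
  }

  variances <- apply(norm, 2, function(v) stats::var(v))
  skipped <- colnames(norm)[variances == 0 | is.na(variances)]
  tested <- setdiff(colnames(norm), skipped)
  if (!length(tested)) abort("no term with nonzero variance to test")

  res <- purrr::map(tested, function(tid) {
    kw <- kruskal_wallis(norm[, tid], level)
    means <- tapply(norm[, tid], level, mean)
    tibble(term_id = tid, H = kw$H, df = kw$df, p_raw = kw$p,
           means = list(tibble(level = names(means),
                               mean_normalized = as.numeric(means))))
  }) %>% bind_rows()
  res$p_adj <- bh_adjust(res$p_raw)
  res$pairwise <- purrr::map(seq_len(nrow(res)), function(i) {
    if (res$p_adj[i] < alpha) dunn(norm[, res$term_id[i]], level) else NULL
  })
  res <- select(res, "term_id", "H", "df", "p_raw", "p_adj", "means", "pairwise")
  attr(res, "skipped") <- skipped
  attr(res, "factor") <- factor
  attr(res, "stratum") <- stratum
  res
}

#' Table-style significance summary
#'
#' Summarises a differential scan the way the per-disease significance table
#' does: the number of terms entered into the scan, the number with adjusted
#' p below 0.05, and their percentage. The percentage is truncated (not
#' rounded) to two decimals, matching values such as 99/372 = 26.61% and
#' 169/287 = 58.88%.
#'
#' @param results A [differential_scan()] result (or any tibble with a
#'   `p_adj` column).
#' @param subset_size Number of terms entered into the scan; defaults to
#'   `nrow(results)`.
#' @param label Optional group label carried into the output.
#' @param alpha Significance threshold on adjusted p.
#' @return Tibble with `group`, `subset_size`, `n_significant`, `percentage`.
#' @export
summarize_significance <- function(results, subset_size = nrow(results),
                                   label = NA_character_, alpha = 0.05) {
  if (subset_size == 0) abort("summarize_significance(): subset_size is zero")
  n_sig <- sum(results$p_adj < alpha, na.rm = TRUE)
  if (n_sig > subset_size) abort("more significant terms than subset_size")
  tibble(group = label, subset_size = as.integer(subset_size),
         n_significant = as.integer(n_sig),
         percentage = trunc(100 * n_sig / subset_size * 100 + 1e-9) / 100)
}

#' Significance stars
#'
#' `***`, `**`, `*` at the 0.001/0.01/0.05 levels, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
signif_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Flatten a differential scan for TSV export
#'
#' Widens the per-level means into `mean_<level>` columns and the pairwise
#' Dunn results into `<a>_vs_<b>` star columns, mirroring the layout of
#' per-interval supplementary-style tables.
#'
#' @param results A [differential_scan()] result.
#' @return A plain tibble suitable for [readr::write_tsv()].
#' @export
flatten_scan <- function(results) {
  means <- purrr::map2(results$term_id, results$means, function(tid, m) {
    tidyr::pivot_wider(mutate(m, term_id = tid),
                       names_from = "level", values_from = "mean_normalized",
                       names_prefix = "mean_")
  }) %>% bind_rows()
  out <- results %>%
    select("term_id", "H", "df", "p_raw", "p_adj") %>%
    left_join(means, by = "term_id")
  pw <- purrr::map2(results$term_id, results$pairwise, function(tid, d) {
    if (is.null(d)) return(NULL)
    d %>%
      mutate(term_id = tid,
             comparison = paste0(.data$group_a, "_vs_", .data$group_b),
             stars = signif_stars(.data$p_adj)) %>%
      select("term_id", "comparison", "stars") %>%
      tidyr::pivot_wider(names_from = "comparison", values_from = "stars")
  }) %>% bind_rows()
  if (nrow(pw)) out <- left_join(out, pw, by = "term_id")
  out
}
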