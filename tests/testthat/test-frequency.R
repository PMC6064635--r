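toy_table <- function() {
  cells <- enumerate_cells(c("CD", "UC"), c("Diet", "Food"), 1991, 1994)
  corpus <- tidyr::expand_grid(cells, doc = 1:3) %>%
    dplyr::mutate(citation_id = paste0(cell_id, "#", doc))
  # term A in 2 of 3 docs everywhere; term B only in CD cells, 1 doc each;
  # term C once in the whole corpus
  tags <- dplyr::bind_rows(
    corpus %>% dplyr::filter(doc <= 2) %>%
      dplyr::transmute(citation_id, term_id = "A"),
    corpus %>% dplyr::filter(doc == 1, disease_group == "CD") %>%
      dplyr::transmute(citation_id, term_id = "B"),
    corpus %>% dplyr::slice(1) %>%
      dplyr::transmute(citation_id, term_id = "C"))
  build_counts(corpus, tags, cells = cells)
}

test_that("presence counts tabulate per cell with annotated denominators", {
  tbl <- toy_table()
  expect_s3_class(tbl, "term_table")
  expect_equal(dim(tbl), c(8L, 3L))
  expect_true(all(tbl$counts[, "A"] == 2))
  cd_cells <- tbl$cells$disease_group == "CD"
  expect_true(all(tbl$counts[cd_cells, "B"] == 1))
  expect_true(all(tbl$counts[!cd_cells, "B"] == 0))
  expect_equal(sum(tbl$counts[, "C"]), 1)
  expect_true(all(tbl$cells$n_docs == 3))
  # docs annotated: doc1 and doc2 everywhere (A), doc3 nowhere
  expect_true(all(tbl$cells$annotated_docs == 2))
  expect_true(all(tbl$counts <= tbl$cells$annotated_docs))

  empty_corpus <- tibble::tibble(citation_id = character(0),
                                 cell_id = character(0),
                                 disease_group = character(0),
                                 keyword_category = character(0),
                                 start_year = integer(0),
                                 end_year = integer(0))
  expect_error(build_counts(empty_corpus,
                            tibble::tibble(citation_id = character(0),
                                           term_id = character(0))),
               "empty corpus")
})

test_that("column sums are invariant under cell reordering", {
  tbl <- toy_table()
  perm <- sample(nrow(tbl$counts))
  reord <- tbl
  reord$cells <- tbl$cells[perm, ]
  reord$counts <- tbl$counts[perm, , drop = FALSE]
  expect_equal(colSums(reord$counts), colSums(tbl$counts))
})

test_that("rare-term filter keeps terms at or above the threshold", {
  tbl <- toy_table()
  totals <- colSums(tbl$counts) # A = 16, B = 4, C = 1
  kept <- filter_rare(tbl, min_total = 5)
  expect_equal(colnames(kept$counts), "A")
  # boundary: a total exactly at the threshold survives
  at4 <- filter_rare(tbl, min_total = totals[["B"]])
  expect_setequal(colnames(at4$counts), c("A", "B"))
  expect_false("C" %in% colnames(at4$counts))
  # min_total = 0 is the identity
  expect_equal(filter_rare(tbl, 0)$counts, tbl$counts)
  expect_error(filter_rare(tbl, 1e6), "lower the threshold")
})

test_that("document-based normalisation divides by annotated documents", {
  tbl <- normalize_documents(toy_table())
  expect_equal(unname(tbl$normalized[, "A"]), rep(1, 8))
  expect_equal(max(tbl$normalized[, "C"]), 0.5)
  # scale equivariance: doubling counts and denominators changes nothing
  doubled <- toy_table()
  doubled$counts <- doubled$counts * 2L
  doubled$cells$annotated_docs <- doubled$cells$annotated_docs * 2L
  expect_equal(normalize_documents(doubled)$normalized, tbl$normalized)
})

test_that("group_yearpair scope pools category denominators", {
  tbl <- toy_table()
  pooled <- normalize_documents(tbl, scope = "group_yearpair")
  # two categories x 2 annotated docs pooled per (group, pair)
  expect_equal(unname(pooled$normalized[, "A"]), rep(2 / 4, 8))
})

test_that("zero-count cells normalise to zero rows; inconsistency errors", {
  tbl <- toy_table()
  tbl$cells$annotated_docs[1] <- 0L
  tbl$counts[1, ] <- 0L
  norm <- normalize_documents(tbl)
  expect_equal(unname(norm$normalized[1, ]), c(0, 0, 0))
  tbl$counts[1, "A"] <- 1L
  expect_error(normalize_documents(tbl), "zero annotated")
})

test_that("term subsetting keeps subset order and reports unknowns", {
  tbl <- toy_table()
  expect_equal(select_terms(tbl, colnames(tbl$counts))$counts, tbl$counts)
  two <- select_terms(tbl, c("C", "A"))
  expect_equal(colnames(two$counts), c("C", "A"))
  expect_warning(withx <- select_terms(tbl, c("A", "nope")), "1 subset id")
  expect_equal(attr(withx, "unmatched"), "nope")
  expect_error(select_terms(tbl, "nothing"), "none of the subset terms")
})

test_that("filter-then-subset is the pipeline order and commutes only within survivors", {
  tbl <- toy_table()
  a <- select_terms(filter_rare(tbl, 5), "A")
  b <- filter_rare(select_terms(tbl, "A"), 5)
  expect_equal(a$counts, b$counts)
  # C does not survive the filter, so subsetting to C afterwards must fail
  expect_error(select_terms(filter_rare(tbl, 5), "C"))
})

test_that("interval binning labels cells and rejects straddling pairs", {
  tbl <- toy_table()
  one <- bin_intervals(tbl, tibble::tibble(start = 1991, end = 1994))
  expect_equal(unique(one$cells$interval), "1991-1994")

  split2 <- bin_intervals(tbl, tibble::tibble(start = c(1991, 1993),
                                              end = c(1992, 1994)))
  expect_equal(sort(unique(split2$cells$interval)), c("1991-1992", "1993-1994"))

  expect_error(bin_intervals(tbl, tibble::tibble(start = c(1991, 1992),
                                                 end = c(1991, 1994))),
               "straddling")
  expect_error(bin_intervals(tbl, tibble::tibble(start = 1991, end = 1992)),
               "outside the intervals")

  # the default four study intervals place 1995-1996 in 1991-1998
  cells <- enumerate_cells("CD", "Diet", 1991, 2016)
  corpus <- dplyr::mutate(cells, citation_id = cell_id)
  tags <- tibble::tibble(citation_id = corpus$citation_id, term_id = "A")
  full <- bin_intervals(build_counts(corpus, tags, cells = cells))
  expect_equal(full$cells$interval[full$cells$start_year == 1995], "1991-1998")
  expect_equal(sort(unique(full$cells$interval)),
               c("1991-1998", "1999-2004", "2005-2010", "2011-2016"))
})

test_that("top_terms ranks by summed normalised frequency with id tiebreak", {
  cells <- enumerate_cells("CD", c("Diet", "Food"), 1991, 1992)
  corpus <- tidyr::expand_grid(cells, doc = 1:2) %>%
    dplyr::mutate(citation_id = paste0(cell_id, "#", doc))
  tags <- dplyr::bind_rows(
    tibble::tibble(citation_id = corpus$citation_id[c(1, 2, 3)], term_id = "A"),
    tibble::tibble(citation_id = corpus$citation_id[c(1, 3, 4)], term_id = "B"),
    tibble::tibble(citation_id = corpus$citation_id[1], term_id = "Z"),
    tibble::tibble(citation_id = corpus$citation_id[2], term_id = "Y"))
  tbl <- normalize_documents(build_counts(corpus, tags, cells = cells))
  tt <- top_terms(tbl, "CD", k = 10)
  expect_equal(tt$term_id[1:2], c("A", "B"))
  # Y and Z tie on frequency; lexicographic order breaks it
  expect_equal(tt$term_id[3:4], c("Y", "Z"))
  expect_equal(nrow(top_terms(tbl, "CD", k = 2)), 2)
  expect_error(top_terms(tbl, "XX"), "unknown disease group")
})

test_that("tables round-trip through TSV serialisation", {
  tbl <- normalize_documents(toy_table())
  dir <- withr::local_tempdir()
  path <- file.path(dir, "counts.tsv")
  write_term_table(tbl, path, what = "counts")
  back <- read_term_table(path, what = "counts")
  expect_equal(back$counts, tbl$counts)
  expect_equal(back$cells$annotated_docs, tbl$cells$annotated_docs)
})
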