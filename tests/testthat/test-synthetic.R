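test_that("generator configuration validates its inputs", {
  lex <- toy_lexicon()
  expect_error(corpus_config(lexicon = lex, filler_vocabulary = c("study", "wheat")),
               "collides")
  # a token of a multi-word surface form is also a collision
  expect_error(corpus_config(lexicon = lex, filler_vocabulary = c("study", "fatty")),
               "collides")
  expect_error(corpus_config(lexicon = lex, anchor_term = "NOPE"), "anchor_term")
  expect_error(corpus_config(lexicon = lex,
                             group_effects = tibble::tibble(
                               term_id = "NOPE", group = "CD", effect = 1)),
               "not in lexicon")
  cfg <- corpus_config(lexicon = lex, docs_per_cell = 3)
  expect_equal(nrow(cfg$cells), 156)
})

test_that("true probabilities follow the logistic model with the anchor forced", {
  cfg <- corpus_config(
    baseline_logit = -1,
    group_effects = tibble::tibble(term_id = "NUTR:0002", group = "CD",
                                   effect = 2),
    time_slopes = c("NUTR:0003" = 0.5))
  pr <- true_probabilities(cfg)
  # anchor term is certain everywhere
  expect_true(all(pr$p[pr$term_id == cfg$anchor_term] == 1))
  # group effect: logistic(1) in CD, logistic(-1) elsewhere
  t2 <- pr[pr$term_id == "NUTR:0002" & pr$pair_index == 0, ]
  expect_equal(t2$p[t2$group == "CD"], plogis(1))
  expect_equal(unique(t2$p[t2$group != "CD"]), plogis(-1))
  # positive slope: strictly increasing in the year-pair index
  t3 <- pr[pr$term_id == "NUTR:0003" & pr$group == "UC", ]
  expect_true(all(diff(t3$p[order(t3$pair_index)]) > 0))
  # all probabilities in (0, 1] with anchor the only 1
  expect_true(all(pr$p > 0 & pr$p <= 1))
})

test_that("boundary probabilities plant always or never", {
  lex <- toy_lexicon()
  b0 <- setNames(rep(-30, nrow(lex$terms)), lex$terms$term_id)
  b0["NUTR:0002"] <- 30
  cfg <- corpus_config(lexicon = lex, groups = "CD", categories = "Diet",
                       first_year = 2000, last_year = 2003,
                       docs_per_cell = 8, baseline_logit = b0, seed = 1L)
  dir <- withr::local_tempdir()
  gen <- generate_corpus(cfg, dir)
  truth_terms <- table(gen$truth$term_id)
  n_docs <- nrow(cfg$cells) * cfg$docs_per_cell
  # p ~ 1 terms in every document, p ~ 0 terms in none
  expect_equal(truth_terms[["NUTR:0002"]], n_docs)
  expect_equal(truth_terms[[cfg$anchor_term]], n_docs)
  expect_equal(length(truth_terms), 2)
  corpus <- read_corpus(read_manifest(gen$manifest))
  expect_true(all(grepl("gliadin", corpus$abstract)))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- corpus_config(docs_per_cell = 2, first_year = 1991, last_year = 1994,
                       groups = c("CD", "UC"), categories = "Diet", seed = 9L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_corpus(cfg, d1); g2 <- generate_corpus(cfg, d2)
  for (i in seq_along(g1$files)) {
    expect_identical(readLines(g1$files[i]), readLines(g2$files[i]))
  }
  expect_equal(g1$truth, g2$truth)
})

test_that("tagging a generated corpus recovers the planted truth exactly", {
  cfg <- corpus_config(docs_per_cell = 5, seed = 42L)
  dir <- withr::local_tempdir()
  gen <- generate_corpus(cfg, dir)
  corpus <- read_corpus(read_manifest(gen$manifest))
  expect_equal(nrow(corpus), 156 * 5)
  tags <- tag_corpus(corpus, build_matcher(cfg$lexicon))
  truth <- dplyr::distinct(gen$truth, citation_id, term_id)
  false_pos <- dplyr::anti_join(tags, truth, by = c("citation_id", "term_id"))
  false_neg <- dplyr::anti_join(truth, tags, by = c("citation_id", "term_id"))
  expect_equal(nrow(false_pos), 0)
  expect_equal(nrow(false_neg), 0)
})

test_that("simulate_counts shares the presence stream with generate_corpus", {
  cfg <- corpus_config(docs_per_cell = 4, groups = c("CD", "CCD"),
                       first_year = 1991, last_year = 1996, seed = 11L)
  dir <- withr::local_tempdir()
  gen <- generate_corpus(cfg, dir)
  corpus <- read_corpus(read_manifest(gen$manifest))
  tags <- tag_corpus(corpus, build_matcher(cfg$lexicon))
  tbl <- build_counts(corpus, tags, cells = cfg$cells)
  sim <- simulate_counts(cfg)
  expect_identical(tbl$counts, sim$counts)
  expect_equal(tbl$cells, sim$cells)
})

test_that("empirical presence frequencies converge to the expected table", {
  cfg <- corpus_config(docs_per_cell = 60, baseline_logit = -1,
                       time_slopes = 0.1, seed = 13L)
  tbl <- normalize_documents(simulate_counts(cfg))
  exp_tbl <- expected_table(cfg)
  obs <- tidy(tbl) %>%
    dplyr::inner_join(exp_tbl, by = c("cell_id", "term_id"))
  # anchor makes denominators exact
  expect_true(all(tbl$cells$annotated_docs == cfg$docs_per_cell))
  dev <- abs(obs$normalized - obs$expected_normalized)
  tol <- 3 * sqrt(obs$p * (1 - obs$p) / cfg$docs_per_cell)
  expect_gte(mean(dev <= tol), 0.95)
})

test_that("a planted group effect is detected by the pipeline PERMANOVA", {
  lex <- toy_lexicon()
  eff <- tidyr::expand_grid(term_id = lex$terms$term_id[2:11], group = "CD") %>%
    dplyr::mutate(effect = 2)
  hits <- 0L
  nrep <- 50
  for (r in seq_len(nrep)) {
    cfg <- corpus_config(lexicon = lex, docs_per_cell = 50,
                         group_effects = eff, seed = 10000 + r)
    tbl <- normalize_documents(simulate_counts(cfg))
    fit <- permanova(bray_curtis(tbl), tbl$cells$disease_group,
                     n_perm = 199, seed = r)
    if (fit$p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.9)
})

test_that("without a group effect the PERMANOVA detection rate stays near alpha", {
  hits <- 0L
  nrep <- 50
  for (r in seq_len(nrep)) {
    cfg <- corpus_config(docs_per_cell = 50, seed = 20000 + r)
    tbl <- normalize_documents(simulate_counts(cfg))
    fit <- permanova(bray_curtis(tbl), tbl$cells$disease_group,
                     n_perm = 199, seed = r)
    if (fit$p <= 0.05) hits <- hits + 1L
  }
  expect_lte(hits / nrep, 0.2)
})

test_that("shrinking cell variance over time yields falling LCBD profiles", {
  lex <- toy_lexicon()
  ids <- lex$terms$term_id
  b0 <- setNames(rep(-1.5, length(ids)), ids)
  dl <- setNames(rep(0, length(ids)), ids)
  drift <- ids[2:13]
  b0[drift] <- 0
  dl[drift[1:6]] <- 0.45
  dl[drift[7:12]] <- -0.45
  neg <- 0L
  nrep <- 30
  for (r in seq_len(nrep)) {
    cfg <- corpus_config(lexicon = lex, docs_per_cell = 30,
                         baseline_logit = b0, time_slopes = dl,
                         seed = 30000 + r)
    ser <- lcbd_series(normalize_documents(simulate_counts(cfg)))
    rho <- ser %>%
      dplyr::group_by(disease_group) %>%
      dplyr::summarise(rho = suppressWarnings(
        cor(lcbd, pair_index, method = "spearman")))
    if (all(rho$rho < 0)) neg <- neg + 1L
  }
  expect_gte(neg / nrep, 0.9)
})
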