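test_that("Hellinger transform gives square-rooted row proportions", {
  expect_equal(hellinger(matrix(c(1, 3), 1)),
               matrix(c(0.5, sqrt(3) / 2), 1))
  # degenerate one-hot row
  expect_equal(hellinger(matrix(c(7, 0, 0), 1)), matrix(c(1, 0, 0), 1))
  # zero rows stay zero
  expect_equal(hellinger(matrix(0, 2, 3)), matrix(0, 2, 3))
  # unit row sums of squares for nonzero rows
  set.seed(3)
  m <- matrix(rexp(40), 8, 5)
  expect_equal(unname(rowSums(hellinger(m)^2)), rep(1, 8))
  expect_error(hellinger(matrix(c(-1, 2), 1)), "negative")
})

test_that("Hellinger matches the standard implementation", {
  set.seed(4)
  m <- matrix(rpois(60, 5), 10, 6)
  expect_equal(hellinger(m),
               unclass(as.matrix(vegan::decostand(m, "hellinger"))),
               ignore_attr = TRUE)
})

test_that("Bray-Curtis follows the definition with its boundary cases", {
  expect_equal(as.vector(bray_curtis(rbind(c(1, 2, 3), c(3, 2, 1)))), 1 / 3)
  expect_equal(as.vector(bray_curtis(rbind(c(1, 2), c(1, 2)))), 0)
  expect_equal(as.vector(bray_curtis(rbind(c(1, 0), c(0, 2)))), 1)
  # all-zero pair: 0 by convention
  expect_equal(as.vector(bray_curtis(rbind(c(0, 0), c(0, 0)))), 0)
  expect_error(bray_curtis(rbind(c(-1, 0), c(0, 1))), "negative")
})

test_that("Bray-Curtis agrees with vegan and ignores all-zero columns", {
  set.seed(8)
  m <- matrix(runif(60), 10, 6)
  d <- bray_curtis(m)
  expect_equal(as.matrix(d), as.matrix(vegan::vegdist(m, "bray")),
               ignore_attr = TRUE)
  expect_equal(as.matrix(bray_curtis(cbind(m, 0))), as.matrix(d))
  # bounds and symmetry
  expect_true(all(as.vector(d) >= 0 & as.vector(d) <= 1))
})

test_that("LCBD reproduces hand-computed decompositions", {
  # two distinct rows split the variance evenly
  r2 <- lcbd(rbind(c(1, 0), c(0, 1)))
  expect_equal(r2$samples$lcbd, c(0.5, 0.5))
  # three-row worked example
  r3 <- lcbd(rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(r3$samples$lcbd, c(1 / 6, 2 / 3, 1 / 6))
  expect_equal(r3$bd_total, 2 / 3)
  # identical rows: degenerate, uniform
  rd <- lcbd(rbind(c(1, 2), c(1, 2), c(1, 2)))
  expect_true(rd$degenerate)
  expect_equal(rd$samples$lcbd, rep(1 / 3, 3))
})

test_that("LCBD sums to one and matches the pairwise-distance oracle", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    y <- hellinger(matrix(rexp(n * 5), n, 5))
    res <- lcbd(y)
    expect_equal(sum(res$samples$lcbd), 1)
    orc <- lcbd_pairwise_oracle(y)
    expect_equal(res$ss_total, orc$ss_total)
    expect_equal(res$samples$lcbd, unname(orc$lcbd))
  }
})

test_that("PERMANOVA reproduces the fully enumerable toy instance", {
  d <- dist(c(0, 1, 10, 11))
  fit <- permanova(d, c("A", "A", "B", "B"), exact = TRUE)
  expect_equal(fit$ss_total, 101)
  expect_equal(fit$ss_within, 1)
  expect_equal(fit$pseudo_F, 200)
  expect_equal(fit$R2, 100 / 101)
  expect_equal(fit$p, 2 / 6)
})

test_that("PERMANOVA matches adonis2 on the observed statistic", {
  set.seed(12)
  m <- matrix(runif(70), 10, 7)
  g <- rep(c("A", "B"), each = 5)
  d <- bray_curtis(m)
  ours <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1])
  expect_equal(ours$R2, ref$R2[1])
})

test_that("exact PERMANOVA p equals full enumeration over all label orders", {
  set.seed(13)
  for (i in 1:3) {
    n <- 7
    m <- matrix(rnorm(n * 3), n, 3)
    g <- c("A", "A", "A", "B", "B", "B", "B")
    d <- dist(m)
    fit <- permanova(d, g, exact = TRUE)
    expect_equal(fit$p, permanova_enum_oracle(d, g))
    expect_equal(fit$pseudo_F, permanova_f_oracle(d, g))
  }
})

test_that("PERMANOVA permutation stream is seeded and degenerate cases defined", {
  set.seed(14)
  m <- matrix(runif(50), 10, 5)
  g <- rep(c("A", "B"), 5)
  d <- bray_curtis(m)
  a <- permanova(d, g, n_perm = 199, seed = 7)
  b <- permanova(d, g, n_perm = 199, seed = 7)
  expect_identical(a$p, b$p)
  expect_true(a$p >= 1 / 200 && a$p <= 1)

  # all samples identical
  z <- permanova(dist(rep(0, 6)), rep(c("A", "B"), 3), n_perm = 9, seed = 1)
  expect_equal(z$R2, 0)
  expect_equal(z$p, 1)
  # zero within-group distances
  inf <- permanova(dist(c(0, 0, 5, 5)), c("A", "A", "B", "B"),
                   n_perm = 9, seed = 1)
  expect_true(is.infinite(inf$pseudo_F))

  expect_error(permanova(d, rep("A", 10)), "at least two groups")
})

test_that("PERMANOVA holds its size under a true null", {
  nrep <- 600
  rej <- 0L
  for (r in seq_len(nrep)) {
    set.seed(100000 + r)
    d <- dist(matrix(rnorm(60), 12, 5))
    fit <- permanova(d, rep(c("A", "B"), each = 6), n_perm = 199,
                     seed = 200000 + r)
    if (fit$p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / nrep, 0.03)
  expect_lte(rej / nrep, 0.07)
})

test_that("NMDS embeds Euclidean-realizable distances at near-zero stress", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 3
  D[1, 3] <- D[3, 1] <- 4
  D[2, 3] <- D[3, 2] <- 5
  ord <- nmds(as.dist(D), k = 2, n_starts = 5, seed = 1)
  expect_lte(ord$stress, 1e-6)
  # non-metric fit: only the rank order of the input is constrained
  expect_equal(order(as.vector(dist(ord$points))), c(1, 2, 3))
})

test_that("NMDS stress is non-increasing within a start and rigid-motion invariant", {
  set.seed(31)
  m <- matrix(runif(48), 8, 6)
  d <- bray_curtis(m)
  ord <- nmds(d, k = 2, n_starts = 4, seed = 2)
  expect_true(all(diff(ord$stress_trace) <= 1e-12))
  # stress recomputed after rotation + translation is unchanged
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- ord$points %*% R + 5
  stress_of <- function(X, dvec) {
    dc <- as.vector(dist(X))
    ordx <- order(dvec, dc)
    fit <- isoreg(seq_along(ordx), dc[ordx])$yf
    dhat <- numeric(length(dc)); dhat[ordx] <- fit
    sqrt(sum((dhat - dc)^2) / sum(dc^2))
  }
  dvec <- as.vector(d)
  expect_equal(stress_of(moved, dvec), stress_of(ord$points, dvec))
})

test_that("NMDS handles duplicate samples and rejects impossible dimensions", {
  m <- rbind(c(1, 2), c(1, 2), c(5, 1), c(2, 8))
  d <- dist(m)
  ord <- nmds(d, k = 2, n_starts = 3, seed = 3)
  expect_true(is.finite(ord$stress))
  expect_error(nmds(dist(m[1:2, ]), k = 2), "need more than")
})

test_that("NMDS stress is competitive with monoMDS on the same input", {
  set.seed(33)
  m <- matrix(runif(60), 10, 6)
  d <- bray_curtis(m)
  ord <- nmds(d, k = 2, n_starts = 10, seed = 4)
  ref <- vegan::monoMDS(d, k = 2, model = "global")
  expect_lte(ord$stress, ref$stress + 0.03)
})

test_that("per-group LCBD series requires normalisation and sums to 1 per group", {
  cfg <- corpus_config(docs_per_cell = 10, seed = 77L)
  tbl <- simulate_counts(cfg)
  expect_error(lcbd_series(tbl), "normalize_documents")
  ser <- lcbd_series(normalize_documents(tbl))
  sums <- ser %>% dplyr::group_by(disease_group) %>%
    dplyr::summarise(s = sum(lcbd))
  expect_equal(sums$s, rep(1, 4))
})
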