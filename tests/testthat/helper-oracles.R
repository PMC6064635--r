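# Independent oracles, implemented from the textbook definitions and kept
# separate from the package's code paths.

# Benjamini-Hochberg by its min-over-larger-ranks definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (pos in seq_len(m)) {
    j <- pos:m
    adj[o[pos]] <- min(1, min(p[o[j]] * m / j))
  }
  adj
}

# Kruskal-Wallis H with midranks and tie correction
kw_oracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  Rg <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) return(0)
  H / corr
}

# Dunn z for one pair of groups
dunn_z_oracle <- function(values, groups, a, b) {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  sigma2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1)))
  na <- sum(groups == a); nb <- sum(groups == b)
  (mean(r[groups == a]) - mean(r[groups == b])) /
    sqrt(sigma2 * (1 / na + 1 / nb))
}

# PERMANOVA pseudo-F from a distance matrix and labels, by the sums of
# squared distances definition
permanova_f_oracle <- function(D, labels) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_w <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- D2[idx, idx]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  a <- length(unique(labels))
  ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# exact permutation p by enumerating every one of the n! label orders
permanova_enum_oracle <- function(D, labels) {
  n <- length(labels)
  perms <- all_index_permutations(n)
  f_obs <- permanova_f_oracle(D, labels)
  fs <- apply(perms, 1, function(ix) permanova_f_oracle(D, labels[ix]))
  mean(fs >= f_obs - 1e-12)
}

all_index_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_index_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)), deparse.level = 0)
  }))
}

# total and per-row beta-diversity sums of squares from pairwise Euclidean
# distances (identity: sum_{i<k} d2_ik = n * ss_total)
lcbd_pairwise_oracle <- function(y) {
  n <- nrow(y)
  d2 <- as.matrix(dist(y))^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_i <- rowSums(sweep(y, 2, colMeans(y))^2)
  list(ss_total = ss_total, lcbd = ss_i / sum(ss_i))
}

make_cells_corpus <- function(lexicon = toy_lexicon(), docs_per_cell = 5,
                              seed = 42L, ...) {
  cfg <- corpus_config(lexicon = lexicon, docs_per_cell = docs_per_cell,
                       seed = seed, ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  gen <- generate_corpus(cfg, dir)
  list(cfg = cfg, gen = gen, dir = dir)
}

medline_fixture <- function() {
  c("PMID- 12345",
    "TI  - A title",
    "AB  - first",
    "      second",
    "DP  - 1999 Jan",
    "",
    "PMID- 777",
    "AB  - wheat and gliadin.",
    "DP  - 2001",
    "",
    "PMID- 888",
    "TI  - No abstract here",
    "DP  - 2003 Dec")
}
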