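#' Hellinger transformation
#'
#' Transforms a non-negative samples x terms matrix to square-rooted row
#' proportions: `y[i, j] = sqrt(x[i, j] / rowSums(x)[i])`. Rows summing to
#' zero map to zero rows. The transform makes Euclidean geometry appropriate
#' for composition-like counts and precedes the LCBD decomposition in the
#' pipeline.
#'
#' @param x Non-negative numeric matrix (or a normalised `term_table`, whose
#'   normalized matrix is used).
#' @return A numeric matrix of the same shape.
#' @export
hellinger <- function(x) {
  x <- as_stat_matrix(x)
  if (any(x < 0)) abort("hellinger(): negative entries are not allowed")
  rs <- rowSums(x)
  safe <- ifelse(rs == 0, 1, rs)
  sqrt(x / safe)
}

#' Bray-Curtis dissimilarity
#'
#' Computes the Bray-Curtis dissimilarity between all row pairs:
#' `d[i, j] = sum(|x[i, ] - x[j, ]|) / sum(x[i, ] + x[j, ])`, which is 0 for
#' identical compositions and 1 for disjoint ones. A pair of all-zero rows
#' has distance 0 by convention.
#'
#' @param x Non-negative numeric matrix (or a normalised `term_table`).
#' @return A `dist` object with the row names of `x` as labels.
#' @export
bray_curtis <- function(x) {
  x <- as_stat_matrix(x)
  if (any(x < 0)) abort("bray_curtis(): negative entries are not allowed")
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    for (j in (i + 1):n) {
      denom <- sum(xi + x[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(abs(xi - x[j, ])) / denom
    }
  }
  rownames(d) <- colnames(d) <- rownames(x)
  stats::as.dist(d)
}

#' Local contributions to beta diversity (LCBD)
#'
#' Decomposes the total variance of a (typically Hellinger-transformed)
#' samples x terms matrix into per-sample contributions: deviations from the
#' column means are squared and summed per row (`ss_i`), the total sum of
#' squares `ss_total` and total beta diversity `bd_total = ss_total/(n-1)`
#' are formed, and `lcbd[i] = ss_i / ss_total`. LCBD values are non-negative
#' and sum to 1; a small value means the sample sits close to the group
#' average. When all rows are identical (`ss_total = 0`) the result is
#' flagged degenerate and LCBD is uniform `1/n`.
#'
#' @param x Numeric matrix; apply [hellinger()] first to match the standard
#'   formulation.
#' @return An `lcbd_result` with elements `samples` (tibble of `sample`,
#'   `ss`, `lcbd`), `ss_total`, `bd_total`, `degenerate`.
#' @export
lcbd <- function(x) {
  x <- as_stat_matrix(x)
  n <- nrow(x)
  dev <- sweep(x, 2, colMeans(x))
  ss_i <- rowSums(dev^2)
  ss_total <- sum(ss_i)
  degenerate <- ss_total <= .Machine$double.eps * length(x)
  vals <- if (degenerate) rep(1 / n, n) else ss_i / ss_total
  labels <- rownames(x) %||% as.character(seq_len(n))
  structure(list(
    samples = tibble(sample = labels, ss = unname(ss_i), lcbd = unname(vals)),
    ss_total = ss_total,
    bd_total = if (n > 1) ss_total / (n - 1) else NA_real_,
    degenerate = degenerate
  ), class = "lcbd_result")
}

#' @export
print.lcbd_result <- function(x, ...) {
  cat(sprintf("<lcbd_result> %d samples, bd_total = %.6g%s\n",
              nrow(x$samples), x$bd_total,
              if (x$degenerate) " (degenerate: identical rows)" else ""))
  invisible(x)
}

#' @export
tidy.lcbd_result <- function(x, ...) x$samples

#' @export
glance.lcbd_result <- function(x, ...) {
  tibble(n = nrow(x$samples), ss_total = x$ss_total, bd_total = x$bd_total,
         degenerate = x$degenerate)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (the adonis-style partition): the total sum of squared inter-point
#' distances `SS_total = sum(d^2)/N` is split into within-group
#' (`SS_within = sum over groups of within-pair d^2 / n_g`) and
#' between-group parts, giving `pseudo_F = (SS_between/(a-1)) /
#' (SS_within/(N-a))` and `R2 = SS_between/SS_total`. The p-value permutes
#' group labels with a seeded generator and uses the add-one convention
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`, so p is never 0. With
#' `exact = TRUE` all distinct label arrangements are enumerated instead and
#' p is the exact fraction with `F >= F_obs` (the observed arrangement
#' included).
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param labels Group label per sample (at least two groups; no group may
#'   cover all samples).
#' @param n_perm Number of permutations (ignored when `exact = TRUE`).
#' @param seed Integer seed for the permutation stream.
#' @param exact Enumerate all distinct label arrangements (feasible for
#'   small n only; guarded at 100000 arrangements).
#' @return A `permanova_fit`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 20180726L,
                      exact = FALSE) {
  D <- as.matrix(d)
  n <- nrow(D)
  labels <- as.character(labels)
  stopifnot(length(labels) == n, n_perm >= 1)
  lev <- unique(labels)
  a <- length(lev)
  if (a < 2) abort("permanova(): need at least two groups")
  if (any(table(labels) == n)) abort("permanova(): a group covers all samples")

  D2 <- D^2
  ss_total <- sum(D2) / (2 * n)
  g <- match(labels, lev)

  f_stat <- function(g) {
    ss_w <- 0
    for (k in seq_len(a)) {
      idx <- which(g == k)
      if (length(idx) > 1) {
        ss_w <- ss_w + sum(D2[idx, idx]) / (2 * length(idx))
      }
    }
    ss_b <- ss_total - ss_w
    list(ss_w = ss_w, ss_b = ss_b,
         f = if (ss_w == 0) Inf else (ss_b / (a - 1)) / (ss_w / (n - a)))
  }

  obs <- f_stat(g)
  R2 <- if (ss_total == 0) 0 else obs$ss_b / ss_total

  if (ss_total == 0) {
    p <- 1
    n_used <- 0L
  } else if (exact) {
    perms <- unique_permutations(g)
    n_used <- nrow(perms)
    fs <- apply(perms, 1, function(gg) f_stat(gg)$f)
    p <- mean(fs >= obs$f - 1e-12)
  } else {
    n_used <- as.integer(n_perm)
    ge <- 0L
    with_seed(seed, {
      for (b in seq_len(n_used)) {
        if (f_stat(sample(g))$f >= obs$f - 1e-12) ge <- ge + 1L
      }
    })
    p <- (1 + ge) / (1 + n_used)
  }

  structure(list(
    pseudo_F = obs$f, R2 = R2, p = p,
    ss_between = obs$ss_b, ss_within = obs$ss_w, ss_total = ss_total,
    df_between = a - 1L, df_within = n - a,
    n_perm = n_used, seed = as.integer(seed), exact = exact,
    groups = lev, n = n
  ), class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf(
    "<permanova_fit> %d samples, %d groups: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%s)\n",
    x$n, length(x$groups), x$pseudo_F, x$R2, x$p,
    if (x$exact) sprintf("exact, %d arrangements", x$n_perm)
    else sprintf("%d permutations", x$n_perm)))
  invisible(x)
}

#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble(
    term = c("groups", "residual", "total"),
    df = c(x$df_between, x$df_within, x$n - 1L),
    sum_sq = c(x$ss_between, x$ss_within, x$ss_total),
    pseudo_F = c(x$pseudo_F, NA_real_, NA_real_),
    R2 = c(x$R2, 1 - x$R2, 1),
    p_value = c(x$p, NA_real_, NA_real_)
  )
}

#' @export
glance.permanova_fit <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p,
         n = x$n, n_groups = length(x$groups), n_perm = x$n_perm)
}

# all distinct permutations of an integer vector (multiset-aware)
unique_permutations <- function(g, limit = 100000L) {
  counts <- table(g)
  total <- factorial(length(g)) / prod(factorial(counts))
  if (total > limit) {
    abort(sprintf("exact enumeration would need %.0f arrangements (> %d)",
                  total, limit))
  }
  rec <- function(remaining) {
    vals <- sort(unique(remaining))
    if (length(remaining) == 1) return(matrix(remaining, 1, 1))
    out <- list()
    for (v in vals) {
      rest <- remaining[-match(v, remaining)]
      sub <- rec(rest)
      out[[length(out) + 1]] <- cbind(v, sub, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  rec(g)
}

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimising Kruskal
#' stress-1, `sqrt(sum((dhat - dconf)^2) / sum(dconf^2))`, where `dconf` are
#' configuration distances and `dhat` the monotone (isotonic, primary/weak
#' tie handling) regression of `dconf` on the rank order of the input
#' dissimilarities. Each start alternates an isotonic fit with a Guttman
#' majorisation step until the stress improvement drops below `tol`; the
#' first start is the classical-scaling (principal coordinates)
#' configuration and the remaining `n_starts - 1` are seeded random
#' configurations. The best configuration over all starts is returned,
#' centred at the origin.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix (n > k).
#' @param k Embedding dimension.
#' @param n_starts Number of starts (first = classical scaling).
#' @param seed Integer seed for the random starts.
#' @param max_iter Maximum iterations per start.
#' @param tol Stop when stress decreases by less than this.
#' @return An `nmds_ord` with `points` (n x k matrix), `stress`,
#'   `converged`, `k`, `n_starts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 20180726L,
                 max_iter = 200, tol = 1e-8) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n <= k) abort(sprintf("nmds(): need more than k = %d samples, got %d", k, n))
  labels <- rownames(D) %||% as.character(seq_len(n))
  dvec <- D[lower.tri(D)]

  run_start <- function(X) {
    X <- scale(X, scale = FALSE)
    stress_prev <- Inf
    converged <- FALSE
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      dc <- as.vector(dist(X))
      if (all(dc == 0)) break
      # primary ("weak") ties: within ties of the input dissimilarities the
      # fitted values are unconstrained, achieved by sub-ordering on dc
      ord <- order(dvec, dc)
      fit <- isoreg(seq_along(ord), dc[ord])$yf
      dhat <- numeric(length(dc))
      dhat[ord] <- fit
      stress <- sqrt(sum((dhat - dc)^2) / sum(dc^2))
      trace <- c(trace, stress)
      if (stress > stress_prev + 1e-15) { # guard: keep previous configuration
        X <- X_prev
        stress <- stress_prev
        trace[length(trace)] <- stress
        converged <- TRUE
        break
      }
      if (stress_prev - stress < tol) {
        stress_prev <- stress
        converged <- TRUE
        break
      }
      stress_prev <- stress
      X_prev <- X
      # Guttman transform with target distances dhat
      ratio <- ifelse(dc > 0, dhat / dc, 0)
      B <- matrix(0, n, n)
      B[lower.tri(B)] <- -ratio
      B <- B + t(B)
      diag(B) <- -rowSums(B)
      X <- (B %*% X) / n
      X <- scale(X, scale = FALSE)
    }
    list(X = X, stress = stress_prev, converged = converged, trace = trace)
  }

  starts <- list()
  cm <- suppressWarnings(cmdscale(stats::as.dist(D), k = k))
  if (ncol(cm) < k) cm <- cbind(cm, matrix(0, n, k - ncol(cm)))
  starts[[1]] <- cm
  if (n_starts > 1) {
    with_seed(seed, {
      for (s in 2:n_starts) {
        starts[[s]] <- matrix(stats::rnorm(n * k), n, k)
      }
    })
  }

  best <- NULL
  for (s in seq_along(starts)) {
    res <- run_start(starts[[s]])
    if (is.null(best) || res$stress < best$stress) best <- res
  }

  pts <- best$X
  rownames(pts) <- labels
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress,
                 converged = best$converged, k = k,
                 n_starts = n_starts, seed = as.integer(seed),
                 stress_trace = best$trace),
            class = "nmds_ord")
}

#' @export
print.nmds_ord <- function(x, ...) {
  cat(sprintf("<nmds_ord> %d points in %d dimensions, stress = %.6g%s\n",
              nrow(x$points), x$k, x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
tidy.nmds_ord <- function(x, ...) {
  as_tibble(x$points, rownames = "sample")
}

#' @export
glance.nmds_ord <- function(x, ...) {
  tibble(stress = x$stress, k = x$k, converged = x$converged,
         n = nrow(x$points), n_starts = x$n_starts)
}

#' LCBD time series per disease group
#'
#' For each disease group separately, Hellinger-transforms the group's
#' normalised cell rows and computes per-cell LCBD, yielding the temporal
#' profile of how far each search (category x year pair) sits from the
#' group's multivariate centroid. A falling profile indicates convergence of
#' the literature onto a common set of terms.
#'
#' @param table A normalised `term_table`.
#' @return A tibble with cell metadata, `pair_index` recomputed per group,
#'   and `lcbd`.
#' @export
lcbd_series <- function(table) {
  stopifnot(inherits(table, "term_table"))
  if (is.null(table$normalized)) abort("normalize_documents() must run before lcbd_series()")
  groups <- unique(table$cells$disease_group)
  parts <- lapply(groups, function(gr) {
    sel <- table$cells$disease_group == gr
    y <- hellinger(table$normalized[sel, , drop = FALSE])
    res <- lcbd(y)
    cells <- table$cells[sel, ]
    cells$lcbd <- res$samples$lcbd
    cells
  })
  bind_rows(parts) %>%
    group_by(.data$disease_group) %>%
    mutate(pair_index = match(.data$start_year, sort(unique(.data$start_year))) - 1L) %>%
    ungroup()
}

as_stat_matrix <- function(x) {
  if (inherits(x, "term_table")) {
    if (is.null(x$normalized)) abort("term_table has no normalized matrix; run normalize_documents()")
    return(x$normalized)
  }
  if (is.data.frame(x)) {
    rn <- if ("cell_id" %in% names(x)) x$cell_id else rownames(x)
    x <- as.matrix(x[, setdiff(names(x), "cell_id"), drop = FALSE])
    rownames(x) <- rn
  }
  stopifnot(is.matrix(x), is.numeric(x))
  x
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
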