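#' Spearman rank-correlation matrix
#'
#' Tie-corrected (average-rank) Spearman correlations between every pair of
#' the requested columns, with two-sided p-values from the asymptotic
#' t-approximation (`t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df).
#' Pairs involving a constant column are returned as `NA` with a warning.
#'
#' @param data data.frame.
#' @param columns character vector of numeric column names (default: all
#'   numeric columns).
#' @return list with matrices `rho`, `p`, `n` (pairwise complete n).
#' @export
spearman_matrix <- function(data, columns = NULL) {
  .cor_matrix(data, columns, method = "spearman")
}

#' Pearson correlation matrix
#'
#' Companion to [spearman_matrix()] for approximately normal outcomes
#' (e.g. intake and pre-meal fullness versus age), with t-based p-values.
#'
#' @inheritParams spearman_matrix
#' @return list with matrices `rho`, `p`, `n`.
#' @export
pearson_matrix <- function(data, columns = NULL) {
  .cor_matrix(data, columns, method = "pearson")
}

.cor_matrix <- function(data, columns, method) {
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  k <- length(columns)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  diag(rho) <- 1; diag(p) <- 0
  warned <- FALSE
  for (i in seq_len(k)) {
    n[i, i] <- sum(is.finite(data[[columns[i]]]))
    for (j in seq_len(k)[-seq_len(i)]) {
      x <- data[[columns[i]]]; y <- data[[columns[j]]]
      ok <- is.finite(x) & is.finite(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        warned <- TRUE
        next
      }
      r <- cor(x[ok], y[ok], method = method)
      nn <- sum(ok)
      pv <- if (abs(r) == 1) 0 else {
        tt <- r * sqrt((nn - 2) / (1 - r^2))
        2 * pt(-abs(tt), nn - 2)
      }
      rho[i, j] <- rho[j, i] <- r
      p[i, j] <- p[j, i] <- pv
    }
  }
  if (warned) warning("constant or too-short column pair(s): NA entries")
  list(rho = rho, p = p, n = n)
}

#' Mann-Whitney-Wilcoxon two-sample test
#'
#' The U statistic counts the pairs (a in A, b in B) with a > b, scoring
#' ties 1/2 — equivalently `U = R_A - nA(nA+1)/2` with R_A the rank sum of
#' group A in the pooled sample.  Complete separation with A below B gives
#' U = 0; identical groups give `U = nA*nB/2`.  p-values use the normal
#' approximation with tie correction (via [stats::wilcox.test()]); for
#' small pooled samples an exact permutation p-value over all group
#' assignments is available and serves as its own oracle.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact logical; enumerate all `choose(nx+ny, nx)` assignments
#'   (feasible for pooled n up to ~12).
#' @return list with `U`, `p`, `n` = c(nx, ny), `method`.
#' @export
mann_whitney <- function(x, y, exact = FALSE) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (exact) {
    pooled <- c(x, y)
    stat <- function(idx) {
      rr <- rank(pooled)
      sum(rr[idx]) - nx * (nx + 1) / 2
    }
    combos <- combn(nx + ny, nx)
    mid <- nx * ny / 2
    stats_all <- apply(combos, 2, stat)
    # two-sided permutation p: assignments at least as extreme (distance
    # from the null mean) as observed
    p <- mean(abs(stats_all - mid) >= abs(U - mid) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
    method <- "normal approximation, tie-corrected"
  }
  list(U = U, p = p, n = c(nx, ny), method = method)
}

#' Kruskal-Wallis k-group rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (via [stats::kruskal.test()]).  When every value is identical, H
#' is 0 by convention (with a warning).
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    warning("all values identical: H = 0 by convention")
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Benjamini-Hochberg adjustment within test families
#'
#' Step-up false-discovery-rate adjustment applied separately within each
#' family of tests (e.g. the 28 pairwise parameter correlations, the 8
#' parameter tests per behavioural metric, the 6 characteristic tests per
#' parameter).  Adjusted values are monotone in the raw p-values and capped
#' at 1.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param family optional vector of family labels (same length as `p`);
#'   `NULL` treats all p-values as one family.
#' @return numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  out <- numeric(length(p))
  for (f in unique(family)) {
    idx <- family == f
    out[idx] <- p.adjust(p[idx], method = "BH")
  }
  out
}

#' Two-sample Welch t-test summary
#'
#' Thin wrapper used for comparing normally distributed outcomes (intake,
#' fullness) across a binary characteristic such as sex.
#'
#' @param x,y numeric samples.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
two_sample_t <- function(x, y) {
  tt <- t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(diff(rev(tt$estimate))))
}
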