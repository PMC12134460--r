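#' @title Statistical kernel
#'
#' @description
#' The statistical routines used throughout the pipeline: Spearman rank
#' correlation (average ranks for ties, t-approximation p, optional exact p
#' for small untied samples), one-way and two-way fixed-effects ANOVA (Type
#' III sums of squares with sum-to-zero contrasts by default), pairwise
#' percent length ratios, and the interaction-count group summary.
#'
#' @name stats_kernel
NULL

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average ranks. The p-value uses the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom; for `n <= 10` with no ties, `exact = TRUE` switches to the
#' exact permutation null distribution.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`. Pairs with missing
#'   values are dropped.
#' @param exact Use the exact permutation p-value when `n <= 10` and there
#'   are no ties (falls back to the t approximation otherwise).
#' @return List with `rho`, `n`, `df = n - 2`, `p`. A constant input vector
#'   gives `rho = NA`, `p = NA`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs (got %d)", n)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, n = n, df = n - 2L, p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (exact && n <= 10L && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, n = n, df = n - 2L, p = p)
}

#' One-way fixed-effects ANOVA
#'
#' Classic decomposition: `F = MS_between / MS_within` with `df1 = g - 1`,
#' `df2 = n - g`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor), at least 2 groups.
#' @return data.frame with rows for the group effect and residuals:
#'   `effect`, `df`, `sum_sq`, `mean_sq`, `F`, `p`. If the within-group mean
#'   square is zero, `F` is `Inf` with a warning.
#' @export
one_way_anova <- function(values, groups) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]
  g <- droplevels(factor(groups[ok]))
  if (nlevels(g) < 2L) abort("need at least 2 groups")
  if (length(values) <= nlevels(g))
    abort("need more observations than groups")
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  out <- data.frame(effect = c("group", "residual"),
                    df = tab[["Df"]],
                    sum_sq = tab[["Sum Sq"]],
                    mean_sq = tab[["Mean Sq"]],
                    F = c(tab[["F value"]][1], NA_real_),
                    p = c(tab[["Pr(>F)"]][1], NA_real_),
                    stringsAsFactors = FALSE)
  if (out$sum_sq[2] <= 1e-12 * max(sum(out$sum_sq), .Machine$double.xmin)) {
    warning("within-group mean square is zero; F reported as Inf")
    out$sum_sq[2] <- 0
    out$mean_sq[2] <- 0
    out$F[1] <- if (out$mean_sq[1] > 0) Inf else NaN
    out$p[1] <- if (out$mean_sq[1] > 0) 0 else NA_real_
  }
  out
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits `values ~ A * B` with sum-to-zero contrasts and reports, by default,
#' Type III sums of squares (Types I and II available behind `ss_type`),
#' computed as residual-sum-of-squares differences between the full model
#' and the model with the effect's columns removed. Interaction df is
#' `(a - 1)(b - 1)`; residual df is `n - a * b`.
#'
#' @param values Numeric response vector.
#' @param a,b Factors (coerced); every (A, B) cell must be non-empty.
#' @param ss_type 1, 2 or 3 (default 3).
#' @return data.frame with rows A, B, A:B, residual: `effect`, `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p`.
#' @export
two_way_anova <- function(values, a, b, ss_type = 3) {
  ok <- stats::complete.cases(values, a, b)
  values <- values[ok]
  a <- droplevels(factor(a[ok])); b <- droplevels(factor(b[ok]))
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    abort("both factors need at least 2 levels")
  cells <- table(a, b)
  if (any(cells == 0L))
    abort(paste("empty (A, B) cell(s); aggregate to cell means or drop the",
                "empty levels before fitting"))
  if (length(values) <= nlevels(a) * nlevels(b))
    abort("no residual degrees of freedom (n <= a * b)")
  if (!ss_type %in% c(1, 2, 3)) abort("ss_type must be 1, 2 or 3")
  X <- stats::model.matrix(~ A * B,
                           data = data.frame(A = a, B = b),
                           contrasts.arg = list(A = "contr.sum",
                                                B = "contr.sum"))
  asg <- attr(X, "assign")   # 0 = intercept, 1 = A, 2 = B, 3 = A:B
  rss <- function(terms) {
    cols <- asg %in% c(0, terms)
    sum(stats::lm.fit(X[, cols, drop = FALSE], values)$residuals^2)
  }
  rss_full <- rss(1:3)
  ss <- switch(as.character(ss_type),
    "1" = c(rss(integer(0)) - rss(1), rss(1) - rss(1:2),
            rss(1:2) - rss_full),
    "2" = c(rss(2) - rss(1:2), rss(1) - rss(1:2), rss(1:2) - rss_full),
    "3" = c(rss(2:3) - rss_full, rss(c(1, 3)) - rss_full,
            rss(1:2) - rss_full))
  ss <- pmax(ss, 0)
  n <- length(values)
  na <- nlevels(a); nb <- nlevels(b)
  df <- c(na - 1L, nb - 1L, (na - 1L) * (nb - 1L), n - na * nb)
  ss <- c(ss, rss_full)
  if (ss[4] <= 1e-12 * max(sum(ss), .Machine$double.xmin)) ss[4] <- 0
  ms <- ss / df
  if (ms[4] == 0) {
    warning("residual mean square is zero; F reported as Inf")
    Fv <- c(ifelse(ss[1:3] > 0, Inf, NaN), NA_real_)
    p <- c(ifelse(ss[1:3] > 0, 0, NA_real_), NA_real_)
  } else {
    Fv <- c(ms[1:3] / ms[4], NA_real_)
    p <- c(stats::pf(Fv[1:3], df[1:3], df[4], lower.tail = FALSE),
           NA_real_)
  }
  data.frame(effect = c("A", "B", "A:B", "residual"), df = df, sum_sq = ss,
             mean_sq = ms, F = Fv, p = p, stringsAsFactors = FALSE)
}

#' Pairwise percent differences between group means
#'
#' `ratio_pct(a, b) = 100 * (mean_a / mean_b - 1)` for every ordered pair of
#' groups (e.g. means 184 vs 100 give +84).
#'
#' @param means Named numeric vector of positive group means.
#' @return data.frame `group_a`, `group_b`, `pct_longer` for all ordered
#'   pairs `a != b`.
#' @export
group_length_ratios <- function(means) {
  stopifnot(!is.null(names(means)), all(nzchar(names(means))))
  if (any(means <= 0)) abort("group means must be positive")
  grid <- expand.grid(group_a = names(means), group_b = names(means),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$group_a != grid$group_b, , drop = FALSE]
  grid$pct_longer <- 100 * (means[grid$group_a] / means[grid$group_b] - 1)
  rownames(grid) <- NULL
  grid
}

#' Mean physical-interaction count per pathway group
#'
#' @param counts data.frame `protein_id`, `physical_interaction_count`
#'   ([read_interaction_counts()] layout).
#' @param groups Named character vector (or data.frame with `anchor_id`,
#'   `pathway_group`) giving the group label per protein. Proteins without a
#'   label are skipped with a warning.
#' @return data.frame `pathway_group`, `n`, `mean_interactions`.
#' @export
interaction_count_summary <- function(counts, groups) {
  if (is.data.frame(groups)) {
    lab <- groups$pathway_group
    names(lab) <- groups$anchor_id
    groups <- lab
  }
  g <- groups[counts$protein_id]
  miss <- is.na(g)
  if (any(miss)) {
    warning(sprintf("skipping %d protein(s) without a group label",
                    sum(miss)))
    counts <- counts[!miss, , drop = FALSE]
    g <- g[!miss]
  }
  f <- factor(g)
  data.frame(pathway_group = levels(f),
             n = as.integer(table(f)),
             mean_interactions =
               as.numeric(tapply(counts$physical_interaction_count, f, mean)),
             stringsAsFactors = FALSE)
}
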