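test_that("spearman matches the average-rank oracle, with and without ties", {
  r <- spearman_test(1:10, 1:10)
  expect_equal(r$rho, 1)
  expect_equal(spearman_test(1:10, 10:1)$rho, -1)
  # tie case against first-principles average ranks + Pearson-from-sums
  x <- c(1, 2, 2, 4, 5, 6); y <- c(2, 1, 3, 4, 6, 5)
  got <- spearman_test(x, y)
  expect_equal(got$rho, pearson_sums(avg_ranks(x), avg_ranks(y)),
               tolerance = 1e-12)
  expect_equal(got$n, 6L)
  expect_equal(got$df, 4L)
  # t-approximation p
  tstat <- got$rho * sqrt((got$n - 2) / (1 - got$rho^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), got$n - 2), tolerance = 1e-12)
  # random untied instances agree with the rank-Pearson oracle to 1e-12
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(spearman_test(x, y)$rho,
                 pearson_sums(avg_ranks(x), avg_ranks(y)),
                 tolerance = 1e-12)
  }
  # constant vector flagged as undefined
  expect_true(is.na(spearman_test(rep(1, 5), 1:5)$rho))
  # exact small-sample switch agrees with the exact reference distribution
  set.seed(6)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman_test(x, y, exact = TRUE)$p,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
})

test_that("one-way ANOVA matches textbook sums of squares", {
  vals <- c(4, 6, 8, 5, 7, 9, 10, 8, 12, 14, 11, 13)
  grp <- rep(c("A", "B", "C"), each = 4)
  a <- one_way_anova(vals, grp)
  # hand-computed: SSB = 3318/36, SSW = 18.75, F = 22.12 exactly
  expect_equal(a$df, c(2L, 9L))
  expect_equal(a$sum_sq, c(3318 / 36, 18.75), tolerance = 1e-12)
  expect_equal(a$F[1], 22.12, tolerance = 1e-12)
  expect_equal(a$p[1], pf(22.12, 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)
  # equal group means give F = 0 exactly
  expect_equal(one_way_anova(c(1, 3, 1, 3), c("a", "a", "b", "b"))$F[1], 0)
  # zero within-group variance is flagged
  expect_warning(z <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
                 "Inf")
  expect_equal(z$F[1], Inf)
  expect_error(one_way_anova(1:3, c("a", "a", "a")), "2 groups")
})

test_that("two-group one-way F equals the squared pooled-variance t", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = 0.5)
    a <- one_way_anova(c(x, y), rep(c("x", "y"), c(length(x), length(y))))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(a$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p[1], tt$p.value, tolerance = 1e-10)
  }
})

test_that("two-way ANOVA: additivity, balance, and df arithmetic", {
  # purely additive balanced data: interaction SS is zero
  g <- expand.grid(A = factor(1:3), B = factor(1:4), rep = 1:2)
  y_add <- as.numeric(g$A) * 2 + as.numeric(g$B) * 5
  expect_warning(tw <- two_way_anova(y_add, g$A, g$B), "residual")
  expect_equal(tw$sum_sq[tw$effect == "A:B"], 0)
  expect_equal(tw$df, c(2L, 3L, 6L, 12L))
  # balanced noisy data: Type I and Type III decompositions coincide
  set.seed(9)
  y <- y_add + rnorm(length(y_add))
  t1 <- two_way_anova(y, g$A, g$B, ss_type = 1)
  t3 <- two_way_anova(y, g$A, g$B, ss_type = 3)
  expect_equal(t1$sum_sq, t3$sum_sq, tolerance = 1e-8)
  expect_equal(t1$F, t3$F, tolerance = 1e-8)
  # empty cell instructs cell-mean handling
  expect_error(two_way_anova(y[-(1:2)], g$A[-(1:2)], g$B[-(1:2)])
               , NA)  # removing replicates only is fine
  keep <- !(g$A == 1 & g$B == 1)
  expect_error(two_way_anova(y[keep], g$A[keep], g$B[keep]), "cell")
})

test_that("Type III sums of squares match the projection-matrix oracle", {
  # unbalanced 2x3 with sum-to-zero contrasts: SS_effect = RSS(reduced
  # model dropping the effect's columns) - RSS(full)
  set.seed(10)
  a <- factor(rep(c(1, 2), times = c(7, 9)))
  b <- factor(c(rep(1:3, times = c(2, 2, 3)), rep(1:3, times = c(4, 2, 3))))
  y <- rnorm(16, mean = 2 * as.numeric(a) + 0.5 * as.numeric(b))
  X <- model.matrix(~ a * b,
                    contrasts.arg = list(a = "contr.sum", b = "contr.sum"))
  asg <- attr(X, "assign")
  rss <- function(cols) {
    fit <- lm.fit(X[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  full <- rss(seq_len(ncol(X)))
  oracle <- vapply(1:3, function(term)
    rss(which(asg != term)) - full, numeric(1))
  got <- two_way_anova(y, a, b, ss_type = 3)
  expect_equal(got$sum_sq[1:3], oracle, tolerance = 1e-8)
  expect_equal(got$sum_sq[4], full, tolerance = 1e-8)
  # independent cross-check against car's Type II / III implementation
  fit <- lm(y ~ a * b, contrasts = list(a = "contr.sum", b = "contr.sum"))
  car3 <- car::Anova(fit, type = 3)
  expect_equal(got$sum_sq[1:3],
               car3[c("a", "b", "a:b"), "Sum Sq"], tolerance = 1e-8,
               ignore_attr = TRUE)
  car2 <- car::Anova(fit, type = 2)
  got2 <- two_way_anova(y, a, b, ss_type = 2)
  expect_equal(got2$sum_sq[1:3],
               car2[c("a", "b", "a:b"), "Sum Sq"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("group length ratios are percent differences of means", {
  r <- group_length_ratios(c(ddr = 184, hk = 100))
  expect_equal(r$pct_longer[r$group_a == "ddr"], 84)
  expect_equal(group_length_ratios(c(a = 5, b = 5))$pct_longer, c(0, 0))
  expect_error(group_length_ratios(c(a = 1, b = 0)), "positive")
})

test_that("interaction-count summary averages per labelled group", {
  set.seed(12)
  counts <- data.frame(protein_id = sprintf("p%02d", 1:54),
                       physical_interaction_count =
                         c(rpois(27, 15), rpois(27, 6)),
                       stringsAsFactors = FALSE)
  groups <- setNames(rep(c("DDR", "housekeeping"), each = 27),
                     counts$protein_id)
  s <- interaction_count_summary(counts, groups)
  expect_equal(s$n, c(27L, 27L))
  expect_equal(s$mean_interactions[s$pathway_group == "DDR"],
               mean(counts$physical_interaction_count[1:27]))
  expect_equal(s$mean_interactions[s$pathway_group == "housekeeping"],
               sum(counts$physical_interaction_count[28:54]) / 27)
  # unlabelled proteins are skipped with a warning
  expect_warning(s2 <- interaction_count_summary(counts, groups[-1]),
                 "without a group label")
  expect_equal(s2$n[s2$pathway_group == "DDR"], 26L)
})
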