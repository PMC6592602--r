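test_that("one-way ANOVA reduces to the squared pooled t with two groups", {
  set.seed(606)
  x <- rnorm(6, 10); y <- rnorm(5, 12)
  res <- anova_dunnett_tukey(c(x, y), rep(c("a", "b"), c(6, 5)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA F is location invariant and scale-consistent", {
  set.seed(607)
  v <- rnorm(12); g <- rep(letters[1:3], 4)
  f0 <- anova_dunnett_tukey(v, g)$f
  expect_equal(anova_dunnett_tukey(v + 100, g)$f, f0, tolerance = 1e-9)
  expect_equal(anova_dunnett_tukey(v * 7, g)$f, f0, tolerance = 1e-9)
})

test_that("identical observations give F = 0 and unit p-values", {
  res <- anova_dunnett_tukey(rep(5, 9), rep(letters[1:3], 3), control = "a")
  expect_identical(res$f, 0)
  expect_identical(res$p, 1)
  expect_true(all(res$tukey$p_adj == 1))
  expect_true(all(res$dunnett$p_adj == 1))
  expect_error(anova_dunnett_tukey(1:3, c("a", "b", "c")), "2 replicates")
})

test_that("Tukey and Dunnett adjustments agree with independent routes", {
  set.seed(608)
  v <- c(rnorm(4, 0), rnorm(4, 1), rnorm(4, 3))
  g <- rep(c("ctrl", "mid", "high"), each = 4)
  res <- anova_dunnett_tukey(v, g, control = "ctrl")
  # Tukey route 1 (stats::TukeyHSD, used internally) vs route 2 (multcomp)
  fit <- aov(y ~ grp, data = data.frame(y = v, grp = factor(g,
             levels = c("ctrl", "high", "mid"))))
  gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(grp = "Tukey")))
  p2 <- sort(unname(gl$test$pvalues))
  expect_equal(sort(res$tukey$p_adj), p2, tolerance = 2e-3)
  # Dunnett with 2 groups collapses to the plain t-test
  res2 <- anova_dunnett_tukey(v[1:8], g[1:8], control = "ctrl")
  tt <- t.test(v[5:8], v[1:4], var.equal = TRUE)
  expect_equal(res2$dunnett$p_adj, tt$p.value, tolerance = 1e-4)
})

test_that("Kruskal-Wallis pairwise comparisons carry Bonferroni bounds", {
  # completely separated ranks, n = 6 per group: exact two-sided rank-sum
  x <- 1:6; y <- 101:106; z <- 201:206
  res <- kruskal_bonferroni(c(x, y, z), rep(c("a", "b", "c"), each = 6))
  expect_equal(res$pairwise$p_raw, rep(2 / choose(12, 6), 3),
               tolerance = 1e-12)
  expect_equal(res$pairwise$p_adj, pmin(1, res$pairwise$p_raw * 3),
               tolerance = 1e-12)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adj <= 1))
  kw <- kruskal.test(list(x, y, z))
  expect_equal(res$h, unname(kw$statistic), tolerance = 1e-10)
})

test_that("Kruskal H is invariant under monotone transforms and zero on ties", {
  set.seed(609)
  v <- rexp(15); g <- rep(letters[1:3], 5)
  expect_equal(kruskal_bonferroni(v, g)$h, kruskal_bonferroni(log(v), g)$h,
               tolerance = 1e-12)
  expect_equal(kruskal_bonferroni(v, g)$h, kruskal_bonferroni(rank(v), g)$h,
               tolerance = 1e-12)
  tied <- kruskal_bonferroni(rep(3, 8), rep(c("a", "b"), 4))
  expect_identical(tied$h, 0)
  expect_identical(tied$p, 1)
})

test_that("body-length slopes recover exact lines and their contrasts", {
  days <- rep(c(0, 5, 10), each = 4)
  exact <- data.frame(treatment = "ctrl", day = days,
                      length_mm = 1.0 + 0.02 * days)
  flat <- data.frame(treatment = "cd", day = days, length_mm = 1.1)
  res <- suppressWarnings(length_slopes(rbind(exact, flat)))  # zero-residual lines
  expect_equal(res$slopes$slope[res$slopes$treatment == "ctrl"], 0.02,
               tolerance = 1e-12)
  expect_equal(res$slopes$slope[res$slopes$treatment == "cd"], 0,
               tolerance = 1e-12)
  expect_equal(res$contrasts$estimate, 0.02, tolerance = 1e-12)
  expect_error(length_slopes(data.frame(treatment = "x", day = 1,
                                        length_mm = 1)), "2 distinct days")
})

test_that("slope contrasts cover the true difference at the nominal rate", {
  true_diff <- 0.02 - (-0.05)
  hits <- 0
  set.seed(610)
  for (i in 1:50) {
    days <- rep(c(0, 2, 5, 8, 10), each = 8)
    d <- rbind(
      data.frame(treatment = "ctrl", day = days,
                 length_mm = 1.0 + 0.02 * days + rnorm(length(days), 0, 0.08)),
      data.frame(treatment = "cd", day = days,
                 length_mm = 1.2 - 0.05 * days + rnorm(length(days), 0, 0.08)))
    con <- length_slopes(d)$contrasts
    if (abs(abs(con$estimate[1]) - true_diff) <= 2 * con$se[1])
      hits <- hits + 1
  }
  expect_gte(hits, 45)
})
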