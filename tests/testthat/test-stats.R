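test_that("D'Agostino-Pearson matches an independent reference implementation", {
  # frozen reference values computed with an independent implementation of
  # the K2 omnibus test on these exact samples
  set.seed(101); x <- round(rnorm(60, 5, 2), 6)
  set.seed(202); y <- round(rlnorm(60, 0, 1), 6)
  rx <- dagostino_pearson(x)
  expect_equal(unname(rx$statistic), 3.8614574277, tolerance = 1e-8)
  expect_equal(rx$p.value, 0.1450424655, tolerance = 1e-8)
  ry <- dagostino_pearson(y)
  expect_equal(unname(ry$statistic), 64.1536745793, tolerance = 1e-8)
  expect_lt(ry$p.value, 0.001)

  # null calibration at large n; a skewed sample is firmly rejected
  set.seed(7)
  expect_gt(dagostino_pearson(rnorm(5000))$p.value, 0.01)
  expect_error(dagostino_pearson(rep(3, 50)), "constant")
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("log-transform gate dispatches normal, lognormal and nonpositive data", {
  set.seed(31)
  normal <- rnorm(100, 10, 2)
  g1 <- log_transform_gate(normal)
  expect_equal(g1$transform, "none")
  expect_identical(g1$values, normal)

  lognormal <- exp(rnorm(200, 1, 0.8))
  g2 <- log_transform_gate(lognormal)
  expect_equal(g2$transform, "log")
  expect_true(g2$parametric)

  with_zero <- c(0, exp(rnorm(99, 1, 0.8)))
  g3 <- log_transform_gate(with_zero)
  expect_equal(g3$transform, "nonparametric")
  expect_false(g3$parametric)
})

test_that("Kruskal-Wallis matches the rank formula and base R, with ties", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis(v, g)
  # brute-force rank formula: no ties, H = 12/(N(N+1)) sum nj (Rbar - (N+1)/2)^2
  rk <- rank(v)
  h_manual <- 12 / (9 * 10) *
    sum(3 * (tapply(rk, g, mean) - 5)^2)
  expect_equal(unname(res$statistic), h_manual, tolerance = 1e-12)

  set.seed(5)
  v2 <- sample(1:6, 30, TRUE); g2 <- rep(1:3, 10)
  mine <- kruskal_wallis(v2, g2)
  base <- stats::kruskal.test(v2, factor(g2))
  expect_equal(unname(mine$statistic), unname(base$statistic),
               tolerance = 1e-12)
  expect_equal(mine$p.value, base$p.value, tolerance = 1e-12)

  ident <- kruskal_wallis(rep(4, 9), rep(1:3, 3))
  expect_equal(unname(ident$statistic), 0)
  expect_equal(ident$p.value, 1)
})

test_that("Dunn z values match the hand-rank oracle and adjustments behave", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  tab <- dunn_posthoc(v, g, adjustment = "none")
  # no ties: se = sqrt(N(N+1)/12 * (1/3+1/3)), mean ranks 2, 5, 8
  se <- sqrt(9 * 10 / 12 * (2 / 3))
  expect_equal(tab$z, c(-3, -6, -3) / se, tolerance = 1e-12)

  bonf <- dunn_posthoc(v, g, adjustment = "bonferroni")
  expect_true(all(bonf$p_adj >= tab$p_raw))
  expect_equal(bonf$p_adj, pmin(1, tab$p_raw * 3), tolerance = 1e-12)

  two_same <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(two_same$z, 0)
  expect_equal(two_same$p_adj, 1)
})

test_that("one-way ANOVA: F = t^2 for two groups; Tukey ordering tracks means", {
  set.seed(9)
  a <- rnorm(12); b <- rnorm(15, 1)
  res <- one_way_anova(c(a, b), rep(c("a", "b"), c(12, 15)))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(unname(res$statistic), unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(res$p.value, tt$p.value, tolerance = 1e-9)

  set.seed(10)
  g3v <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 3))
  g3 <- rep(c("lo", "mid", "hi"), each = 10)
  tk <- tukey_hsd(g3v, g3)
  # pair with the largest mean separation has the smallest p
  sep <- abs(tk$diff)
  expect_equal(order(tk$p_adj), order(-sep))
  # oracle: base R TukeyHSD on the same fit
  base_tk <- stats::TukeyHSD(stats::aov(g3v ~ factor(g3)))[[1]]
  key <- sub(" vs ", "-", tk$comparison)
  flip <- setdiff(key, rownames(base_tk))
  key[key %in% flip] <- sapply(strsplit(flip, "-"),
                               function(p) paste(p[2], p[1], sep = "-"))
  expect_equal(tk$p_adj, unname(base_tk[key, "p adj"]), tolerance = 1e-6)

  expect_error(one_way_anova(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3)),
               "zero within-group variance")
})

test_that("two-way ANOVA: balanced Type-II equals the textbook decomposition", {
  set.seed(3)
  fa <- factor(rep(c("x", "y"), each = 12))
  fb <- factor(rep(rep(c("u", "v", "w"), each = 4), 2))
  v <- rnorm(24) + (fa == "y") * 1 + (fb == "v") * 0.5
  res <- two_way_anova(v, fa, fb)
  base <- summary(stats::aov(v ~ fa * fb))[[1]]
  expect_equal(unname(res$table$ss[1:3]), base[1:3, "Sum Sq"],
               tolerance = 1e-9)
  expect_equal(unname(res$p.value), base[1:3, "Pr(>F)"], tolerance = 1e-9)

  # additive truth: interaction stays quiet in most seeded replicates
  set.seed(21)
  quiet <- mean(replicate(100, {
    va <- rnorm(40) + rep(c(0, 1), each = 20) + rep(rep(c(0, .5), each = 10), 2)
    two_way_anova(va, factor(rep(1:2, each = 20)),
                  factor(rep(rep(1:2, each = 10), 2)))$p.value["AB"] > 0.05
  }))
  expect_gte(quiet, 0.9)

  expect_error(two_way_anova(rnorm(4), factor(c(1, 1, 2, 2)),
                             factor(c(1, 2, 1, 2))),
               "interaction untestable")
  expect_error(two_way_anova(rnorm(6), factor(c(1, 1, 1, 1, 2, 2)),
                             factor(c(1, 1, 2, 2, 1, 1))),
               "empty design cells")
})

test_that("Scheirer-Ray-Hare matches the rank-decomposition oracle", {
  # 2x2 toy table checked against a direct computation on ranks
  v <- c(3, 5, 4, 8, 9, 7, 12, 14, 13, 6, 5, 7)
  fa <- factor(rep(c("a", "b"), each = 6))
  fb <- factor(rep(rep(c("p", "q"), each = 3), 2))
  res <- scheirer_ray_hare(v, fa, fb)
  r <- rank(v)
  ms_total <- sum((r - mean(r))^2) / (length(r) - 1)
  sm <- summary(stats::aov(r ~ fa * fb))[[1]]   # balanced: Type I == II
  expect_equal(unname(res$statistic), sm[1:3, "Sum Sq"] / ms_total,
               tolerance = 1e-9)

  # pure factor-A shift loads H_A, not H_B
  set.seed(12)
  va <- rnorm(40) + rep(c(0, 3), each = 20)
  fA <- factor(rep(c(1, 2), each = 20))
  fB <- factor(rep(rep(c(1, 2), each = 10), 2))
  shift <- scheirer_ray_hare(va, fA, fB)
  expect_gt(unname(shift$statistic["A"]), 10)
  expect_lt(shift$p.value["A"], 0.01)
  expect_gt(shift$p.value["B"], 0.05)

  allsame <- scheirer_ray_hare(rep(2, 12), fa, fb)
  expect_equal(unname(allsame$statistic), c(0, 0, 0))
})

test_that("Wilcoxon variants match base R's normal approximation; BH matches step-up", {
  set.seed(9)
  a <- rnorm(20); b <- rnorm(20, 0.8)
  expect_equal(wilcoxon_test(a, b)$p.value,
               stats::wilcox.test(a, b, exact = FALSE)$p.value,
               tolerance = 1e-12)
  expect_equal(wilcoxon_test(a, b, paired = TRUE)$p.value,
               stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-12)
  expect_equal(wilcoxon_test(a, b, alternative = "less")$p.value,
               stats::wilcox.test(a, b, exact = FALSE,
                                  alternative = "less")$p.value,
               tolerance = 1e-12)
  expect_equal(wilcoxon_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p.value, 1)

  # BH step-up: hand case and agreement with p.adjust
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(25)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)

  days <- list(list(x = a, y = b), list(x = a, y = a + 0.1),
               list(x = a, y = rev(a)))
  wb <- wilcoxon_bh(days, paired = TRUE)
  expect_true(all(wb$p_adj >= wb$p_raw - 1e-15))
  expect_equal(wb$p_adj, bh_adjust(wb$p_raw))
  expect_error(wilcoxon_bh(list(list(x = numeric(), y = 1:3))), "empty")
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(14)
  v <- rnorm(45)
  g <- rep(1:3, 15)
  fa <- factor(rep(1:3, 15)); fb <- factor(rep(rep(1:3, each = 5), 3))
  maps <- list(function(z) exp(z), function(z) z^3,
               function(z) atan(z) * 5 + 100)
  for (f in maps) {
    expect_equal(kruskal_wallis(f(v), g)$statistic,
                 kruskal_wallis(v, g)$statistic, tolerance = 1e-12)
    expect_equal(dunn_posthoc(f(v), g)$z, dunn_posthoc(v, g)$z,
                 tolerance = 1e-12)
    expect_equal(scheirer_ray_hare(f(v), fa, fb)$statistic,
                 scheirer_ray_hare(v, fa, fb)$statistic, tolerance = 1e-12)
  }
})

test_that("test-selection dispatch reproduces the battery's routing rule", {
  set.seed(16)
  normal_groups <- c(rnorm(30, 10), rnorm(30, 12))
  g <- rep(c("a", "b"), each = 30)
  sel <- select_test(normal_groups, g)
  expect_equal(sel$route, "parametric")
  expect_equal(sel$omnibus$method, "one-way ANOVA")

  skewed <- c(exp(rnorm(30, 1, 1)) - 3, exp(rnorm(30, 1.6, 1)) - 3)
  sel2 <- select_test(skewed, g)   # negative values block the log rescue
  expect_equal(sel2$route, "nonparametric")

  lognorm <- c(exp(rnorm(30, 1, 0.9)), exp(rnorm(30, 1.5, 0.9)))
  sel3 <- select_test(lognorm, g)
  expect_true(sel3$route == "parametric" && sel3$transform == "log")

  expect_equal(p_stars(c(0.2, 0.04, 0.009, 8e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})
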