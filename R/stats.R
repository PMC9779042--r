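#' Significance stars
#'
#' The usual four-tier convention: `*` p<0.05, `**` p<0.01, `***` p<0.001,
#' `****` p<0.0001, else `ns`.
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
    ifelse(p < 1e-3, "***",
      ifelse(p < 1e-2, "**",
        ifelse(p < 0.05, "*", "ns"))))
}

new_test_result <- function(method, statistic, df, p, pairwise = NULL,
                            extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p.value = p, pairwise = pairwise), extra),
            class = "fly_test")
}

#' @export
print.fly_test <- function(x, ...) {
  stat_txt <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
                    collapse = ", ")
  df_txt <- if (length(x$df)) paste0(" (df ",
                                     paste(x$df, collapse = ", "), ")") else ""
  p_txt <- paste(sprintf("p = %.4g %s", x$p.value, p_stars(x$p.value)),
                 collapse = "; ")
  cat(sprintf("%s: %s%s, %s\n", x$method, stat_txt, df_txt, p_txt))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

check_groups <- function(values, groups, min_k = 2L) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < min_k)
    stop(sprintf("need at least %d groups", min_k))
  list(values = values, groups = droplevels(groups))
}

tie_sizes <- function(values) {
  tj <- table(values)
  as.numeric(tj[tj > 1])
}

# ---- normality gate ---------------------------------------------------------

#' D'Agostino-Pearson omnibus normality test
#'
#' K2 = Z(sqrt(b1))^2 + Z(b2)^2: the squared z-transforms of sample skewness
#' (D'Agostino 1970) and kurtosis (Anscombe & Glynn 1983), referred to
#' chi-squared with 2 df.
#'
#' @param values numeric sample, n >= 8 (the kurtosis transform needs ~8+).
#' @return a `fly_test` with K2, p, and the component z statistics.
#' @export
dagostino_pearson <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test needs n >= 8")
  if (stats::sd(x) == 0) stop("undefined moments: sample is constant")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5           # sample skewness g1
  b2 <- m4 / m2^2             # sample kurtosis g2 (not excess)

  # skewness transform (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  new_test_result("D'Agostino-Pearson omnibus normality",
                  c(K2 = k2), df = 2,
                  p = stats::pchisq(k2, 2, lower.tail = FALSE),
                  extra = list(z_skew = z1, z_kurt = z2))
}

#' Normality gate with log-transform fallback
#'
#' The parametric/nonparametric dispatch: keep the data if it passes
#' normality; otherwise (when all values are positive) log-transform and
#' retest; otherwise flag the sample for a nonparametric test.
#'
#' @param values numeric sample.
#' @param alpha gate level (default 0.05).
#' @return list `(values, transform, parametric, p_normality)`; `transform`
#'   is `"none"`, `"log"`, or `"nonparametric"`.
#' @export
log_transform_gate <- function(values, alpha = 0.05) {
  p0 <- tryCatch(dagostino_pearson(values)$p.value, error = function(e) 0)
  if (p0 >= alpha)
    return(list(values = values, transform = "none", parametric = TRUE,
                p_normality = p0))
  if (any(values <= 0, na.rm = TRUE))
    return(list(values = values, transform = "nonparametric",
                parametric = FALSE, p_normality = p0))
  lv <- log(values)
  p1 <- tryCatch(dagostino_pearson(lv)$p.value, error = function(e) 0)
  if (p1 >= alpha)
    return(list(values = lv, transform = "log", parametric = TRUE,
                p_normality = p1))
  list(values = values, transform = "nonparametric", parametric = FALSE,
       p_normality = p1)
}

# ---- rank-based k-group tests ----------------------------------------------

#' Kruskal-Wallis rank test (with tie correction)
#'
#' H computed from mid-rank group means and divided by the tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; p from chi-squared with k-1 df. A sample
#' in which every value is identical gives H = 0, p = 1.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor).
#' @return a `fly_test`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- check_groups(values, groups)
  x <- g$values; grp <- g$groups
  n <- length(x)
  if (n < 3) stop("need at least 3 observations in total")
  rk <- rank(x)
  nj <- tabulate(grp)
  rbar <- tapply(rk, grp, mean)
  h <- 12 / (n * (n + 1)) * sum(nj * (rbar - (n + 1) / 2)^2)
  ties <- tie_sizes(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (corr > 0) h / corr else 0
  k <- nlevels(grp)
  new_test_result("Kruskal-Wallis rank sum", c(H = h), df = k - 1L,
                  p = if (corr > 0)
                    stats::pchisq(h, k - 1L, lower.tail = FALSE) else 1)
}

#' Dunn's post hoc multiple comparisons
#'
#' z for each pair from the difference of mean ranks over its tie-corrected
#' standard error; family-wise adjustment over the k(k-1)/2 pairs
#' (Bonferroni by default, matching the usual reading of "Dunn's multiple
#' comparisons test"; Holm, Sidak and none are exposed).
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param adjustment `"bonferroni"` (default), `"holm"`, `"sidak"`, `"none"`.
#' @return data.frame: comparison, z, p_raw, p_adj, stars.
#' @export
dunn_posthoc <- function(values, groups,
                         adjustment = c("bonferroni", "holm", "sidak",
                                        "none")) {
  adjustment <- match.arg(adjustment)
  g <- check_groups(values, groups)
  x <- g$values; grp <- g$groups
  if (nlevels(grp) < 2) stop("post hoc needs at least two groups")
  n <- length(x)
  rk <- rank(x)
  nj <- tabulate(grp)
  rbar <- tapply(rk, grp, mean)
  ties <- tie_sizes(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(grp)
  combs <- utils::combn(seq_along(lv), 2)
  m <- ncol(combs)
  z <- p_raw <- numeric(m)
  comparison <- character(m)
  for (c_i in seq_len(m)) {
    i <- combs[1, c_i]; j <- combs[2, c_i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / nj[i] + 1 / nj[j]))
    z[c_i] <- (rbar[i] - rbar[j]) / se
    p_raw[c_i] <- 2 * stats::pnorm(-abs(z[c_i]))
    comparison[c_i] <- paste(lv[i], "vs", lv[j])
  }
  p_adj <- switch(adjustment,
    bonferroni = pmin(1, p_raw * m),
    holm = {
      o <- order(p_raw)
      adj <- cummax(pmin(1, p_raw[o] * (m - seq_len(m) + 1)))
      out <- numeric(m); out[o] <- adj; out
    },
    sidak = 1 - (1 - p_raw)^m,
    none = p_raw)
  data.frame(comparison = comparison, z = z, p_raw = p_raw, p_adj = p_adj,
             stars = p_stars(p_adj), stringsAsFactors = FALSE)
}

# ---- parametric battery -----------------------------------------------------

#' One-way ANOVA
#'
#' F = MS_between / MS_within against F(k-1, N-k).
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @return a `fly_test` with F, both df, p and the mean squares.
#' @export
one_way_anova <- function(values, groups) {
  g <- check_groups(values, groups)
  x <- g$values; grp <- g$groups
  nj <- tabulate(grp)
  if (any(nj < 2)) stop("each group needs n >= 2")
  k <- nlevels(grp)
  n <- length(x)
  gm <- mean(x)
  mj <- tapply(x, grp, mean)
  ssb <- sum(nj * (mj - gm)^2)
  ssw <- sum((x - mj[grp])^2)
  if (ssw == 0) stop("zero within-group variance: F undefined")
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- msb / msw
  new_test_result("one-way ANOVA", c(F = f), df = c(k - 1L, n - k),
                  p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
                  extra = list(ms_within = msw, ss_between = ssb,
                               ss_within = ssw))
}

#' Tukey honest significant differences
#'
#' Pairwise q statistics (Tukey-Kramer for unequal n) on the one-way ANOVA's
#' within mean square, referred to the studentized range distribution.
#'
#' @inheritParams one_way_anova
#' @return data.frame: comparison, diff, q, p_adj, stars.
#' @export
tukey_hsd <- function(values, groups) {
  g <- check_groups(values, groups)
  x <- g$values; grp <- g$groups
  aov1 <- one_way_anova(x, grp)
  msw <- aov1$ms_within
  k <- nlevels(grp)
  n <- length(x)
  nj <- tabulate(grp)
  mj <- tapply(x, grp, mean)
  lv <- levels(grp)
  combs <- utils::combn(seq_along(lv), 2)
  rows <- lapply(seq_len(ncol(combs)), function(c_i) {
    i <- combs[1, c_i]; j <- combs[2, c_i]
    d <- mj[i] - mj[j]
    q <- abs(d) / sqrt(msw / 2 * (1 / nj[i] + 1 / nj[j]))
    data.frame(comparison = paste(lv[i], "vs", lv[j]), diff = unname(d),
               q = unname(q),
               p_adj = stats::ptukey(q, k, n - k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- p_stars(out$p_adj)
  out
}

rss_of <- function(y, mm) {
  fit <- stats::lm.fit(mm, y)
  sum(fit$residuals^2)
}

#' Two-way ANOVA (Type-II sums of squares)
#'
#' Main effects tested after the other main effect, the interaction after
#' both (Type-II), which is the conventional default for the unbalanced cell
#' counts this pipeline produces. Reduces to the textbook decomposition for
#' balanced designs.
#'
#' @param values numeric observations.
#' @param factor_a,factor_b crossed factors.
#' @return a `fly_test`; `statistic` holds F_A, F_B, F_AB and `p.value` the
#'   matching p-values; `table` has the full decomposition.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  keep <- is.finite(values)
  y <- values[keep]
  fa <- droplevels(factor(factor_a[keep]))
  fb <- droplevels(factor(factor_b[keep]))
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("both factors need at least 2 levels")
  cell_n <- table(fa, fb)
  if (any(cell_n == 0)) {
    bad <- which(cell_n == 0, arr.ind = TRUE)
    stop(sprintf("empty design cells: %s",
                 paste(rownames(cell_n)[bad[, 1]], colnames(cell_n)[bad[, 2]],
                       sep = ":", collapse = ", ")))
  }
  n <- length(y)
  df_a <- nlevels(fa) - 1L
  df_b <- nlevels(fb) - 1L
  df_ab <- df_a * df_b
  df_err <- n - nlevels(fa) * nlevels(fb)
  if (df_err < 1)
    stop("interaction untestable: no residual degrees of freedom ",
         "(one observation per cell)")
  mm_a <- stats::model.matrix(~fa)
  mm_b <- stats::model.matrix(~fb)
  mm_ab <- stats::model.matrix(~ fa + fb)
  mm_full <- stats::model.matrix(~ fa * fb)
  ss_err <- rss_of(y, mm_full)
  ss_a <- rss_of(y, mm_b) - rss_of(y, mm_ab)     # A after B
  ss_b <- rss_of(y, mm_a) - rss_of(y, mm_ab)     # B after A
  ss_ab <- rss_of(y, mm_ab) - ss_err
  ms_err <- ss_err / df_err
  f <- c(A = ss_a / df_a, B = ss_b / df_b, AB = ss_ab / df_ab) / ms_err
  p <- stats::pf(f, c(df_a, df_b, df_ab), df_err, lower.tail = FALSE)
  tab <- data.frame(term = c("A", "B", "A:B", "residuals"),
                    ss = c(ss_a, ss_b, ss_ab, ss_err),
                    df = c(df_a, df_b, df_ab, df_err),
                    f = c(f, NA), p = c(p, NA))
  new_test_result("two-way ANOVA (Type II)", f,
                  df = c(df_a, df_b, df_ab, df_err), p = p,
                  extra = list(table = tab, ms_error = ms_err))
}

#' Scheirer-Ray-Hare test
#'
#' The nonparametric two-factor extension of Kruskal-Wallis: all values are
#' mid-ranked together, a two-way SS decomposition is computed on the ranks,
#' and each effect's H = SS_effect / MS_total (MS_total = SS_total / (N-1))
#' is referred to chi-squared with the effect's df. Ties are handled by the
#' mid-ranks with no further correction.
#'
#' @inheritParams two_way_anova
#' @return a `fly_test` with H_A, H_B, H_AB and matching p-values.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  keep <- is.finite(values)
  y <- rank(values[keep])
  fa <- droplevels(factor(factor_a[keep]))
  fb <- droplevels(factor(factor_b[keep]))
  n <- length(y)
  if (n < 6) stop("Scheirer-Ray-Hare needs N >= 6")
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("both factors need at least 2 levels")
  df_a <- nlevels(fa) - 1L
  df_b <- nlevels(fb) - 1L
  df_ab <- df_a * df_b
  ss_total <- sum((y - mean(y))^2)
  ms_total <- ss_total / (n - 1)
  mm_a <- stats::model.matrix(~fa)
  mm_b <- stats::model.matrix(~fb)
  mm_ab <- stats::model.matrix(~ fa + fb)
  mm_full <- stats::model.matrix(~ fa * fb)
  ss_a <- rss_of(y, mm_b) - rss_of(y, mm_ab)
  ss_b <- rss_of(y, mm_a) - rss_of(y, mm_ab)
  ss_ab <- rss_of(y, mm_ab) - rss_of(y, mm_full)
  if (ms_total == 0) {
    h <- c(A = 0, B = 0, AB = 0)
    p <- stats::setNames(rep(1, 3), names(h))
  } else {
    h <- c(A = ss_a, B = ss_b, AB = ss_ab) / ms_total
    p <- stats::pchisq(h, c(df_a, df_b, df_ab), lower.tail = FALSE)
  }
  new_test_result("Scheirer-Ray-Hare", h, df = c(df_a, df_b, df_ab), p = p)
}

# ---- Wilcoxon + BH ----------------------------------------------------------

#' Wilcoxon rank test (two-sample rank-sum or paired signed-rank)
#'
#' Normal approximation with tie correction and continuity correction, the
#' behavior appropriate for the moderately sized tied samples this pipeline
#' produces. Paired tests drop zero differences (Wilcoxon's convention).
#'
#' @param x,y numeric samples; for `paired = TRUE` they must have equal
#'   length.
#' @param paired signed-rank on `x - y` instead of rank-sum.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger), `"less"`.
#' @return a `fly_test` with W (rank-sum of x) or V (positive-rank sum).
#' @export
wilcoxon_test <- function(x, y, paired = FALSE,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0)
      return(new_test_result("Wilcoxon signed rank", c(V = 0), df = NULL,
                             p = 1))
    rk <- rank(abs(d))
    v <- sum(rk[d > 0])
    mu <- n * (n + 1) / 4
    ties <- tie_sizes(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    stat <- v; mu_s <- mu; sd_s <- sqrt(sigma2)
    name <- "V"; method <- "Wilcoxon signed rank"
  } else {
    n1 <- length(x); n2 <- length(y)
    if (n1 == 0 || n2 == 0) stop("empty sample")
    rk <- rank(c(x, y))
    stat <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x
    mu_s <- n1 * n2 / 2
    nn <- n1 + n2
    ties <- tie_sizes(c(x, y))
    sigma2 <- n1 * n2 / 12 * (nn + 1 - sum(ties^3 - ties) / (nn * (nn - 1)))
    sd_s <- sqrt(sigma2)
    name <- "W"; method <- "Wilcoxon rank sum"
  }
  if (sd_s == 0) {
    p <- 1
  } else {
    cc <- 0.5
    p <- switch(alternative,
      two.sided = {
        z <- (stat - mu_s - sign(stat - mu_s) * cc) / sd_s
        min(1, 2 * stats::pnorm(-abs(z)))
      },
      greater = stats::pnorm((stat - mu_s - cc) / sd_s, lower.tail = FALSE),
      less = stats::pnorm((stat - mu_s + cc) / sd_s))
  }
  res <- new_test_result(method, stats::setNames(stat, name), df = NULL,
                         p = p)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p raw p-values.
#' @return adjusted p-values (monotone step-up smoothing applied).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Per-day Wilcoxon tests with Benjamini-Hochberg correction
#'
#' The day-wise post hoc of the system- and group-comparison figures: one
#' Wilcoxon test per day, BH step-up over the family of days.
#'
#' @param day_sets list; each element is a list `(x, y)` of that day's two
#'   samples.
#' @param paired use the signed-rank test.
#' @param alternative passed to [wilcoxon_test()].
#' @return data.frame: statistic, p_raw, p_adj, stars (one row per day).
#' @export
wilcoxon_bh <- function(day_sets, paired = FALSE,
                        alternative = "two.sided") {
  stopifnot(length(day_sets) >= 1L)
  res <- lapply(day_sets, function(s) {
    if (!length(s$x) || !length(s$y)) stop("empty per-day sample")
    wilcoxon_test(s$x, s$y, paired = paired, alternative = alternative)
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p.value")
  stat <- vapply(res, function(r) unname(r$statistic[1]), numeric(1))
  p_adj <- bh_adjust(p_raw)
  data.frame(statistic = stat, p_raw = p_raw, p_adj = p_adj,
             stars = p_stars(p_adj))
}

# ---- dispatch ---------------------------------------------------------------

#' Brown-Forsythe (median-based Levene) homogeneity of variance test
#'
#' One-way ANOVA on absolute deviations from group medians.
#'
#' @inheritParams one_way_anova
#' @return a `fly_test`.
#' @export
levene_test <- function(values, groups) {
  g <- check_groups(values, groups)
  dev <- abs(g$values - stats::ave(g$values, g$groups,
                                   FUN = stats::median))
  res <- one_way_anova(dev, g$groups)
  res$method <- "Levene (Brown-Forsythe) homogeneity of variance"
  res
}

#' Test-selection dispatch
#'
#' The analysis-battery rule: if every group passes the normality gate
#' (after an optional log rescue) and variances are homogeneous, run the
#' parametric route (one-way ANOVA + Tukey HSD); otherwise the nonparametric
#' route (Kruskal-Wallis + Dunn).
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param alpha gate level for normality and homogeneity.
#' @return list `(route, transform, omnibus, posthoc)`; route is
#'   `"parametric"` or `"nonparametric"`.
#' @export
select_test <- function(values, groups, alpha = 0.05) {
  g <- check_groups(values, groups)
  gates <- tapply(g$values, g$groups, log_transform_gate, alpha = alpha)
  transforms <- vapply(gates, `[[`, character(1), "transform")
  parametric <- all(vapply(gates, `[[`, logical(1), "parametric"))
  transform <- "none"
  vals <- g$values
  if (parametric && any(transforms == "log")) {
    # a shared transform must apply to every group
    if (all(vals > 0)) {
      transform <- "log"
      vals <- log(vals)
    } else parametric <- FALSE
  }
  if (parametric) {
    lev <- tryCatch(levene_test(vals, g$groups), error = function(e) NULL)
    if (is.null(lev) || lev$p.value < alpha) parametric <- FALSE
  }
  if (parametric) {
    list(route = "parametric", transform = transform,
         omnibus = one_way_anova(vals, g$groups),
         posthoc = tukey_hsd(vals, g$groups))
  } else {
    list(route = "nonparametric", transform = "none",
         omnibus = kruskal_wallis(g$values, g$groups),
         posthoc = dunn_posthoc(g$values, g$groups))
  }
}
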