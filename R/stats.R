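#' Likelihood-ratio test for age and genotype effects
#'
#' Compares a Gaussian linear model containing age and genotype main
#' effects with an intercept-only null that disregards them. The statistic
#' is `2 * (logLik_full - logLik_null)` with degrees of freedom equal to
#' the number of added parameters. For the Gaussian family this statistic
#' is a monotone transform of the F ratio, so its null distribution is
#' known exactly at any sample size; the default p-value uses that exact
#' distribution (it converges to the chi-squared reference for large n,
#' which remains available via `p_method = "chisq"`). With
#' `interaction = TRUE` the full model also carries the age-by-genotype
#' interaction.
#'
#' @param value Numeric response (an excitability parameter).
#' @param genotype,age Factors (coerced).
#' @param interaction Include the interaction term in the full model.
#' @param p_method `"exact"` (finite-sample, default) or `"chisq"`
#'   (asymptotic).
#' @return List with `statistic`, `df`, `p`.
#' @export
lrt_age_genotype <- function(value, genotype, age, interaction = FALSE,
                             p_method = c("exact", "chisq")) {
  p_method <- match.arg(p_method)
  genotype <- factor(genotype); age <- factor(age)
  if (nlevels(genotype) < 2 || nlevels(age) < 2)
    stop("need at least 2 levels of each factor")
  d <- data.frame(value = value, genotype = genotype, age = age)
  d <- d[complete.cases(d), ]
  form <- if (interaction) value ~ genotype * age else value ~ genotype + age
  full <- lm(form, data = d)
  if (any(is.na(coef(full)))) stop("singular design")
  if (full$df.residual <= 0) stop("no residual degrees of freedom")
  null <- lm(value ~ 1, data = d)
  df_deg <- attr(logLik(full), "df") - attr(logLik(null), "df")
  if (var(d$value) == 0)
    return(list(statistic = 0, df = df_deg, p = 1))
  stat <- max(as.numeric(2 * (logLik(full) - logLik(null))), 0)
  df <- attr(logLik(full), "df") - attr(logLik(null), "df")
  p <- if (p_method == "chisq") {
    pchisq(stat, df, lower.tail = FALSE)
  } else {
    # 2*logLR = n*log(RSS0/RSS1); invert to the F ratio
    n <- nrow(d)
    df2 <- full$df.residual
    f <- (exp(stat / n) - 1) * df2 / df
    stats::pf(f, df, df2, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p = p)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjusted p-values with rejection flags at level `q`.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param q FDR level.
#' @return List with `p_adj` and logical `reject`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p_adj <- p.adjust(pvalues, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= q)
}

#' Normality-routed pairwise comparison
#'
#' Each group is checked with the Shapiro-Wilk test at `alpha`; if both
#' groups look normal an unpaired two-tailed Student's t-test is used,
#' otherwise a Mann-Whitney U test (exact for small tie-free samples,
#' normal approximation with continuity/tie correction otherwise). The
#' routing decision is part of the result.
#'
#' @param a,b Numeric samples, n >= 3 each.
#' @param alpha Normality-screen level.
#' @param var_equal Use the pooled-variance Student's t-test.
#' @return List with `test_used` (`"t"` or `"mann-whitney"`), `statistic`,
#'   `p`, `shapiro_p`.
#' @export
posthoc_pairwise <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  sw <- c(shapiro.test(a)$p.value, shapiro.test(b)$p.value)
  if (all(sw > alpha)) {
    tt <- t.test(a, b, var.equal = var_equal)
    list(test_used = "t", statistic = unname(tt$statistic), p = tt$p.value,
         shapiro_p = sw)
  } else {
    exact <- max(length(a), length(b)) <= 20 &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact))
    list(test_used = "mann-whitney", statistic = unname(wt$statistic),
         p = wt$p.value, shapiro_p = sw)
  }
}

#' One- or two-way ANOVA with Tukey HSD post hoc contrasts
#'
#' @param value Numeric response.
#' @param f1 First factor.
#' @param f2 Second factor (two-way design, interaction included) or
#'   `NULL`.
#' @return List with `table` (term, df, sum_sq, F, p) and `tukey`.
#' @export
anova_tukey <- function(value, f1, f2 = NULL) {
  f1 <- factor(f1)
  if (nlevels(f1) < 2) stop("need at least 2 groups")
  if (any(table(f1) < 1)) stop("empty group")
  d <- data.frame(value = value, f1 = f1)
  if (is.null(f2)) {
    fit <- aov(value ~ f1, data = d)
  } else {
    d$f2 <- factor(f2)
    if (any(table(d$f1, d$f2) == 0)) stop("empty design cell")
    fit <- aov(value ~ f1 * f2, data = d)
  }
  s <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(s)), df = s[["Df"]],
                    sum_sq = s[["Sum Sq"]], F = s[["F value"]],
                    p = s[["Pr(>F)"]], row.names = NULL)
  list(table = tab, tukey = TukeyHSD(fit))
}

#' Cochran-Mantel-Haenszel test for stratified 2x2 tables
#'
#' Mantel-Haenszel chi-squared (no continuity correction, so an exactly
#' balanced table yields 0) with the Mantel-Haenszel common odds ratio.
#' Strata with a zero margin carry no information and are dropped with a
#' warning.
#'
#' @param table_2x2xk 2 x 2 x K array of counts.
#' @return List with `statistic`, `p`, `common_or`, `k_used`.
#' @export
cmh_test <- function(table_2x2xk) {
  a <- as.array(table_2x2xk)
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
  if (!all(dim(a)[1:2] == 2)) stop("each stratum must be 2x2")
  if (any(a < 0) || any(a != round(a))) stop("counts must be nonnegative integers")
  keep <- vapply(seq_len(dim(a)[3]), function(k) {
    s <- a[, , k]
    sum(s) > 0 && all(rowSums(s) > 0) && all(colSums(s) > 0)
  }, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " stratum/strata with zero margins dropped")
    a <- a[, , keep, drop = FALSE]
  }
  if (dim(a)[3] == 0) stop("no informative strata")
  # closed-form MH statistic: (sum(a11 - E))^2 / sum(Var)
  a11 <- a[1, 1, ]; r1 <- a[1, 1, ] + a[1, 2, ]; c1 <- a[1, 1, ] + a[2, 1, ]
  nn <- apply(a, 3, sum)
  e <- r1 * c1 / nn
  v <- r1 * (nn - r1) * c1 * (nn - c1) / (nn^2 * (nn - 1))
  num <- sum(a11 - e)
  stat <- if (sum(v) == 0) 0 else num^2 / sum(v)
  or_num <- sum(a[1, 1, ] * a[2, 2, ] / nn)
  or_den <- sum(a[1, 2, ] * a[2, 1, ] / nn)
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       common_or = if (or_den == 0) Inf else or_num / or_den,
       k_used = dim(a)[3])
}

#' Two-sided Pearson correlation
#'
#' @param x,y Numeric vectors, n >= 3, nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-cluster comparison of proportional representation
#'
#' For every cluster, per-sample proportions are compared between two
#' groups with an unpaired t-test; p-values are BH-adjusted across
#' clusters. Enrichment flags on adjusted and raw p are reported
#' separately.
#'
#' @param proportions `data.frame` with columns `sample`, `cluster`,
#'   `group`, `proportion`.
#' @param q FDR level for the adjusted flag.
#' @param alpha Level for the raw flag.
#' @return `data.frame`, one row per cluster: `cluster`, `statistic`,
#'   `p_raw`, `p_adj`, `flag_adj`, `flag_raw`.
#' @export
cluster_proportion_tests <- function(proportions, q = 0.05, alpha = 0.05) {
  req <- c("sample", "cluster", "group", "proportion")
  if (!all(req %in% names(proportions)))
    stop("`proportions` needs columns: ", paste(req, collapse = ", "))
  groups <- unique(proportions$group)
  if (length(groups) != 2) stop("exactly two groups required")
  clusters <- sort(unique(proportions$cluster))
  rows <- lapply(clusters, function(cl) {
    d <- proportions[proportions$cluster == cl, ]
    a <- d$proportion[d$group == groups[1]]
    b <- d$proportion[d$group == groups[2]]
    if (length(a) < 2 || length(b) < 2)
      stop("need >= 2 samples per group in cluster ", cl)
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))
      return(data.frame(cluster = cl, statistic = 0, p_raw = 1))
    tt <- t.test(a, b)
    data.frame(cluster = cl, statistic = unname(tt$statistic),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  adj <- fdr_bh(out$p_raw, q)
  out$p_adj <- adj$p_adj
  out$flag_adj <- adj$reject
  out$flag_raw <- out$p_raw < alpha
  out
}
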