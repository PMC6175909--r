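#' @section Statistics engine:
#' Self-contained implementations of every statistical procedure the silencing
#' analyses use. Base R equivalents exist for most of them and serve as
#' independent cross-checks in the test suite; the Scheirer-Ray-Hare rank
#' two-way ANOVA and the continuity-corrected one-sided Mann-Whitney path have
#' no drop-in base equivalent.
#' @name acr-stats
NULL

acr_test <- function(method, statistic, df, p_value, sided = "two-sided",
                     notes = character(), ...) {
  out <- list(method = method, statistic = statistic, df = df,
              p_value = p_value, sided = sided, notes = notes, ...)
  class(out) <- "acr_test"
  out
}

#' @export
print.acr_test <- function(x, ...) {
  cat(x$method, "\n")
  dfs <- if (length(x$df)) paste0(" (df = ", paste(x$df, collapse = ", "), ")") else ""
  cat(sprintf("  statistic = %.6g%s, p = %.4g [%s]\n",
              x$statistic, dfs, x$p_value, x$sided))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table (no continuity correction)
#'
#' Computes the Pearson statistic N(ad - bc)^2 / (r1 r2 c1 c2) with df = 1 and
#' an upper-tail p-value. Used to compare fractions of light-suppressed or
#' antidromically activated units between opsin constructs. No Yates
#' correction is applied; a zero cell is an error directing the caller to
#' [fisher_exact_2x2()].
#'
#' @param a,b,c,d cell counts, laid out as rows (group 1: a, b; group 2: c, d).
#' @return an `acr_test` result with `statistic` (chi-square) and `p_value`.
#' @examples
#' chi2_2x2(14, 59, 2, 68)  # antidromic units, construct comparison
#' @export
chi2_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stop_if_not(all(is.finite(cells)) && all(cells == round(cells)) && all(cells >= 0),
              "cell counts must be non-negative integers")
  if (any(cells == 0)) {
    stop("table contains a zero cell; use fisher_exact_2x2() instead",
         call. = FALSE)
  }
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  acr_test("Pearson chi-square (2x2, uncorrected)", stat, df = 1L,
           p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing, over all tables with the observed
#' margins, the hypergeometric probabilities that do not exceed the observed
#' table's probability (with a small relative tolerance for ties). The
#' reported statistic is the sample odds ratio (ad/bc; infinite when bc = 0).
#'
#' @param a,b,c,d non-negative cell counts (rows: group 1 a, b; group 2 c, d).
#' @return an `acr_test` with `statistic` (odds ratio) and exact `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stop_if_not(all(is.finite(cells)) && all(cells == round(cells)) && all(cells >= 0),
              "cell counts must be non-negative integers")
  m <- a + b      # row 1 total
  n2 <- c + d     # row 2 total
  k <- a + c      # column 1 total
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  p_obs <- logp[support == a]
  p <- sum(exp(logp[logp <= p_obs + 1e-7]))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  acr_test("Fisher's exact test (2x2)", or, df = NULL,
           p_value = min(1, p), notes = "statistic is the sample odds ratio")
}

## Exact null pmf of U1 for sample sizes n1, n2 (no ties), by the classical
## Mann-Whitney count recurrence N(u; n1, n2) = N(u - n2; n1 - 1, n2) +
## N(u; n1, n2 - 1), i.e. partitions of u fitting in an n1 x n2 box.
mwu_null_pmf <- function(n1, n2) {
  umax <- n1 * n2
  # layer[[j + 1]] holds N(.; i, j) for the current i as a vector over u
  delta0 <- c(1, rep(0, umax))
  layer <- rep(list(delta0), n2 + 1)   # i = 0: N(u; 0, j) = [u == 0]
  for (i in seq_len(n1)) {
    newlayer <- vector("list", n2 + 1)
    newlayer[[1]] <- delta0            # j = 0: N(u; i, 0) = [u == 0]
    for (j in seq_len(n2)) {
      shifted <- c(rep(0, j), layer[[j + 1]][seq_len(umax + 1 - j)])
      newlayer[[j + 1]] <- shifted + newlayer[[j]]
    }
    layer <- newlayer
  }
  counts <- layer[[n2 + 1]]
  counts / sum(counts)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. `mode = "exact"` enumerates the
#' exact null distribution of U (valid without ties; enforced for
#' min(n1, n2) <= 10). `mode = "normal_cc"` uses the normal approximation with
#' a 0.5 continuity correction and tie-corrected variance. The reported U is
#' min(U1, U2), the convention used when quoting U alongside group sizes.
#'
#' @param x,y numeric samples.
#' @param alternative "two.sided" (default), "less" or "greater"; directions
#'   refer to `x` relative to `y`.
#' @param mode "exact" or "normal_cc".
#' @return an `acr_test` with `statistic` = min(U1, U2) and fields `u1`, `u2`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater"),
                           mode = c("exact", "normal_cc")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  stop_if_not(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- table(r)
  has_ties <- any(ties > 1)
  notes <- character()
  if (mode == "exact") {
    if (has_ties) stop("exact mode requires untied data", call. = FALSE)
    if (min(n1, n2) > 10) stop("exact mode limited to min(n1, n2) <= 10",
                               call. = FALSE)
    pmf <- mwu_null_pmf(n1, n2)
    cdf_le <- cumsum(pmf)
    p_less <- cdf_le[round(u1) + 1]                 # P(U1 <= u1)
    p_greater <- 1 - if (u1 >= 1) cdf_le[round(u1)] else 0  # P(U1 >= u1)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_less, p_greater)),
                less = p_less,
                greater = p_greater)
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    if (has_ties) notes <- "tie-corrected variance"
    p <- switch(alternative,
                less = pnorm((u1 - mu + 0.5) / sigma),
                greater = pnorm((u1 - mu - 0.5) / sigma, lower.tail = FALSE),
                two.sided = {
                  z <- (u1 - mu - sign(u1 - mu) * 0.5) / sigma
                  min(1, 2 * pnorm(-abs(z)))
                })
  }
  acr_test(paste0("Mann-Whitney U (", mode, ")"), min(u1, u2), df = NULL,
           p_value = p, sided = alternative, notes = notes, u1 = u1, u2 = u2)
}

tie_correction <- function(r) {
  t <- table(r)
  n <- length(r)
  1 - sum(t^3 - t) / (n^3 - n)
}

#' Kruskal-Wallis rank test for k independent groups
#'
#' H statistic with tie correction, referred to a chi-square distribution with
#' k - 1 degrees of freedom. When all observations are identical H = 0 and
#' p = 1.
#'
#' @param groups a list of numeric vectors, one per group.
#' @return an `acr_test` with `statistic` = H.
#' @export
kruskal_wallis <- function(groups) {
  stop_if_not(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  sizes <- lengths(groups)
  stop_if_not(all(sizes >= 1), "empty group")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (length(unique(x)) == 1L) {
    return(acr_test("Kruskal-Wallis H", 0, df = length(groups) - 1L, p_value = 1,
                    notes = "all observations identical"))
  }
  r <- rank(x)
  g <- rep(seq_along(groups), sizes)
  rsum <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / sizes) - 3 * (n + 1)
  h <- h / tie_correction(r)
  df <- length(groups) - 1L
  acr_test("Kruskal-Wallis H", h, df = df,
           p_value = pchisq(h, df, lower.tail = FALSE))
}

#' Scheirer-Ray-Hare rank two-way ANOVA
#'
#' Nonparametric two-way analysis of variance: all N observations are ranked
#' jointly (mean ranks for ties), the two-way ANOVA sums of squares are
#' computed on the ranks, and each effect's statistic is
#' H = SS_effect / MS_total with MS_total = SS_total / (N - 1), referred to a
#' chi-square distribution with the effect's degrees of freedom. Used to
#' compare freezing time courses between treatment groups across trial blocks.
#'
#' @param values numeric response.
#' @param a,b factors (or vectors coercible to factors) of the two crossed
#'   effects; every cell of the A x B cross must be non-empty.
#' @return a list with `acr_test` entries `A`, `B`, `AB` (interaction).
#' @export
scheirer_ray_hare <- function(values, a, b) {
  a <- as.factor(a); b <- as.factor(b)
  stop_if_not(length(values) == length(a) && length(values) == length(b),
              "values, a, b must have equal length")
  stop_if_not(all(is.finite(values)), "values must be finite")
  cell_n <- table(a, b)
  if (any(cell_n == 0)) stop("empty cell in the A x B design", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  grand <- mean(r)
  ss <- function(means, sizes) sum(sizes * (means - grand)^2)
  m_a <- tapply(r, a, mean);       n_a <- as.vector(table(a))
  m_b <- tapply(r, b, mean);       n_b <- as.vector(table(b))
  m_ab <- tapply(r, list(a, b), mean)
  ss_a <- ss(m_a, n_a)
  ss_b <- ss(m_b, n_b)
  ss_cells <- sum(cell_n * (m_ab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((r - grand)^2)
  ms_tot <- ss_tot / (n - 1)
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  mk <- function(label, ss_e, df_e) {
    h <- ss_e / ms_tot
    acr_test(paste("Scheirer-Ray-Hare H,", label), h, df = df_e,
             p_value = pchisq(h, df_e, lower.tail = FALSE))
  }
  list(A = mk("factor A", ss_a, df_a),
       B = mk("factor B", ss_b, df_b),
       AB = mk("interaction", ss_ab, df_ab))
}

#' Paired Student's t-test
#'
#' t on the within-pair differences with df = n - 1. Degenerate inputs are
#' handled without error: all-zero differences give p = 1; zero-variance
#' nonzero-mean differences give p = 0 with a degeneracy note (the paired
#' spike-count comparisons can produce both, e.g. a unit with complete
#' suppression on every trial).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @param alternative "two.sided" (default), "less" or "greater" for the mean
#'   of `x - y`.
#' @return an `acr_test` with `statistic` = t and `mean_diff`.
#' @export
paired_t <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stop_if_not(length(x) == length(y), "paired samples must have equal length")
  stop_if_not(length(x) >= 2, "need at least 2 pairs")
  d <- x - y
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(acr_test("paired t", 0, df = n - 1L, p_value = 1,
                      sided = alternative, notes = "all differences zero",
                      mean_diff = 0))
    }
    tstat <- sign(mean(d)) * Inf
    p <- switch(alternative,
                two.sided = 0,
                less = if (tstat < 0) 0 else 1,
                greater = if (tstat > 0) 0 else 1)
    return(acr_test("paired t", tstat, df = n - 1L, p_value = p,
                    sided = alternative,
                    notes = "degenerate: zero-variance nonzero-mean differences",
                    mean_diff = mean(d)))
  }
  tstat <- mean(d) / (s / sqrt(n))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(tstat), n - 1),
              less = pt(tstat, n - 1),
              greater = pt(tstat, n - 1, lower.tail = FALSE))
  acr_test("paired t", tstat, df = n - 1L, p_value = p, sided = alternative,
           mean_diff = mean(d))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test for a complete subjects x conditions matrix:
#' F = MS_condition / MS_error with df (k - 1, (k - 1)(n - 1)), where the
#' error sum of squares removes the per-subject offsets.
#'
#' @param m numeric matrix, rows = subjects, columns = conditions; no missing
#'   cells.
#' @return an `acr_test` with `statistic` = F and `df` = c(df1, df2).
#' @export
rm_anova_oneway <- function(m) {
  m <- as.matrix(m)
  stop_if_not(all(is.finite(m)), "matrix must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  stop_if_not(n >= 2 && k >= 2, "need >= 2 subjects and >= 2 conditions")
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  eps <- .Machine$double.eps * max(1, ss_tot)
  if (ss_err <= eps) {
    # no within-subject residual variance: identical condition profiles give
    # F = 0 (p = 1); any condition effect on top of that is infinitely strong
    fstat <- if (ss_cond <= eps) 0 else Inf
    return(acr_test("repeated-measures ANOVA (one-way within-subject)", fstat,
                    df = c(df1, df2), p_value = if (fstat == 0) 1 else 0,
                    notes = "degenerate: zero error variance"))
  }
  fstat <- (ss_cond / df1) / (ss_err / df2)
  acr_test("repeated-measures ANOVA (one-way within-subject)", fstat,
           df = c(df1, df2), p_value = pf(fstat, df1, df2, lower.tail = FALSE))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down multiple-comparison correction: the ordered p-values p_(1) <= ...
#' <= p_(m) are multiplied by m, m - 1, ..., 1 with running-maximum
#' monotonicity enforcement and capping at 1.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha family-wise error rate for the reject flags.
#' @return a list with `adjusted` (in input order) and logical `reject`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  stop_if_not(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(list(adjusted = numeric(0), reject = logical(0)))
  o <- order(p)
  adj_sorted <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted <= alpha)
}
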