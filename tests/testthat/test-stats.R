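test_that("2x2 chi-square matches the Pearson formula and base R", {
  cases <- list(c(14, 59, 2, 68), c(21, 79, 51, 47), c(29, 71, 60, 38),
                c(7, 3, 4, 9), c(100, 1, 1, 100))
  for (cc in cases) {
    mine <- chi2_2x2(cc[1], cc[2], cc[3], cc[4])
    ref <- suppressWarnings(
      chisq.test(matrix(cc, 2, byrow = TRUE), correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(chi2_2x2(10, 10, 10, 10)$statistic, 0)
  expect_error(chi2_2x2(0, 10, 5, 5), "fisher")
})

test_that("Fisher's exact test equals hypergeometric enumeration and base R", {
  expect_equal(fisher_exact_2x2(0, 10, 0, 10)$p_value, 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p_value, 2 / 252, tolerance = 1e-12)
  set.seed(42)
  for (rep in 1:25) {
    cc <- rpois(4, 6)
    mine <- fisher_exact_2x2(cc[1], cc[2], cc[3], cc[4])$p_value
    expect_equal(mine, oracle_fisher_enum(cc[1], cc[2], cc[3], cc[4]),
                 tolerance = 1e-10)
    expect_equal(mine,
                 fisher.test(matrix(cc, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("exact Mann-Whitney equals full-enumeration oracle for small samples", {
  set.seed(7)
  sizes <- list(c(3, 3), c(4, 4), c(3, 6), c(5, 5), c(8, 8))
  for (sz in sizes) {
    for (alt in c("two.sided", "less", "greater")) {
      x <- sample(100, sz[1]); y <- sample(200, sz[2]) + 0.5
      mine <- mann_whitney_u(x, y, alternative = alt, mode = "exact")$p_value
      expect_equal(mine, oracle_mwu_enum(x, y, alt), tolerance = 1e-12,
                   label = sprintf("n=(%d,%d), %s", sz[1], sz[2], alt))
    }
  }
  # agreement with base R's exact two-sided path
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("one-sided continuity-corrected Mann-Whitney reproduces quoted U/p pairs", {
  # U = 19 with n1 = n2 = 8 must give p ~= 0.09 one-sided
  set.seed(1)
  repeat {
    z <- sample(16)
    x <- z[1:8]; y <- z[9:16]
    if (sum(rank(c(x, y))[1:8]) - 36 == 19) break
  }
  r <- mann_whitney_u(x, y, alternative = "less", mode = "normal_cc")
  expect_equal(r$statistic, 19)
  expect_equal(r$p_value, 0.0946, tolerance = 0.005)
  # symmetry: U at the null center gives p ~ 0.5
  repeat {
    z <- sample(16)
    x <- z[1:8]; y <- z[9:16]
    if (sum(rank(c(x, y))[1:8]) - 36 == 32) break
  }
  r0 <- mann_whitney_u(x, y, alternative = "less", mode = "normal_cc")
  # the continuity correction shifts the central p slightly above 0.5
  expect_equal(r0$p_value, 0.5, tolerance = 0.06)
})

test_that("Kruskal-Wallis matches base R including ties", {
  set.seed(11)
  for (rep in 1:10) {
    g <- list(rpois(9, 4), rpois(12, 5), rpois(7, 4))  # ties guaranteed
    mine <- kruskal_wallis(g)
    ref <- kruskal.test(g)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(kruskal_wallis(list(rep(1, 5), rep(1, 6)))$statistic, 0)
  expect_equal(kruskal_wallis(list(rep(1, 5), rep(1, 6)))$p_value, 1)
})

test_that("Kruskal-Wallis with two groups is a monotone function of U", {
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10)
  h <- kruskal_wallis(list(x, y))$statistic
  u1 <- mann_whitney_u(x, y, mode = "normal_cc")$u1
  n1 <- 10; n2 <- 10; n <- 20
  # for two untied groups H = (U1 - n1 n2 / 2)^2 * 12 / (n1 n2 (n+1))
  expect_equal(h, (u1 - n1 * n2 / 2)^2 * 12 / (n1 * n2 * (n + 1)),
               tolerance = 1e-10)
})

test_that("Scheirer-Ray-Hare equals the independent rank-ANOVA oracle", {
  set.seed(21)
  for (rep in 1:10) {
    a <- gl(2, 20); b <- rep(gl(2, 10), 2)
    v <- rnorm(40) + as.numeric(a) * runif(1, 0, 2)
    mine <- scheirer_ray_hare(v, a, b)
    ref <- oracle_srh(v, a, b)
    expect_equal(mine$A$statistic, ref$A, tolerance = 1e-9)
    expect_equal(mine$B$statistic, ref$B, tolerance = 1e-9)
    expect_equal(mine$AB$statistic, ref$AB, tolerance = 1e-9)
  }
  # tied data (integer counts) as well
  v <- rpois(40, 3)
  a <- gl(2, 20); b <- rep(gl(4, 5), 2)
  mine <- scheirer_ray_hare(v, a, b)
  ref <- oracle_srh(v, a, b)
  expect_equal(mine$B$statistic, ref$B, tolerance = 1e-9)
  expect_error(scheirer_ray_hare(rnorm(10), gl(2, 5),
                                 factor(c(1, 1, 2, 2, 2, 1, 1, 1, 1, 1))),
               "empty cell")
})

test_that("Scheirer-Ray-Hare detects an overwhelming factor shift", {
  set.seed(22)
  hits <- 0L
  for (rep in 1:50) {
    a <- gl(2, 16); b <- rep(gl(2, 8), 2)
    v <- rnorm(32) + (as.numeric(b) - 1) * 5
    hits <- hits + (scheirer_ray_hare(v, a, b)$B$p_value < 0.05)
  }
  expect_gte(hits / 50, 0.99)
})

test_that("paired t matches the textbook formula and handles degeneracy", {
  set.seed(31)
  x <- rnorm(12); y <- rnorm(12)
  mine <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # identical pairs
  expect_equal(paired_t(x, x)$p_value, 1)
  # zero-variance nonzero-mean differences: degenerate, p -> 0, no crash
  d <- paired_t(rep(10, 10), rep(0, 10))
  expect_equal(d$p_value, 0)
  expect_match(paste(d$notes, collapse = " "), "degenerate")
  # swapping the samples flips the sign of t
  expect_equal(paired_t(x, y)$statistic, -paired_t(y, x)$statistic,
               tolerance = 1e-12)
})

test_that("repeated-measures ANOVA matches aov and is offset-invariant", {
  set.seed(41)
  m <- matrix(rnorm(40), 8, 5)
  mine <- rm_anova_oneway(m)
  d <- data.frame(y = as.vector(m), s = factor(rep(1:8, 5)),
                  cond = factor(rep(1:5, each = 8)))
  ref <- summary(aov(y ~ cond + Error(s), d))[["Error: Within"]][[1]]
  expect_equal(mine$statistic, ref["cond", "F value"], tolerance = 1e-10)
  expect_equal(mine$p_value, ref["cond", "Pr(>F)"], tolerance = 1e-10)
  # per-subject offsets leave F unchanged
  shifted <- m + rnorm(8) * 10
  expect_equal(rm_anova_oneway(shifted)$statistic, mine$statistic,
               tolerance = 1e-8)
  # identical condition profiles: degenerate F = 0, p = 1, no crash
  flat <- matrix(rep(rnorm(8), 4), 8, 4)
  dres <- rm_anova_oneway(flat)
  expect_equal(dres$statistic, 0)
  expect_equal(dres$p_value, 1)
})

test_that("Holm-Bonferroni equals the step-down oracle and p.adjust", {
  set.seed(51)
  for (rep in 1:20) {
    p <- runif(sample(1:8, 1))
    res <- holm_bonferroni(p)
    expect_equal(res$adjusted, oracle_holm(p), tolerance = 1e-12)
    expect_equal(res$adjusted, p.adjust(p, "holm"), tolerance = 1e-12)
    expect_true(all(res$adjusted >= p))
    expect_true(all(res$adjusted <= 1))
  }
  expect_equal(holm_bonferroni(0.03)$adjusted, 0.03)
})

test_that("null calibration: chi-square and paired t reject near alpha", {
  set.seed(61)
  nrep <- 2000
  rej_chi <- rej_t <- 0L
  for (i in 1:nrep) {
    g1 <- rbinom(1, 50, 0.4); g2 <- rbinom(1, 50, 0.4)
    if (g1 %in% c(0, 50) || g2 %in% c(0, 50)) next
    rej_chi <- rej_chi + (chi2_2x2(g1, 50 - g1, g2, 50 - g2)$p_value < 0.05)
    x <- rnorm(10); y <- rnorm(10)
    rej_t <- rej_t + (paired_t(x, y)$p_value < 0.05)
  }
  expect_lt(abs(rej_chi / nrep - 0.05), 0.02)
  expect_lt(abs(rej_t / nrep - 0.05), 0.015)
})
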