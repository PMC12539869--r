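# Permutation statistical layer.

test_that("permutation ANOVA handles degenerate and separable inputs", {
  g <- rep(1:3, each = 3)
  res0 <- perm_anova_oneway(rep(2, 9), g, n_perm = 100, seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p_perm, 1)
  # perfectly separated groups: compare against exhaustive enumeration
  v <- rep(1:3, each = 3)
  combs1 <- utils::combn(9, 3)
  hits <- 0L; total <- 0L
  for (i in seq_len(ncol(combs1))) {
    rest <- setdiff(1:9, combs1[, i])
    combs2 <- utils::combn(rest, 3)
    for (j in seq_len(ncol(combs2))) {
      total <- total + 1L
      gA <- v[combs1[, i]]; gB <- v[combs2[, j]]
      gC <- v[setdiff(rest, combs2[, j])]
      # observed F is infinite; only zero within-group variance matches it
      if (var(gA) == 0 && var(gB) == 0 && var(gC) == 0) hits <- hits + 1L
    }
  }
  p_exact <- hits / total
  res <- perm_anova_oneway(v, g, n_perm = 5000, seed = 3)
  expect_true(is.infinite(res$observed))
  expect_lt(abs(res$p_perm - p_exact), 0.005)
})

test_that("observed F is invariant to affine transforms and relabeling", {
  set.seed(21)
  v <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
  f0 <- perm_anova_oneway(v, g, n_perm = 10, seed = 1)$observed
  f1 <- perm_anova_oneway(3 * v - 7, g, n_perm = 10, seed = 1)$observed
  g2 <- c(a = "z", b = "y", c = "x")[g]
  f2 <- perm_anova_oneway(v, g2, n_perm = 10, seed = 1)$observed
  expect_equal(f1, f0, tolerance = 1e-12)
  expect_equal(f2, f0, tolerance = 1e-12)
})

test_that("permutation and classical ANOVA p agree on normal data", {
  set.seed(4)
  diffs <- vapply(1:200, function(i) {
    v <- rnorm(18)
    g <- rep(1:3, each = 6)
    r <- perm_anova_oneway(v, g, n_perm = 1000, seed = i)
    abs(r$p_perm - r$p_classical)
  }, 0)
  expect_lt(median(diffs), 0.02)
})

test_that("permutation and classical regression p agree on normal data", {
  set.seed(14)
  xs <- rep(c(32, 16, 6), each = 6)
  diffs <- vapply(1:200, function(i) {
    r <- perm_linreg(xs, rnorm(18), n_perm = 1000, seed = i)
    abs(r$p_perm - r$p_classical)
  }, 0)
  expect_lt(median(diffs), 0.02)
})

test_that("permutation p-values are reproducible and bounded below", {
  v <- c(1, 2, 3, 10, 11, 12); g <- rep(1:2, each = 3)
  a <- perm_anova_oneway(v, g, n_perm = 500, seed = 9)
  b <- perm_anova_oneway(v, g, n_perm = 500, seed = 9)
  expect_identical(a$p_perm, b$p_perm)
  expect_gte(a$p_perm, 1 / 501)
})

test_that("Tukey Q matches a pooled-MS hand computation", {
  # 3 groups of 4, worked by hand via the Tukey-Kramer formula
  v <- c(6, 8, 4, 5,  8, 12, 9, 11,  13, 9, 11, 8)
  g <- rep(c("a", "b", "c"), each = 4)
  means <- tapply(v, g, mean)
  msw <- sum((v - means[g])^2) / (12 - 3)
  q_ab <- abs(means["a"] - means["b"]) / sqrt(msw / 4)
  res <- tukey_posthoc(v, g, n_perm = 0)
  row_ab <- res[res$group1 == "a" & res$group2 == "b", ]
  expect_equal(row_ab$Q, unname(q_ab), tolerance = 1e-12)
  expect_equal(row_ab$p_adj,
               ptukey(unname(q_ab), nmeans = 3, df = 9, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical groups: Q = 0, p = 1
  res2 <- tukey_posthoc(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3), n_perm = 100)
  expect_equal(res2$Q, 0)
  expect_equal(res2$p_adj, 1)
  expect_equal(res2$p_perm_maxQ, 1)
})

test_that("permutation max-Q p tracks the studentized-range p", {
  set.seed(31)
  v <- rnorm(18, mean = rep(c(0, 0.5, 1), each = 6))
  res <- tukey_posthoc(v, rep(1:3, each = 6), n_perm = 4000, seed = 2)
  expect_true(all(abs(res$p_perm_maxQ - res$p_adj) < 0.05))
})

test_that("permutation regression: exact fit, sign convention, errors", {
  x <- 1:10
  r <- perm_linreg(x, 2 * x, n_perm = 500, seed = 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$b1, 2)
  expect_equal(r$p_perm, 1 / 501)
  # alpha falling with salinity gives a negative slope
  sal <- rep(c(32, 16, 6), each = 6)
  set.seed(5)
  alpha <- 0.68 - 0.004 * (sal - 6) + rnorm(18, 0, 0.02)
  rs <- perm_linreg(sal, alpha, n_perm = 1000, seed = 2)
  expect_lt(rs$b1, 0)
  expect_lt(rs$p_perm, 0.05)
  expect_error(perm_linreg(rep(1, 5), rnorm(5)), "constant")
  expect_error(perm_linreg(1:2, 1:2), "n >= 3")
})

test_that("Lilliefors D and its Monte-Carlo null behave", {
  set.seed(6)
  crit18 <- lilliefors_critical(18, n_mc = 4000, seed = 6)
  rej <- mean(vapply(1:400, function(i) {
    o2supply:::lilliefors_D(rnorm(18)) > crit18
  }, TRUE))
  expect_lte(rej, 0.07 + 0.02)           # near-nominal size
  # power against a skewed alternative
  crit50 <- lilliefors_critical(50, n_mc = 4000, seed = 7)
  pow <- mean(vapply(1:200, function(i) {
    o2supply:::lilliefors_D(rexp(50)) > crit50
  }, TRUE))
  expect_gte(pow, 0.5)
  expect_error(lilliefors(rep(1, 10)), "zero variance")
  expect_error(lilliefors(c(1, 2, 3)), "n >= 4")
  r <- lilliefors(rnorm(18), n_mc = 500, seed = 3)
  expect_true(r$observed > 0 && r$p_perm >= 1 / 501 && r$p_perm <= 1)
})

test_that("Levene/Brown-Forsythe detects heteroscedasticity and not its absence", {
  set.seed(8)
  # equal variances: rejection rate near nominal using the classical p
  rej <- mean(vapply(1:200, function(i) {
    levene(rnorm(18), rep(1:3, each = 6), n_perm = 0)$p_classical < 0.05
  }, TRUE))
  expect_gte(rej, 0.005); expect_lte(rej, 0.11)
  # 10x SD in one group, n = 6 each
  pow <- mean(vapply(1:100, function(i) {
    v <- c(rnorm(6, sd = 1), rnorm(6, sd = 1), rnorm(6, sd = 10))
    levene(v, rep(1:3, each = 6), n_perm = 0)$p_classical < 0.05
  }, TRUE))
  expect_gte(pow, 0.6)
  # two groups both {-1, 1}: W = 0, p = 1
  r <- levene(c(-1, 1, -1, 1), rep(1:2, each = 2), n_perm = 100)
  expect_equal(r$observed, 0)
  expect_equal(r$p_classical, 1)
  expect_equal(r$p_perm, 1)
})

test_that("group summaries reproduce mean/SD/SE bookkeeping and effects", {
  m <- data.frame(group_psu = rep(c(32, 16, 6), each = 6),
                  alpha = rep(c(0.56, 0.60, 0.68), each = 6),
                  pcmax_kpa = rep(c(16.17, 12.44, 11.19), each = 6))
  s <- summarize_groups(m)
  expect_equal(s$groups$n, rep(6L, 6))
  eff <- s$effects
  a <- eff[eff$endpoint == "alpha", ]
  expect_equal(a$percent_change_raw, (0.68 - 0.56) / 0.56 * 100)
  expect_equal(a$percent_change_rounded, 20)
  p <- eff[eff$endpoint == "pcmax_kpa", ]
  expect_equal(p$percent_change_rounded, -30)
  # single group: no effect summaries
  s1 <- summarize_groups(m[m$group_psu == 32, ])
  expect_null(s1$effects)
})
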