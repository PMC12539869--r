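# Permutation-based statistical layer.
#
# Significance is assessed against a permutation null (default 10,000
# random relabelings, add-one p estimator so p is never exactly zero);
# the classical distribution-based p is always reported alongside.

perm_p <- function(exceed, n_perm) (1 + exceed) / (1 + n_perm)

# one-way F statistic for a value vector against an integer group index;
# vectorised over columns of a permutation matrix for speed.
f_oneway <- function(values, gi, k, n_g) {
  N <- length(values)
  grand <- mean(values)
  means <- rowsum(values, gi) / n_g
  ssb <- sum(n_g * (means - grand)^2)
  ssw <- sum((values - means[gi])^2)
  if (ssw <= 0) return(if (ssb <= 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (N - k))
}

#' Permutation one-way ANOVA
#'
#' Observed F from the standard one-way decomposition; the permutation p
#' is the add-one tail probability of F under random relabeling of the
#' group memberships.  The classical F-distribution p is reported as a
#' reference.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed making the permutation p reproducible.
#' @return List of class `perm_test` with `statistic_name` = "F",
#'   `observed`, `df`, `p_perm`, `p_classical`, `n_perm`, `seed`.
#' @export
perm_anova_oneway <- function(values, groups, n_perm = 10000, seed = 1) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  k <- nlevels(groups)
  n_g <- as.vector(table(groups))
  if (k < 2 || any(n_g < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  N <- length(values)
  gi <- as.integer(groups)
  if (stats::var(values) == 0) {
    return(structure(list(statistic_name = "F", observed = 0,
                          df = c(k - 1, N - k), p_perm = 1, p_classical = 1,
                          n_perm = n_perm, seed = seed), class = "perm_test"))
  }
  obs <- f_oneway(values, gi, k, n_g)
  exceed <- with_seed(seed, {
    ex <- 0L
    for (b in seq_len(n_perm)) {
      fb <- f_oneway(values[sample.int(N)], gi, k, n_g)
      if (fb >= obs - 1e-12) ex <- ex + 1L
    }
    ex
  })
  structure(list(statistic_name = "F", observed = obs, df = c(k - 1, N - k),
                 p_perm = perm_p(exceed, n_perm),
                 p_classical = stats::pf(obs, k - 1, N - k, lower.tail = FALSE),
                 n_perm = n_perm, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s = %.4g, p_perm = %.4g (n_perm = %d), p_classical = %.4g\n",
              x$statistic_name, x$observed, x$p_perm, x$n_perm, x$p_classical))
  invisible(x)
}

#' Tukey's post hoc test on one-way ANOVA groups
#'
#' Tukey-Kramer studentized-range statistic per pair,
#' `Q = |mean_i - mean_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))`, with adjusted p
#' from the studentized-range distribution.  A permutation p based on the
#' null distribution of the maximum Q is reported as a cross-check
#' (`n_perm = 0` skips it).
#'
#' @inheritParams perm_anova_oneway
#' @param n_perm permutations for the max-Q cross-check (default 2000).
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `Q`, `p_adj` (studentized range), `p_perm_maxQ`.
#' @export
tukey_posthoc <- function(values, groups, n_perm = 2000, seed = 1) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n_g <- as.vector(table(groups))
  if (k < 2 || any(n_g < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  N <- length(values)
  gi <- as.integer(groups)
  df_w <- N - k
  q_stats <- function(v) {
    means <- rowsum(v, gi) / n_g
    msw <- sum((v - means[gi])^2) / df_w
    pairs <- utils::combn(k, 2)
    Q <- apply(pairs, 2, function(p) {
      se <- sqrt(msw / 2 * (1 / n_g[p[1]] + 1 / n_g[p[2]]))
      if (se == 0) 0 else abs(means[p[1]] - means[p[2]]) / se
    })
    list(Q = Q, pairs = pairs)
  }
  obs <- q_stats(values)
  p_adj <- stats::ptukey(obs$Q, nmeans = k, df = df_w, lower.tail = FALSE)
  p_adj[obs$Q == 0] <- 1
  p_perm <- rep(NA_real_, length(obs$Q))
  if (n_perm > 0) {
    maxq <- with_seed(seed, vapply(
      seq_len(n_perm),
      function(b) max(q_stats(values[sample.int(N)])$Q), 0))
    p_perm <- vapply(obs$Q, function(q) perm_p(sum(maxq >= q - 1e-12), n_perm), 0)
    p_perm[obs$Q == 0] <- 1
  }
  lev <- levels(groups)
  data.frame(group1 = lev[obs$pairs[1, ]], group2 = lev[obs$pairs[2, ]],
             diff = apply(obs$pairs, 2, function(p) {
               means <- rowsum(values, gi) / n_g
               means[p[2]] - means[p[1]]
             }),
             Q = obs$Q, p_adj = p_adj, p_perm_maxQ = p_perm)
}

#' Permutation linear regression
#'
#' Ordinary least squares of `y` on `x`; the permutation p comes from
#' permuting `y` against `x` with the regression F as the statistic.
#' Reports slope, its t statistic, R^2, adjusted R^2 and F, mirroring a
#' standard regression summary table.
#'
#' @param x predictor (not constant, n >= 3).
#' @param y response.
#' @inheritParams perm_anova_oneway
#' @return List of class `perm_test` with `b1`, `t`, `r_squared`,
#'   `adj_r_squared`, `observed` (F), `p_perm`, `p_classical`, `n_perm`,
#'   `seed`.
#' @export
perm_linreg <- function(x, y, n_perm = 10000, seed = 1) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0) stop("x is constant", call. = FALSE)
  f_stat <- function(yy) {
    fit <- ols_slope(x, yy)
    sst <- sum((yy - mean(yy))^2)
    if (sst == 0) return(list(F = 0, fit = fit, r2 = 0))
    r2 <- fit$r2
    Fv <- if (r2 >= 1) Inf else r2 / (1 - r2) * (n - 2)
    list(F = Fv, fit = fit, r2 = r2)
  }
  obs <- f_stat(y)
  exceed <- with_seed(seed, {
    ex <- 0L
    for (b in seq_len(n_perm)) {
      if (f_stat(y[sample.int(n)])$F >= obs$F - 1e-12) ex <- ex + 1L
    }
    ex
  })
  t_stat <- if (obs$fit$se == 0) Inf * sign(obs$fit$slope)
            else obs$fit$slope / obs$fit$se
  structure(list(statistic_name = "F", b1 = obs$fit$slope, t = t_stat,
                 r_squared = obs$r2,
                 adj_r_squared = 1 - (1 - obs$r2) * (n - 1) / (n - 2),
                 observed = obs$F,
                 p_perm = perm_p(exceed, n_perm),
                 p_classical = stats::pf(obs$F, 1, n - 2, lower.tail = FALSE),
                 n_perm = n_perm, seed = seed),
            class = "perm_test")
}

lilliefors_D <- function(values) {
  n <- length(values)
  z <- sort((values - mean(values)) / stats::sd(values))
  p <- stats::pnorm(z)
  max(max(seq_len(n) / n - p), max(p - (seq_len(n) - 1) / n))
}

#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov distance between the sample and a normal
#' distribution with mean and SD estimated from the same sample; the null
#' distribution of D (which the estimation step shifts well below the
#' standard KS one) is obtained by Monte Carlo from standard-normal
#' samples of the same size.
#'
#' @param values numeric sample (n >= 4, non-zero variance).
#' @param n_mc Monte-Carlo replicates for the null distribution
#'   (default 10000).
#' @param seed integer seed.
#' @return List of class `perm_test` with `statistic_name` = "D",
#'   `observed`, `p_perm` (Monte-Carlo), `p_classical` (= `p_perm`; no
#'   closed form is used), `n_perm`, `seed`.
#' @export
lilliefors <- function(values, n_mc = 10000, seed = 1) {
  n <- length(values)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance", call. = FALSE)
  obs <- lilliefors_D(values)
  sims <- with_seed(seed, matrix(stats::rnorm(n * n_mc), nrow = n))
  d0 <- apply(sims, 2, lilliefors_D)
  p <- perm_p(sum(d0 >= obs - 1e-12), n_mc)
  structure(list(statistic_name = "D", observed = obs, p_perm = p,
                 p_classical = p, n_perm = n_mc, seed = seed),
            class = "perm_test")
}

#' Monte-Carlo critical value of the Lilliefors D statistic
#'
#' @param n sample size.
#' @param alpha significance level (default 0.05).
#' @param n_mc Monte-Carlo replicates.
#' @param seed integer seed.
#' @return The upper `alpha` quantile of the null D distribution.
#' @export
lilliefors_critical <- function(n, alpha = 0.05, n_mc = 20000, seed = 1) {
  sims <- with_seed(seed, matrix(stats::rnorm(n * n_mc), nrow = n))
  stats::quantile(apply(sims, 2, lilliefors_D), 1 - alpha, names = FALSE)
}

#' Levene / Brown-Forsythe test of homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group centre; the default
#' centre is the median (Brown-Forsythe variant, robust to
#' non-normality).  Both the classical F-distribution p and a permutation
#' p are reported.
#'
#' @inheritParams perm_anova_oneway
#' @param center `"median"` (default) or `"mean"`.
#' @param n_perm permutations for the permutation p (default 2000).
#' @return List of class `perm_test` with `statistic_name` = "W",
#'   `observed`, `p_perm`, `p_classical`, `n_perm`, `seed`, `center`.
#' @export
levene <- function(values, groups, center = c("median", "mean"),
                   n_perm = 2000, seed = 1) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n_g <- as.vector(table(groups))
  if (k < 2 || any(n_g < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  ctr <- if (center == "median") tapply(values, groups, stats::median)
         else tapply(values, groups, mean)
  dev <- abs(values - ctr[as.integer(groups)])
  gi <- as.integer(groups)
  N <- length(values)
  if (stats::var(dev) == 0) {
    W <- 0; p_cl <- 1; p_pm <- 1
  } else {
    W <- f_oneway(dev, gi, k, n_g)
    p_cl <- stats::pf(W, k - 1, N - k, lower.tail = FALSE)
    if (n_perm == 0) p_pm <- NA_real_
    else {
      exceed <- with_seed(seed, {
        ex <- 0L
        for (b in seq_len(n_perm)) {
          # permute raw values, recompute deviations under permuted grouping
          vb <- values[sample.int(N)]
          cb <- if (center == "median") tapply(vb, groups, stats::median)
                else tapply(vb, groups, mean)
          db <- abs(vb - cb[gi])
          wb <- if (stats::var(db) == 0) 0 else f_oneway(db, gi, k, n_g)
          if (wb >= W - 1e-12) ex <- ex + 1L
        }
        ex
      })
      p_pm <- perm_p(exceed, n_perm)
    }
  }
  structure(list(statistic_name = "W", observed = W, p_perm = p_pm,
                 p_classical = p_cl, n_perm = n_perm, seed = seed,
                 center = center),
            class = "perm_test")
}

#' Group summary table and salinity effect sizes
#'
#' Per-group mean, SD and SE for every numeric endpoint in `metrics`, plus
#' the percent change between the extreme salinity groups for the supply
#' capacity and PcMax endpoints (raw and rounded to the nearest 10%).
#'
#' @param metrics per-animal metrics data frame with a `group_psu` column
#'   and numeric endpoint columns.
#' @param endpoints columns to summarise (default: all numeric columns
#'   other than `group_psu`).
#' @return List with `groups` (long-format summary: `group_psu`,
#'   `endpoint`, `n`, `mean`, `sd`, `se`) and `effects` (percent change of
#'   each endpoint from the highest- to the lowest-salinity group;
#'   `NULL` when only one group is present).
#' @export
summarize_groups <- function(metrics, endpoints = NULL) {
  stopifnot("group_psu" %in% names(metrics))
  if (is.null(endpoints)) {
    num <- vapply(metrics, is.numeric, TRUE)
    endpoints <- setdiff(names(metrics)[num], "group_psu")
  }
  grp <- sort(unique(metrics$group_psu), decreasing = TRUE)
  rows <- list()
  for (g in grp) {
    sub <- metrics[metrics$group_psu == g, , drop = FALSE]
    if (!nrow(sub)) { warning("empty group ", g, " omitted"); next }
    for (e in endpoints) {
      v <- sub[[e]][!is.na(sub[[e]])]
      rows[[length(rows) + 1L]] <- data.frame(
        group_psu = g, endpoint = e, n = length(v), mean = mean(v),
        sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
        se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_)
    }
  }
  groups <- do.call(rbind, rows)
  effects <- NULL
  if (length(grp) >= 2) {
    hi <- grp[1]; lo <- grp[length(grp)]
    effects <- do.call(rbind, lapply(endpoints, function(e) {
      m_hi <- groups$mean[groups$group_psu == hi & groups$endpoint == e]
      m_lo <- groups$mean[groups$group_psu == lo & groups$endpoint == e]
      if (!length(m_hi) || !length(m_lo) || m_hi == 0) return(NULL)
      pct <- (m_lo - m_hi) / m_hi * 100
      data.frame(endpoint = e, high_group = hi, low_group = lo,
                 mean_high = m_hi, mean_low = m_lo,
                 percent_change_raw = pct,
                 percent_change_rounded = round(pct / 10) * 10)
    }))
  }
  list(groups = groups, effects = effects)
}
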