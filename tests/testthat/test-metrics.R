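# MMR, mass scaling, alpha estimation, bin-width selection, PcMax.

# build a three-period kPa trace with exact per-period linear declines
three_period_trace <- function(rates_umol_g_h, mass = 800, vol = 40,
                               cond = fix_cond(), start = 21) {
  beta <- solubility_per_kpa(cond)
  v_eff <- vol - mass / 1000
  slopes <- -rates_umol_g_h * mass / (beta * v_eff)    # kPa/h
  t <- numeric(); po2 <- numeric(); phase <- character()
  cursor <- 0
  for (k in seq_along(slopes)) {
    tk <- seq(cursor, cursor + 899, by = 1)
    t <- c(t, tk)
    po2 <- c(po2, start + slopes[k] * (tk - cursor) / 3600)
    phase <- c(phase, rep(sprintf("sealed_%d", k), length(tk)))
    cursor <- cursor + 900
    if (k < length(slopes)) {
      tf <- seq(cursor, cursor + 239, by = 1)
      t <- c(t, tf)
      po2 <- c(po2, rep(start, length(tf)))
      phase <- c(phase, rep(sprintf("flush_%d", k), length(tf)))
      cursor <- cursor + 240
    }
  }
  o2_trace(t, po2, "kpa", cond, phase = phase)
}

test_that("mmr_from_trial takes the fastest-declining period", {
  cond <- fix_cond()
  tr <- three_period_trace(c(5.0, 6.2, 5.8), cond = cond)
  proto <- trial_protocol("mmr", start_po2_kpa = 21)
  ch <- chamber_spec(40, 0)
  m <- mmr_from_trial(tr, proto, ch, 800, cond)
  expect_equal(m$per_period, c(5.0, 6.2, 5.8), tolerance = 1e-9)
  expect_equal(m$mmr, 6.2, tolerance = 1e-9)
  # single period is the identity
  tr1 <- three_period_trace(4.4)
  proto1 <- trial_protocol("mmr", start_po2_kpa = 21, n_measure_periods = 1)
  expect_equal(mmr_from_trial(tr1, proto1, ch, 800, cond)$mmr, 4.4,
               tolerance = 1e-9)
})

test_that("both MMR modes recover a noiseless constant demand within 1%", {
  cond <- fix_cond()
  D <- 6
  ani <- constant_demand_animal(800, D, alpha = 5)
  proto <- noiseless_protocol(dt_s = 1)
  ch <- chamber_spec(40, 0)
  sim <- simulate_trial(ani, proto, ch, cond, seed = 1)
  tr <- sim$trace
  tr$o2_value <- kpa_to_percent_sat(sim$truth$po2_kpa, cond)
  for (mode in c("period_regression", "max_bin")) {
    m <- mmr_from_trial(tr, proto, ch, 800, cond, mode = mode)
    expect_equal(m$mmr, D, tolerance = 0.01)
  }
})

test_that("mass-scaling fit is exact on noiseless power-law data", {
  W <- c(160, 400, 800, 1036)
  fit <- fit_mass_scaling(W, 8 * W^(-0.1))
  expect_equal(fit$c, 8, tolerance = 1e-6)
  expect_equal(fit$b, -0.1, tolerance = 1e-6)
  # constant rate across masses: b = 0
  fit0 <- fit_mass_scaling(W, rep(5, 4))
  expect_equal(fit0$b, 0, tolerance = 1e-8)
  expect_error(fit_mass_scaling(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_mass_scaling(rep(500, 4), 8 * rep(500, 4)^(-0.1)),
               "identical")
})

test_that("b is recovered within 0.05 under 5% lognormal noise", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    W <- exp(runif(18, log(160), log(1036)))
    y <- 8 * W^(-0.1) * rlnorm(18, 0, 0.05)
    fit_mass_scaling(W, y)$b - (-0.1)
  }, 0)
  # per-seed sampling SE of b is ~0.022 here, so 0.05 is a ~2-sigma band:
  # require it of the RMSE and of the central 90%, not of every seed
  expect_lt(sqrt(mean(errs^2)), 0.05)
  expect_gte(mean(abs(errs) < 0.05), 0.9)
  expect_lt(abs(mean(errs)), 0.01)
})

test_that("mass correction follows the (common/W)^b convention", {
  fit <- list(b = -0.1, common_mass_g = 600)
  expect_equal(mass_correct(6, 300, fit), 6 * 2^(-0.1))
  expect_equal(round(mass_correct(6, 300, fit), 3), 5.598)
  expect_equal(mass_correct(6, 600, fit), 6)
  expect_equal(mass_correct(6, 300, list(b = 0, common_mass_g = 600)), 6)
  # monotone in mass for b < 0
  expect_true(all(diff(mass_correct(6, c(200, 400, 800), fit)) > 0))
})

test_that("alpha0 arithmetic, floor, and supply-limited constancy", {
  bins <- data.frame(t_mid_s = 1:4 * 10, po2_kpa = c(10, 5, 0.4, 2),
                     slope_kpa_h = -1,
                     mo2_umol_g_h = c(5.6, 2.8, 0.1, 1.12),
                     n = 5L, r2 = 1, flag = c(FALSE, FALSE, FALSE, TRUE))
  a0 <- alpha0_series(bins)
  expect_equal(a0$alpha0, c(0.56, 0.56))      # floor and flag both excluded
  expect_error(alpha0_series(bins[0, ]), "empty")
  cond <- fix_cond()
  ani <- animal_model(100, 500, 1000, 0.5, recovery_tau_h = 1e9)
  proto <- noiseless_protocol(n_measure_periods = 1, measure_duration_min = 30,
                              dt_s = 1)
  ch <- chamber_spec(40, 0)
  sim <- simulate_trial(ani, proto, ch, cond, seed = 1)
  tr <- sim$trace
  tr$o2_value <- kpa_to_percent_sat(sim$truth$po2_kpa, cond)
  b <- segment_bin_slopes(tr, 60, 1, ch, 100, cond)
  a <- alpha0_series(b)
  expect_true(all(abs(a$alpha0 - 0.5) / 0.5 < 0.01))
})

test_that("alpha0 rises as PO2 falls through a demand-limited decline", {
  cond <- fix_cond()
  ani <- constant_demand_animal(800, 5, alpha = 5)   # never limited
  proto <- noiseless_protocol(n_measure_periods = 1, dt_s = 1)
  ch <- chamber_spec(40, 0)
  sim <- simulate_trial(ani, proto, ch, cond, seed = 1)
  tr <- sim$trace
  tr$o2_value <- kpa_to_percent_sat(sim$truth$po2_kpa, cond)
  a <- alpha0_series(segment_bin_slopes(tr, 60, 1, ch, 800, cond))
  ord <- order(a$po2_kpa, decreasing = TRUE)
  expect_true(all(diff(a$alpha0[ord]) > 0))
})

test_that("estimate_alpha averages the three largest alpha0", {
  expect_equal(estimate_alpha(seq(0.1, 0.5, by = 0.1))$alpha, 0.4)
  expect_equal(estimate_alpha(rep(0.68, 5))$alpha, 0.68)
  expect_error(estimate_alpha(c(0.1, 0.2)), "at least 3")
  set.seed(7)
  for (i in 1:20) {
    v <- runif(sample(3:30, 1))
    est <- estimate_alpha(v)
    s <- sort(v, decreasing = TRUE)
    expect_lte(est$alpha, s[1])
    expect_gte(est$alpha, s[3])
  }
})

test_that("bin-width scan is flat when noiseless and inflated at small bins", {
  cond <- fix_cond(6)
  ani <- animal_model(800, 8 / 3, 8, 0.68)
  proto <- trial_protocol("hypoxia", start_po2_kpa = 11.7)
  ch <- chamber_spec(40, 0)
  sim <- simulate_trial(ani, proto, ch, cond, seed = 9)
  clean <- sim$trace
  clean$o2_value <- kpa_to_percent_sat(sim$truth$po2_kpa, cond)
  sc_clean <- bin_width_scan(clean, chamber = ch, mass = 800, cond = cond)
  expect_lt(diff(range(sc_clean$alpha)) / mean(sc_clean$alpha), 0.01)
  expect_true(all(diff(sc_clean$n_bins) <= 0))
  sc_noisy <- bin_width_scan(sim$trace, chamber = ch, mass = 800, cond = cond)
  plateau <- mean(tail(sc_noisy$alpha, 3))
  expect_gte(sc_noisy$alpha[1], plateau)
})

test_that("bin-width selection follows the rank-sum rule", {
  flat <- data.frame(width_s = c(30, 60, 120), alpha = 0.6, sd_top3 = 0.01,
                     n_bins = c(40, 20, 10), n_alpha0 = c(40, 20, 10))
  expect_equal(select_bin_width(flat), 30)  # all tied: smallest width
  dom <- data.frame(width_s = c(30, 60, 120, 240),
                    alpha = c(0.70, 0.62, 0.61, 0.615),
                    sd_top3 = c(0.05, 0.02, 0.01, 0.012),
                    n_bins = 1, n_alpha0 = 1)
  expect_equal(select_bin_width(dom), 120)  # uniquely minimises both
  jumpy <- data.frame(width_s = c(30, 60, 120),
                      alpha = c(1, 0.5, 1),
                      sd_top3 = c(0.3, 0.05, 0.2), n_bins = 1, n_alpha0 = 1)
  expect_warning(w <- select_bin_width(jumpy), "no stable region")
  expect_equal(w, 60)
  expect_error(select_bin_width(flat[1:2, ]), "at least 3")
})

test_that("adaptive width beats a fixed 45-s width on RMSE", {
  res <- lapply(1:12, function(s) {
    sim <- estimate_one_alpha(0.68, seed = 1000 + s)
    cond <- water_conditions(26, 6)
    # recompute fixed-45s estimate from the same trial
    sim
  })
  # estimate_one_alpha already runs the adaptive path; rebuild fixed-width
  fixed <- vapply(1:12, function(s) {
    set.seed(1000 + s)
    mass <- min(max(stats::rlnorm(1, log(500), 0.45), 160), 1036)
    cond <- water_conditions(26, 6)
    vol <- c(9, 25, 40)[findInterval(mass, c(300, 600)) + 1]
    ch <- chamber_spec(vol, 2)
    ani <- animal_model(mass, 8 / 3, 8, 0.68)
    sim <- simulate_trial(ani, trial_protocol("hypoxia", start_po2_kpa = 11.7),
                          ch, cond, seed = 1000 + s)
    blank <- simulate_microbial_check(ch, cond, seed = 1000 + s + 1)
    mr <- microbial_rate(blank$trace, ch, cond)$rate_chamber_umol_h
    bins <- segment_bin_slopes(sim$trace, 45, 3, ch, mass, cond)
    bins <- subtract_background(bins, max(0, mr), mass)
    estimate_alpha(alpha0_series(bins)$alpha0)$alpha
  }, 0)
  adaptive <- vapply(res, function(r) r$alpha_hat, 0)
  rmse <- function(x) sqrt(mean((x - 0.68)^2))
  expect_lt(rmse(adaptive), rmse(fixed))
})

test_that("pcmax is the MMR/alpha ratio with exact identity", {
  expect_equal(pcmax(0.68, 0.68), 1)
  expect_equal(pcmax(7.46, 0.68), 7.46 / 0.68)
  expect_equal(round(pcmax(7.46, 0.68), 2), 10.97)
  # near, but not equal to, a mean-of-ratios group value of 11.19
  expect_lt(abs(pcmax(7.46, 0.68) - 11.19) / 11.19, 0.03)
  expect_error(pcmax(5, 0), "alpha")
  expect_error(pcmax(0, 1), "mmr_max")
  set.seed(2)
  m <- runif(20, 1, 10); a <- runif(20, 0.1, 1)
  expect_equal(pcmax(m, a) * a, m, tolerance = 1e-15)
})

test_that("a simulated animal's PcMax lands within 10% of mmr0/alpha_true", {
  cond <- fix_cond(6)
  mass <- 700
  ch <- chamber_spec(40, 2)
  ani <- animal_model(mass, 8 / 3, 8, 0.68)
  seeds <- c(11, 12, 13)
  protos <- list(trial_protocol("mmr", start_po2_kpa = 21),
                 trial_protocol("mmr", start_po2_kpa = 27),
                 trial_protocol("hypoxia", start_po2_kpa = 11.7))
  blank <- simulate_microbial_check(ch, cond, seed = 14)
  micro <- max(0, microbial_rate(blank$trace, ch, cond)$rate_chamber_umol_h)
  mmrs <- numeric(3)
  alpha_est <- NULL
  for (i in 1:3) {
    sim <- simulate_trial(ani, protos[[i]], ch, cond, seed = seeds[i])
    mmrs[i] <- mmr_from_trial(sim$trace, protos[[i]], ch, mass, cond,
                              microbial_chamber_umol_h = micro)$mmr
    if (i == 3) alpha_est <- alpha_from_hypoxia(sim$trace, ch, mass, cond,
                                                microbial_chamber_umol_h = micro)
  }
  pc_hat <- pcmax(max(mmrs), alpha_est$alpha)
  expect_lt(abs(pc_hat - 8 / 0.68) / (8 / 0.68), 0.1)
})
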