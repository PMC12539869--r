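# Shared fixtures: everything is generated in code, nothing read from disk.

fix_cond <- function(salinity = 32) water_conditions(26, salinity)

# near-constant demand: recovery so slow that demand == mmr0 to ~1e-13
constant_demand_animal <- function(mass = 800, demand = 5, alpha = 5) {
  animal_model(mass, smr = demand / 2, mmr0 = demand, alpha_true = alpha,
               recovery_tau_h = 1e9)
}

noiseless_protocol <- function(trial_type = "mmr", start_po2 = 21, ...) {
  trial_protocol(trial_type, start_po2_kpa = start_po2, noise_sd_pct = 0, ...)
}

# one simulated animal of the low-salinity stated world: hypoxia trial plus
# blank, alpha estimated through the full scan/selection path
estimate_one_alpha <- function(alpha_true, seed, mass = NULL,
                               salinity = 6, mmr0 = 8) {
  set.seed(seed)
  if (is.null(mass)) {
    mass <- stats::rlnorm(1, log(500), 0.45)
    mass <- min(max(mass, 160), 1036)
  }
  cond <- water_conditions(26, salinity)
  vol <- c(9, 25, 40)[findInterval(mass, c(300, 600)) + 1]
  ch <- chamber_spec(vol, 2)
  ani <- animal_model(mass, mmr0 / 3, mmr0, alpha_true)
  sim <- simulate_trial(ani, trial_protocol("hypoxia", start_po2_kpa = 11.7),
                        ch, cond, seed = seed)
  blank <- simulate_microbial_check(ch, cond, seed = seed + 1)
  mr <- microbial_rate(blank$trace, ch, cond)
  est <- alpha_from_hypoxia(sim$trace, ch, mass, cond,
                            microbial_chamber_umol_h = max(0, mr$rate_chamber_umol_h))
  list(alpha_hat = est$alpha, alpha_true = alpha_true, mass = mass,
       width = est$selected_width_s)
}

# a hand-built piecewise trace in kPa with one exact linear sealed segment
linear_kpa_trace <- function(slope_kpa_h, start_kpa = 11, duration_s = 900,
                             cond = fix_cond(), t0 = 0) {
  t <- seq(t0, t0 + duration_s, by = 1)
  po2 <- start_kpa + slope_kpa_h * (t - t0) / 3600
  tr <- o2_trace(t, po2, unit = "kpa", cond = cond,
                 phase = rep("sealed_1", length(t)))
  tr
}
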